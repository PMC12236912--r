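#' Derive a child seed from a parent seed and an index
#'
#' All randomness in the package flows from one cohort/run seed; component
#' seeds (per subject, per ensemble member, per stage) are derived with this
#' integer mixing function so any component can be regenerated in isolation.
#' The congruential form is evaluated in double precision but all intermediate
#' products stay below 2^53, so the result is exact; outputs lie in
#' [1, 2^31 - 2].
#'
#' @param seed integer parent seed.
#' @param index integer stream index (may be negative).
#' @return a single integer seed.
#' @export
mix_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L)
  m <- 2147483647  # 2^31 - 1
  s <- ((seed %% 94906265) * 22695477) %% m
  s <- (s + ((index %% 94906265) * 1103515245) %% m + 12345) %% m
  as.integer(s %% (m - 1) + 1)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Zero-padded truncated-Gaussian filtering applied along each axis in turn.
#' A constant-zero field smooths to exactly zero, which the phantom generator
#' relies on for its baseline Jacobian channel.
#'
#' @param arr 3D numeric array.
#' @param fwhm full width at half maximum of the kernel, in voxels. A value
#'   of 0 (or less) returns the array unchanged.
#' @return smoothed array of the same dimensions.
#' @export
gauss_smooth3d <- function(arr, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, as.integer(ceiling(2.5 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    acc <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(d[ax]) + off
      keep <- src >= 1L & src <= d[ax]
      if (!any(keep)) next
      idx_dst <- which(keep)
      idx_src <- src[keep]
      if (ax == 1) acc[idx_dst, , ] <- acc[idx_dst, , ] + k[j] * out[idx_src, , ]
      if (ax == 2) acc[, idx_dst, ] <- acc[, idx_dst, ] + k[j] * out[, idx_src, ]
      if (ax == 3) acc[, , idx_dst] <- acc[, , idx_dst] + k[j] * out[, , idx_src]
    }
    out <- acc
  }
  out
}

# run `expr` under a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}
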