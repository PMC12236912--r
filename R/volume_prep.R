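channel_order <- c("gm", "wm", "t1", "jac")

#' Four aligned 3D channels for one subject
#'
#' @param channels named list with elements gm, wm, t1, jac (3D arrays of
#'   identical dimensions); stored in canonical order.
#' @param space_label label of the reference space (e.g., "MNI152").
#' @return an object of class \code{volume_set}.
#' @export
volume_set <- function(channels, space_label = "MNI152") {
  missing <- setdiff(channel_order, names(channels))
  if (length(missing) > 0)
    stop(sprintf("missing channel(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  channels <- channels[channel_order]
  dims <- dim(channels[[1]])
  for (ch in channel_order) {
    if (length(dim(channels[[ch]])) != 3)
      stop(sprintf("channel '%s' is not a 3D array", ch), call. = FALSE)
    if (!all(dim(channels[[ch]]) == dims))
      stop(sprintf("channel '%s' dims (%s) differ from gm dims (%s)",
                   ch, paste(dim(channels[[ch]]), collapse = "x"),
                   paste(dims, collapse = "x")), call. = FALSE)
  }
  structure(list(channels = channels, dims = as.integer(dims),
                 space_label = space_label), class = "volume_set")
}

#' Load a subject's four channels from NIfTI files
#'
#' @param paths named character vector (or list) mapping gm, wm, t1, jac to
#'   file paths.
#' @param expected_dims voxel triple the volumes must match; NULL to skip.
#' @param subject_id used in error messages.
#' @return a \code{volume_set}.
#' @export
load_volume_set <- function(paths, expected_dims = NULL, subject_id = "?") {
  missing <- setdiff(channel_order, names(paths))
  if (length(missing) > 0)
    stop(sprintf("subject %s: missing channel(s): %s", subject_id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  channels <- list()
  for (ch in channel_order) {
    f <- paths[[ch]]
    if (!file.exists(f))
      stop(sprintf("subject %s: channel '%s' file not found: %s",
                   subject_id, ch, f), call. = FALSE)
    arr <- tryCatch(array(as.numeric(RNifti::readNifti(f)),
                          dim(RNifti::readNifti(f))),
                    error = function(e)
                      stop(sprintf("subject %s: channel '%s' unreadable: %s",
                                   subject_id, ch, conditionMessage(e)),
                           call. = FALSE))
    if (!is.null(expected_dims) && !all(dim(arr) == expected_dims))
      stop(sprintf("subject %s: channel '%s' dims %s do not match expected %s",
                   subject_id, ch, paste(dim(arr), collapse = "x"),
                   paste(expected_dims, collapse = "x")), call. = FALSE)
    channels[[ch]] <- arr
  }
  volume_set(channels)
}

#' Centered crop of a 3D volume
#'
#' Per axis, the low-side margin is floor((source - target)/2) and the
#' high side takes the remainder; the output is a contiguous sub-block of
#' the input (no interpolation). Cropping 91 x 109 x 91 to 75 x 88 x 78
#' removes margins (8, 10, 6) low and (8, 11, 7) high.
#'
#' @param vol 3D array.
#' @param target_dims voxel triple, each <= the corresponding source dim.
#' @return cropped array of dimension \code{target_dims}.
#' @export
crop_volume <- function(vol, target_dims) {
  src <- dim(vol)
  stopifnot(length(src) == 3, length(target_dims) == 3)
  if (any(target_dims > src))
    stop(sprintf("target dims %s exceed source dims %s on some axis",
                 paste(target_dims, collapse = "x"),
                 paste(src, collapse = "x")), call. = FALSE)
  lo <- (src - target_dims) %/% 2
  vol[lo[1] + seq_len(target_dims[1]),
      lo[2] + seq_len(target_dims[2]),
      lo[3] + seq_len(target_dims[3]), drop = FALSE]
}

#' @rdname crop_volume
#' @param vol_set a \code{volume_set}; every channel is cropped.
#' @export
crop_volume_set <- function(vol_set, target_dims) {
  stopifnot(inherits(vol_set, "volume_set"))
  volume_set(lapply(vol_set$channels, crop_volume, target_dims = target_dims),
             space_label = vol_set$space_label)
}

#' Automated quality-control screen of a volume set
#'
#' Raises flags (not errors) for non-finite voxels, all-zero channels, and
#' channel dimension mismatches; a subject fails QC if any flag is raised.
#'
#' @param vol_set a \code{volume_set}.
#' @return list with logical flags \code{nonfinite}, \code{empty_channel},
#'   \code{dims_mismatch}, per-channel detail, and overall \code{pass}.
#' @export
qc_screen <- function(vol_set) {
  stopifnot(inherits(vol_set, "volume_set"))
  nonfinite <- vapply(vol_set$channels, function(a) any(!is.finite(a)), TRUE)
  empty <- vapply(vol_set$channels, function(a) all(a == 0), TRUE)
  dmis <- vapply(vol_set$channels,
                 function(a) !all(dim(a) == vol_set$dims), TRUE)
  flags <- list(nonfinite = any(nonfinite), empty_channel = any(empty),
                dims_mismatch = any(dmis),
                by_channel = data.frame(channel = names(vol_set$channels),
                                        nonfinite = nonfinite,
                                        empty = empty))
  flags$pass <- !(flags$nonfinite || flags$empty_channel || flags$dims_mismatch)
  flags
}

#' Stack volume sets into the 5D batch layout
#'
#' Axis order is (batch, channel, X, Y, Z) with the channel axis fixed to
#' (gm, wm, t1, jac) - the layout the CNN consumes.
#'
#' @param vol_sets list of \code{volume_set}s sharing dimensions.
#' @param subject_ids optional ids (defaults to list names).
#' @return an object of class \code{batch_tensor}: list with \code{data}
#'   (5D array) and \code{subject_ids}.
#' @export
stack_batch <- function(vol_sets, subject_ids = names(vol_sets)) {
  stopifnot(length(vol_sets) >= 1)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_along(vol_sets))
  dims <- vol_sets[[1]]$dims
  for (i in seq_along(vol_sets)) {
    stopifnot(inherits(vol_sets[[i]], "volume_set"))
    if (!all(vol_sets[[i]]$dims == dims))
      stop(sprintf("volume %d dims %s differ from first volume dims %s",
                   i, paste(vol_sets[[i]]$dims, collapse = "x"),
                   paste(dims, collapse = "x")), call. = FALSE)
  }
  n <- length(vol_sets)
  data <- array(0, c(n, length(channel_order), dims))
  for (i in seq_len(n))
    for (c in seq_along(channel_order))
      data[i, c, , , ] <- vol_sets[[i]]$channels[[channel_order[c]]]
  structure(list(data = data, subject_ids = subject_ids),
            class = "batch_tensor")
}

#' @rdname stack_batch
#' @param batch a \code{batch_tensor}.
#' @return \code{unstack_batch}: the list of \code{volume_set}s.
#' @export
unstack_batch <- function(batch) {
  stopifnot(inherits(batch, "batch_tensor"))
  d <- dim(batch$data)
  out <- lapply(seq_len(d[1]), function(i) {
    chans <- lapply(seq_len(d[2]), function(c)
      array(batch$data[i, c, , , ], d[3:5]))
    names(chans) <- channel_order
    volume_set(chans)
  })
  names(out) <- batch$subject_ids
  out
}

#' Subset a batch tensor by subject id
#' @param batch a \code{batch_tensor}.
#' @param ids subject ids to keep, in the requested order.
#' @export
subset_batch <- function(batch, ids) {
  stopifnot(inherits(batch, "batch_tensor"))
  idx <- match(ids, batch$subject_ids)
  if (anyNA(idx)) stop("unknown subject id(s) in batch subset", call. = FALSE)
  structure(list(data = batch$data[idx, , , , , drop = FALSE],
                 subject_ids = batch$subject_ids[idx]),
            class = "batch_tensor")
}

#' Persist / restore a prepared batch tensor
#'
#' A fast binary array cache between preparation and training; round-trips
#' exactly.
#' @param batch a \code{batch_tensor}.
#' @param path cache file path.
#' @export
save_batch_cache <- function(batch, path) {
  stopifnot(inherits(batch, "batch_tensor"))
  saveRDS(batch, path)
  invisible(path)
}

#' @rdname save_batch_cache
#' @export
load_batch_cache <- function(path) {
  batch <- readRDS(path)
  stopifnot(inherits(batch, "batch_tensor"))
  batch
}

#' Render, crop, QC and stack a cohort in one step
#'
#' The in-memory preparation path used by the pipeline: renders every
#' phantom, center-crops to \code{target_dims}, drops QC failures, and
#' stacks the survivors.
#'
#' @param cohort a \code{cohort}.
#' @param params a \code{phantom_params}.
#' @param target_dims crop target (defaults to the phantom grid: no crop).
#' @param control_noise_sd morphological noise SD for controls.
#' @return list with \code{batch} (a \code{batch_tensor}), \code{qc}
#'   (per-subject pass flags), and \code{cohort} (QC-passing rows).
#' @export
prepare_cohort <- function(cohort, params, target_dims = params$grid_dims,
                           control_noise_sd = 0.25) {
  vols <- render_cohort(cohort, params, control_noise_sd = control_noise_sd)
  vols <- lapply(vols, crop_volume_set, target_dims = target_dims)
  qc <- vapply(vols, function(v) qc_screen(v)$pass, TRUE)
  keep <- names(vols)[qc]
  list(batch = stack_batch(vols[keep], keep),
       qc = qc,
       cohort = cohort[cohort$subject_id %in% keep, ])
}
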