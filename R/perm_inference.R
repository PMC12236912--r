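#' Build a GLM design matrix with site-wise parameters
#'
#' Three design families for PAD inference, all with per-site intercepts:
#' model 1 has diagnosis only; model 2 adds site-wise slopes for the
#' covariates (age, sex, medication, comorbidity by default); model 3 is
#' model 2 plus a diagnosis-by-centered-age interaction as the tested
#' regressor (diagnosis itself becoming a nuisance). Continuous covariates
#' are mean-centered within site. Diagnosis is coded 0 (HC) / 1 (GAD).
#' Rank-deficient columns (e.g., a covariate constant within every site)
#' are dropped with a warning.
#'
#' @param tbl data frame with diagnosis (or dx), site, and any covariates.
#' @param model_id 1, 2 or 3.
#' @param covariates covariate columns for models 2 and 3.
#' @param site_specific give each site its own intercept and covariate
#'   slopes (default TRUE; with a single site this reduces to ordinary
#'   covariates, with a warning).
#' @return list with \code{X} (design matrix), \code{contrast} (vector over
#'   columns picking the tested regressor), \code{labels}, and
#'   \code{dropped} (labels of any dropped columns).
#' @export
build_design <- function(tbl, model_id = 1L,
                         covariates = c("age", "sex", "med", "comorbid"),
                         site_specific = TRUE) {
  if (!model_id %in% 1:3) stop_config("model_id", "must be 1, 2 or 3")
  dxcol <- if ("diagnosis" %in% names(tbl)) "diagnosis" else "dx"
  if (!dxcol %in% names(tbl)) stop("no diagnosis column", call. = FALSE)
  if (!"site" %in% names(tbl)) stop("no site column", call. = FALSE)
  dx <- as.numeric(tbl[[dxcol]] == "GAD")
  if (all(dx == 0) || all(dx == 1))
    stop("cohort contains a single diagnosis group", call. = FALSE)
  site <- factor(tbl$site)
  if (site_specific && nlevels(site) < 2) {
    warning("single site: site-specific design reduces to ordinary covariates")
    site_specific <- FALSE
  }
  n <- nrow(tbl)
  num_cov <- function(v) {
    if (is.numeric(v)) v else as.numeric(factor(v)) - 1
  }
  cols <- list()
  labels <- character()
  add <- function(v, lab) {
    cols[[length(cols) + 1L]] <<- v
    labels[length(labels) + 1L] <<- lab
  }
  # intercepts
  if (site_specific) {
    for (s in levels(site)) add(as.numeric(site == s), paste0("intercept_", s))
  } else add(rep(1, n), "intercept")
  use_cov <- if (model_id >= 2) covariates else character()
  missing <- setdiff(use_cov, names(tbl))
  if (length(missing) > 0)
    stop(sprintf("missing covariate column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  center_within_site <- function(v) {
    stats::ave(v, site, FUN = function(x) x - mean(x))
  }
  for (cv in use_cov) {
    v <- num_cov(tbl[[cv]])
    vc <- if (is.numeric(tbl[[cv]]) && length(unique(v)) > 2)
      center_within_site(v) else v
    if (site_specific) {
      for (s in levels(site))
        add(vc * (site == s), paste0(cv, "_", s))
    } else add(vc, cv)
  }
  add(dx, "dx")
  if (model_id == 3) {
    agec <- center_within_site(num_cov(tbl$age))
    add(dx * agec, "dx_x_age")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  tested <- if (model_id == 3) "dx_x_age" else "dx"
  # drop rank-deficient columns, never the tested one (QR with the tested
  # column ordered first so the pivot cannot discard it)
  must <- match(tested, labels)
  ord <- c(must, setdiff(seq_len(ncol(X)), must))
  qrX <- qr(X[, ord, drop = FALSE])
  dropped <- character()
  if (qrX$rank < ncol(X)) {
    keep <- sort(ord[qrX$pivot[seq_len(qrX$rank)]])
    dropped <- labels[setdiff(seq_len(ncol(X)), keep)]
    warning(sprintf("dropped rank-deficient column(s): %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  contrast <- as.numeric(labels == tested)
  list(X = X, contrast = contrast, labels = labels, dropped = dropped,
       model_id = model_id)
}

#' Heteroscedasticity-aware GLM contrast statistic with variance groups
#'
#' For a rank-1 contrast c: an ordinary least-squares start yields
#' per-variance-group residual variances (group residual sum of squares
#' divided by group residual degrees of freedom, n_g minus the summed OLS
#' leverages in g); one weighted-least-squares step with weights 1/sigma_g^2
#' then gives the statistic c'beta / sqrt(c'(X'WX)^{-1}c). With a single
#' variance group this reduces exactly to the classical t statistic, and
#' for a two-group design with two variance groups to Welch's t.
#'
#' @param X design matrix (full column rank).
#' @param y response vector.
#' @param contrast numeric contrast vector of length ncol(X).
#' @param vg variance-group labels (one per row); NULL for one group.
#' @return list with \code{stat}, \code{beta}, \code{group_var}, and
#'   \code{degenerate} (TRUE if some group has zero residual variance, in
#'   which case the statistic is NA).
#' @export
glm_statistic <- function(X, y, contrast, vg = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(contrast) == p)
  if (is.null(vg)) vg <- rep(1L, n)
  vg <- as.factor(vg)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  beta_ols <- qr.coef(qrX, y)
  res <- y - X %*% beta_ols
  h <- rowSums(qr.Q(qrX)^2)  # leverages
  gv <- numeric(nlevels(vg))
  for (i in seq_len(nlevels(vg))) {
    sel <- vg == levels(vg)[i]
    dof <- sum(sel) - sum(h[sel])
    if (dof <= 0)
      stop(sprintf("variance group '%s' has no residual degrees of freedom",
                   levels(vg)[i]), call. = FALSE)
    gv[i] <- sum(res[sel]^2) / dof
  }
  names(gv) <- levels(vg)
  if (any(gv <= 0)) {
    return(list(stat = NA_real_, beta = drop(beta_ols), group_var = gv,
                degenerate = TRUE))
  }
  w <- 1 / gv[as.integer(vg)]
  Xw <- X * w
  XtWX <- crossprod(X, Xw)
  beta <- solve(XtWX, crossprod(Xw, y))
  se <- sqrt(drop(t(contrast) %*% solve(XtWX, contrast)))
  list(stat = drop(crossprod(contrast, beta)) / se, beta = drop(beta),
       group_var = gv, degenerate = FALSE)
}

# reparametrize X so the tested effect c'beta becomes the coefficient of the
# first column; K = [c'; N']^-1 with N a basis of the null space of c'
partition_design <- function(X, contrast) {
  p <- ncol(X)
  qc <- qr(matrix(contrast, ncol = 1))
  N <- qr.Q(qc, complete = TRUE)[, -1, drop = FALSE]
  K <- rbind(t(contrast), t(N))
  Xt <- X %*% solve(K)
  colnames(Xt) <- c("tested", paste0("nuis", seq_len(p - 1L)))
  Xt
}

#' Sign-flipping permutation test of a GLM contrast
#'
#' Freedman-Lane style: the response is residualized against the nuisance
#' part of the (reparametrized) design; each permutation multiplies the
#' residuals by random signs, adds back the nuisance fit, and recomputes
#' the variance-group statistic. When 2^n <= n_perm the 2^n sign patterns
#' are enumerated instead (the identity pattern included), giving an exact
#' test; otherwise p = (1 + #{|stat_perm| >= |stat_obs|}) / (n_perm + 1).
#'
#' @param X design matrix.
#' @param y response.
#' @param contrast rank-1 contrast vector.
#' @param vg variance-group labels or NULL.
#' @param cfg a \code{perm_config}.
#' @return object of class \code{perm_result}: stat, p, perm_stats,
#'   n_perm (effective), enumerated, seed.
#' @export
sign_flip_test <- function(X, y, contrast, vg = NULL, cfg = perm_config()) {
  stopifnot(inherits(cfg, "perm_config"))
  X <- as.matrix(X)
  n <- nrow(X)
  Xt <- partition_design(X, contrast)
  e1 <- c(1, rep(0, ncol(Xt) - 1))
  obs <- glm_statistic(Xt, y, e1, vg)$stat
  Z <- Xt[, -1, drop = FALSE]
  if (ncol(Z) > 0) {
    fit <- qr.fitted(qr(Z), y)
    res <- y - fit
  } else {
    fit <- rep(0, n)
    res <- y
  }
  enumerate <- n <= 30 && 2^n <= cfg$n_perm
  tol <- 1e-8 * (1 + abs(obs))
  if (enumerate) {
    n_eff <- 2^n
    stats <- numeric(n_eff)
    for (i in seq_len(n_eff)) {
      s <- 1 - 2 * as.integer(intToBits(i - 1))[seq_len(n)]
      stats[i] <- glm_statistic(Xt, fit + s * res, e1, vg)$stat
    }
    p <- mean(abs(stats) >= abs(obs) - tol)
  } else {
    n_eff <- cfg$n_perm
    stats <- with_seed(mix_seed(cfg$seed, 31L), {
      vapply(seq_len(n_eff), function(i) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        glm_statistic(Xt, fit + s * res, e1, vg)$stat
      }, 1)
    })
    p <- (1 + sum(abs(stats) >= abs(obs) - tol)) / (n_eff + 1)
  }
  structure(list(stat = obs, p = p, perm_stats = stats, n_perm = n_eff,
                 enumerated = enumerate, seed = cfg$seed),
            class = "perm_result")
}

#' Permutation configuration
#'
#' @param n_perm number of sign-flips (default 10,000).
#' @param scheme permutation scheme; only \code{"sign_flip"} is supported.
#' @param seed integer seed for the flip sequence.
#' @param fwer compute max-statistic FWER-adjusted p-values across the
#'   contrasts of a run.
#' @return an object of class \code{perm_config}.
#' @export
perm_config <- function(n_perm = 10000L, scheme = "sign_flip", seed = 1L,
                        fwer = TRUE) {
  if (n_perm < 1) stop_config("n_perm", "must be >= 1")
  if (!identical(scheme, "sign_flip"))
    stop_config("scheme", "must be 'sign_flip'")
  structure(list(n_perm = as.integer(n_perm), scheme = scheme,
                 seed = as.integer(seed), fwer = isTRUE(fwer)),
            class = "perm_config")
}

#' Max-statistic FWER adjustment across contrasts
#'
#' Requires every contrast to have been evaluated on the same permutation
#' schedule (same seed, count and enumeration mode). The adjusted p for
#' contrast c is the proportion of permutations whose maximum absolute
#' statistic across contrasts reaches |stat_obs,c| (with +1 smoothing for
#' sampled schedules); it is never smaller than the unadjusted p.
#'
#' @param results list of \code{perm_result}s sharing a schedule.
#' @return data frame: contrast, stat, p_unadj, p_fwer.
#' @export
fwer_adjust <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "perm_result")))
  n_perm <- vapply(results, `[[`, 1L, "n_perm")
  seeds <- vapply(results, `[[`, 1L, "seed")
  enum <- vapply(results, `[[`, TRUE, "enumerated")
  if (length(unique(n_perm)) != 1 || length(unique(seeds)) != 1 ||
      length(unique(enum)) != 1)
    stop("mismatched permutation schedules across contrasts", call. = FALSE)
  mat <- vapply(results, function(r) abs(r$perm_stats), numeric(n_perm[1]))
  maxstat <- apply(matrix(mat, nrow = n_perm[1]), 1, max)
  labs <- names(results)
  if (is.null(labs)) labs <- paste0("contrast", seq_along(results))
  out <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tol <- 1e-8 * (1 + abs(r$stat))
    p_adj <- if (enum[1]) mean(maxstat >= abs(r$stat) - tol)
    else (1 + sum(maxstat >= abs(r$stat) - tol)) / (n_perm[1] + 1)
    data.frame(contrast = labs[i], stat = r$stat, p_unadj = r$p,
               p_fwer = max(p_adj, r$p))
  })
  do.call(rbind, out)
}

#' Run the three PAD GLMs with sign-flipping and FWER correction
#'
#' Convenience wrapper: builds designs for model ids 1-3 on a PAD table,
#' uses diagnosis as the variance grouping, runs
#' \code{\link{sign_flip_test}} for each model's tested contrast on a
#' shared permutation schedule, and applies max-statistic FWER correction
#' across the three contrasts.
#'
#' @param pad_table a \code{pad_table} (needs age, sex, medication,
#'   comorbidity, site, diagnosis columns).
#' @param cfg a \code{perm_config}.
#' @param model_ids which of the three models to run.
#' @return list with \code{table} (contrast, statistic, p_unadj, p_fwer,
#'   n_perm) and \code{results} (named \code{perm_result}s).
#' @export
run_pad_glms <- function(pad_table, cfg = perm_config(), model_ids = 1:3) {
  tbl <- data.frame(diagnosis = pad_table$diagnosis, site = pad_table$site,
                    age = pad_table$true_age, sex = pad_table$sex,
                    med = pad_table$medication,
                    comorbid = pad_table$comorbidity)
  y <- pad_table$pad
  vg <- pad_table$diagnosis
  results <- list()
  for (mid in model_ids) {
    ds <- build_design(tbl, model_id = mid)
    results[[sprintf("model%d_%s", mid,
                     ds$labels[which(ds$contrast != 0)])]] <-
      sign_flip_test(ds$X, y, ds$contrast, vg, cfg)
  }
  adj <- fwer_adjust(results)
  adj$n_perm <- vapply(results, `[[`, 1L, "n_perm")
  list(table = adj, results = results)
}
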