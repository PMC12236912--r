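#' Specification of a homogeneous deep ensemble
#'
#' k instantiations of one architecture, each trained on its own random
#' 90/10 train/validation split of the training sample and initialized with
#' its own random weights; test predictions are averaged across members.
#'
#' @param k number of members (default 8).
#' @param val_fraction fraction of the training sample held out per member
#'   for validation (default 0.10; rounded to the nearest subject, floor 1).
#' @param base_seed seed from which member split and weight seeds are
#'   derived.
#' @param arch an \code{arch_config} shared by all members.
#' @param train_cfg a \code{train_config} shared by all members.
#' @return an object of class \code{ensemble_spec}.
#' @export
ensemble_spec <- function(k = 8L, val_fraction = 0.10, base_seed = 1L,
                          arch = arch_config(), train_cfg = train_config()) {
  if (k < 2) stop_config("k", "must be >= 2")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop_config("val_fraction", "must be in (0, 1)")
  structure(list(k = as.integer(k), val_fraction = val_fraction,
                 base_seed = as.integer(base_seed), arch = arch,
                 train_cfg = train_cfg), class = "ensemble_spec")
}

#' Independent train/validation splits for each ensemble member
#'
#' Each member holds out an independent random \code{val_fraction} of the
#' subject ids (rounded to nearest, at least 1); within each split, train
#' and validation partition the ids. Member m's draw uses the seed derived
#' from \code{base_seed} and m, so splits are reproducible per member.
#'
#' @param subject_ids character vector of ids.
#' @param spec an \code{ensemble_spec}.
#' @return list of k lists with elements \code{train} and \code{val}.
#' @export
make_splits <- function(subject_ids, spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- length(subject_ids)
  if (n < 10) stop("need at least 10 subjects to split", call. = FALSE)
  n_val <- max(1L, as.integer(round(n * spec$val_fraction)))
  lapply(seq_len(spec$k), function(m) {
    val <- with_seed(mix_seed(spec$base_seed, m),
                     sample(subject_ids, n_val))
    list(train = setdiff(subject_ids, val), val = val)
  })
}

#' Train a homogeneous ensemble
#'
#' Trains \code{spec$k} models independently. Member m uses split m from
#' \code{\link{make_splits}}, a weight seed derived from the base seed, and
#' a training-loop seed of its own, so any member can be retrained in
#' isolation.
#'
#' @param train list with \code{x} (a \code{batch_tensor} of the full
#'   training sample) and \code{ages} aligned with its subjects.
#' @param spec an \code{ensemble_spec}.
#' @return list with \code{models}, \code{logs}, \code{splits}, \code{spec}.
#' @export
train_ensemble <- function(train, spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  ids <- train$x$subject_ids
  ages <- stats::setNames(train$ages, ids)
  splits <- make_splits(ids, spec)
  models <- vector("list", spec$k)
  logs <- vector("list", spec$k)
  for (m in seq_len(spec$k)) {
    res <- tryCatch({
      model <- build_model(spec$arch, seed = mix_seed(spec$base_seed, 1000L + m))
      cfg <- spec$train_cfg
      cfg$seed <- mix_seed(spec$base_seed, 2000L + m)
      tr <- list(x = subset_batch(train$x, splits[[m]]$train),
                 ages = unname(ages[splits[[m]]$train]))
      va <- list(x = subset_batch(train$x, splits[[m]]$val),
                 ages = unname(ages[splits[[m]]$val]))
      train_model(model, tr, va, cfg)
    }, error = function(e)
      stop(sprintf("ensemble member %d failed: %s", m, conditionMessage(e)),
           call. = FALSE))
    models[[m]] <- res$model
    logs[[m]] <- res$log
  }
  list(models = models, logs = logs, splits = splits, spec = spec)
}

#' Averaged ensemble predictions with per-member columns
#'
#' @param models list of trained \code{cnn_model}s.
#' @param batch a \code{batch_tensor} of test subjects.
#' @return an object of class \code{ensemble_predictions}: list with
#'   \code{matrix} (subjects x k member predictions), \code{ensemble_mean}
#'   (rowwise arithmetic mean), and \code{subject_ids}.
#' @export
ensemble_predict <- function(models, batch) {
  stopifnot(length(models) >= 1, inherits(batch, "batch_tensor"))
  preds <- vapply(models, function(m) unname(predict_ages(m, batch)),
                  numeric(length(batch$subject_ids)))
  preds <- matrix(preds, nrow = length(batch$subject_ids),
                  dimnames = list(batch$subject_ids,
                                  paste0("pred_m", seq_along(models))))
  structure(list(matrix = preds,
                 ensemble_mean = rowMeans(preds),
                 subject_ids = batch$subject_ids),
            class = "ensemble_predictions")
}

#' Intraclass correlation ICC(2,k) of member predictions
#'
#' Two-way random-effects, average-of-k-raters, absolute-agreement ICC
#' (Shrout-Fleiss form [2,k]). With MSR, MSC and MSE the between-subject,
#' between-rater and residual mean squares of the two-way decomposition,
#' \deqn{ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n).}
#' The consistency variant, (MSR - MSE)/MSR, is available via \code{type}.
#'
#' @param pred_matrix numeric matrix, subjects x raters (no missing cells).
#' @param type \code{"agreement"} (default) or \code{"consistency"}.
#' @return list with \code{icc} (clipped to [-1, 1]), \code{icc_raw},
#'   mean squares, and \code{degenerate} (TRUE when total variance is zero,
#'   in which case ICC is defined as 1).
#' @export
icc_2k <- function(pred_matrix, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(pred_matrix)
  if (anyNA(m)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total <= .Machine$double.eps * max(1, abs(grand))^2) {
    return(list(icc = 1, icc_raw = 1, msr = msr, msc = msc, mse = mse,
                degenerate = TRUE))
  }
  raw <- if (type == "agreement")
    (msr - mse) / (msr + (msc - mse) / n)
  else
    (msr - mse) / msr
  list(icc = max(-1, min(1, raw)), icc_raw = raw,
       msr = msr, msc = msc, mse = mse, degenerate = FALSE)
}

#' Predictions table in the export layout
#'
#' @param ep an \code{ensemble_predictions}.
#' @param true_ages named numeric vector of chronological ages.
#' @return data frame: subject_id, true_age, pred_m1..pred_mk, pred_ensemble.
#' @export
predictions_table <- function(ep, true_ages) {
  stopifnot(inherits(ep, "ensemble_predictions"))
  data.frame(subject_id = ep$subject_ids,
             true_age = unname(true_ages[ep$subject_ids]),
             ep$matrix,
             pred_ensemble = unname(ep$ensemble_mean),
             row.names = NULL)
}
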