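#' Predicted age difference (PAD) table
#'
#' PAD = predicted age minus chronological age, so a positive PAD reads as
#' an "older-looking" brain. Subjects are partitioned at the age cutoff
#' (default 25 years): strictly younger is \code{under25}, 25 and older is
#' \code{over25}.
#'
#' @param predictions data frame with columns \code{subject_id} and
#'   \code{pred_ensemble} (e.g., from \code{\link{predictions_table}}), or
#'   an \code{ensemble_predictions} object.
#' @param participants data frame with subject_id, age, sex, site, dx, med,
#'   comorbid.
#' @param age_cutoff partition boundary in years.
#' @return data frame of class \code{pad_table}: subject_id, true_age,
#'   predicted_age, pad, diagnosis, site, sex, medication, comorbidity,
#'   age_partition.
#' @export
compute_pad <- function(predictions, participants, age_cutoff = 25) {
  if (inherits(predictions, "ensemble_predictions"))
    predictions <- data.frame(subject_id = predictions$subject_ids,
                              pred_ensemble = unname(predictions$ensemble_mean))
  stopifnot(all(c("subject_id", "pred_ensemble") %in% names(predictions)))
  idx <- match(predictions$subject_id, participants$subject_id)
  if (anyNA(idx))
    stop("prediction subject ids missing from participants table",
         call. = FALSE)
  p <- participants[idx, ]
  if (anyNA(p$age)) stop("missing ages in participants table", call. = FALSE)
  out <- data.frame(
    subject_id = predictions$subject_id,
    true_age = p$age,
    predicted_age = predictions$pred_ensemble,
    pad = predictions$pred_ensemble - p$age,
    diagnosis = p$dx,
    site = p$site,
    sex = p$sex,
    medication = p$med,
    comorbidity = p$comorbid,
    age_partition = ifelse(p$age < age_cutoff, "under25", "over25"),
    row.names = NULL)
  class(out) <- c("pad_table", "data.frame")
  out
}

#' Per-group accuracy and PAD summaries
#'
#' MAE = mean |pad|, MSE = mean pad^2; SD uses the unbiased (n-1)
#' denominator and variance is its square.
#'
#' @param pad_table a \code{pad_table}.
#' @param grouping column name to group by (e.g., "diagnosis"), or a factor
#'   aligned with the rows; NULL for a single overall group.
#' @return data frame with group, n, mae, mse, mean_pad, median_pad,
#'   sd_pad, var_pad.
#' @export
group_metrics <- function(pad_table, grouping = "diagnosis") {
  g <- if (is.null(grouping)) rep("all", nrow(pad_table))
  else if (length(grouping) == 1 && is.character(grouping))
    pad_table[[grouping]]
  else grouping
  out <- lapply(split(pad_table$pad, g), function(pad) {
    if (length(pad) == 0) stop("empty group", call. = FALSE)
    data.frame(n = length(pad), mae = mean(abs(pad)), mse = mean(pad^2),
               mean_pad = mean(pad), median_pad = median(pad),
               sd_pad = sd(pad), var_pad = var(pad))
  })
  cbind(data.frame(group = names(out)), do.call(rbind, out), row.names = NULL)
}

#' Correlations of true age with predicted age and with PAD
#'
#' Pearson correlations with two-sided p-values from the t transform.
#' If either variable is constant the correlation is flagged undefined.
#'
#' @param pad_table a \code{pad_table}.
#' @return data frame with rows \code{true_vs_predicted} and
#'   \code{true_vs_pad}: r, p, n, defined.
#' @export
correlations <- function(pad_table) {
  stopifnot(nrow(pad_table) >= 3)
  one <- function(x, y, label) {
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(comparison = label, r = NA_real_, p = NA_real_,
                        n = length(x), defined = FALSE))
    ct <- cor.test(x, y)
    data.frame(comparison = label, r = unname(ct$estimate), p = ct$p.value,
               n = length(x), defined = TRUE)
  }
  rbind(one(pad_table$true_age, pad_table$predicted_age, "true_vs_predicted"),
        one(pad_table$true_age, pad_table$pad, "true_vs_pad"))
}

#' Levene's test of variance equality
#'
#' ANOVA on absolute deviations from group centers: with
#' \eqn{Z_{ij} = |x_{ij} - c_i|},
#' \deqn{W = \frac{N-g}{g-1}\cdot
#'   \frac{\sum_i n_i(\bar Z_i - \bar Z)^2}{\sum_i\sum_j (Z_{ij}-\bar Z_i)^2}}
#' referred to the upper tail of F(g-1, N-g). Mean centering is the classic
#' Levene test; median centering gives the Brown-Forsythe variant.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 values).
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return list of class \code{variance_test}: labels, sizes, group mean
#'   absolute deviations, W, df = (g-1, N-g), p. Fully degenerate data
#'   (all deviations zero) yields W = 0, p = 1.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  cfun <- if (center == "mean") mean else median
  z <- lapply(groups, function(x) abs(x - cfun(x)))
  ni <- vapply(z, length, 1L)
  g <- length(z)
  N <- sum(ni)
  zbar_i <- vapply(z, mean, 1)
  zbar <- sum(unlist(z)) / N
  num <- sum(ni * (zbar_i - zbar)^2)
  den <- sum(vapply(seq_len(g), function(i) sum((z[[i]] - zbar_i[i])^2), 1))
  if (den <= 0) {
    w <- if (num <= 0) 0 else Inf
  } else {
    w <- ((N - g) / (g - 1)) * num / den
  }
  p <- if (is.infinite(w)) 0 else pf(w, g - 1, N - g, lower.tail = FALSE)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(g))
  structure(list(labels = labels, n = ni, group_mad = zbar_i,
                 W = w, df = c(g - 1L, N - g), p = p, center = center),
            class = "variance_test")
}

#' Pairwise Levene tests across diagnosis and age partition
#'
#' Tests the 6 unordered pairs among \{GAD<25, HC<25, GAD>25, HC>25\} plus
#' the overall GAD-vs-HC comparison on PAD.
#'
#' @param pad_table a \code{pad_table}.
#' @param center passed to \code{\link{levene_test}}.
#' @return data frame: group1, group2, n1, n2, W, df1, df2, p, skipped.
#' @export
pairwise_variance_tests <- function(pad_table, center = "mean") {
  cell <- interaction(pad_table$diagnosis, pad_table$age_partition, sep = " ")
  lv <- c("GAD under25", "HC under25", "GAD over25", "HC over25")
  nice <- c("GAD < 25", "HC < 25", "GAD > 25", "HC > 25")
  cells <- lapply(lv, function(l) pad_table$pad[cell == l])
  names(cells) <- nice
  pairs <- utils::combn(4, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- cells[[i1]]; b <- cells[[i2]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(group1 = nice[i1], group2 = nice[i2],
                        n1 = length(a), n2 = length(b), W = NA_real_,
                        df1 = NA_integer_, df2 = NA_integer_, p = NA_real_,
                        skipped = TRUE))
    lt <- levene_test(list(a, b), center = center)
    data.frame(group1 = nice[i1], group2 = nice[i2], n1 = length(a),
               n2 = length(b), W = lt$W, df1 = lt$df[1], df2 = lt$df[2],
               p = lt$p, skipped = FALSE)
  })
  gad <- pad_table$pad[pad_table$diagnosis == "GAD"]
  hc <- pad_table$pad[pad_table$diagnosis == "HC"]
  overall <- if (length(gad) >= 2 && length(hc) >= 2) {
    lt <- levene_test(list(gad, hc), center = center)
    data.frame(group1 = "GAD", group2 = "HC", n1 = length(gad),
               n2 = length(hc), W = lt$W, df1 = lt$df[1], df2 = lt$df[2],
               p = lt$p, skipped = FALSE)
  } else {
    data.frame(group1 = "GAD", group2 = "HC", n1 = length(gad),
               n2 = length(hc), W = NA_real_, df1 = NA_integer_,
               df2 = NA_integer_, p = NA_real_, skipped = TRUE)
  }
  rbind(do.call(rbind, rows), overall)
}

#' Per-site Welch t-tests of age matching between diagnostic groups
#'
#' For each site (and overall), a Welch unequal-variance two-sample t-test
#' of mean age, GAD vs HC. Sites where either group has fewer than 2
#' subjects are flagged N/A rather than tested.
#'
#' @param participants data frame with age, site, dx.
#' @return data frame: site, n_gad, n_hc, mean_age_gad, mean_age_hc, t, p,
#'   na_flag.
#' @export
site_age_matching <- function(participants) {
  one <- function(label, dat) {
    a <- dat$age[dat$dx == "GAD"]
    b <- dat$age[dat$dx == "HC"]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(site = label, n_gad = length(a), n_hc = length(b),
                        mean_age_gad = if (length(a)) mean(a) else NA_real_,
                        mean_age_hc = if (length(b)) mean(b) else NA_real_,
                        t = NA_real_, p = NA_real_, na_flag = TRUE))
    tt <- t.test(a, b)
    data.frame(site = label, n_gad = length(a), n_hc = length(b),
               mean_age_gad = mean(a), mean_age_hc = mean(b),
               t = unname(tt$statistic), p = tt$p.value, na_flag = FALSE)
  }
  sites <- sort(unique(participants$site))
  rows <- lapply(sites, function(s) one(s, participants[participants$site == s, ]))
  rbind(do.call(rbind, rows), one("overall", participants))
}
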