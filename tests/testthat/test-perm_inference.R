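two_site_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(diagnosis = rep(c("HC", "GAD"), n / 2),
             site = rep(c("s1", "s2"), each = n / 2),
             age = runif(n, 8, 80),
             sex = sample(c("F", "M"), n, TRUE),
             med = rbinom(n, 1, 0.3),
             comorbid = rbinom(n, 1, 0.2))
}

test_that("designs have the documented column structure", {
  tbl <- two_site_table()
  d1 <- build_design(tbl, model_id = 1)
  expect_equal(ncol(d1$X), 3)  # 2 site intercepts + dx
  expect_setequal(d1$labels, c("intercept_s1", "intercept_s2", "dx"))
  expect_equal(sum(d1$contrast), 1)
  expect_equal(d1$labels[d1$contrast == 1], "dx")
  d2 <- build_design(tbl, model_id = 2)
  expect_equal(ncol(d2$X), 11)  # 2 intercepts + 2x4 site slopes + dx
  d3 <- build_design(tbl, model_id = 3)
  expect_equal(ncol(d3$X), 12)
  expect_equal(d3$labels[d3$contrast == 1], "dx_x_age")
  # age is mean-centered within site
  agec <- d3$X[, "age_s1"]
  expect_equal(sum(agec[tbl$site == "s1"]), 0, tolerance = 1e-9)
})

test_that("degenerate designs warn or error as specified", {
  tbl <- two_site_table()
  one_site <- tbl
  one_site$site <- "only"
  expect_warning(build_design(one_site, model_id = 1), "single site")
  hc_only <- tbl
  hc_only$diagnosis <- "HC"
  expect_error(build_design(hc_only, model_id = 1), "single diagnosis")
  expect_error(build_design(tbl, model_id = 2,
                            covariates = c("age", "nope")), "nope")
  # a covariate constant everywhere duplicates the intercepts -> dropped
  tbl$med <- 1L
  expect_warning(build_design(tbl, model_id = 2), "rank-deficient")
})

test_that("the variance-group statistic reduces to classical and Welch t", {
  set.seed(33)
  g <- rep(0:1, c(14, 11))
  y <- rnorm(25) + g * 0.8
  X <- cbind(intercept = 1, dx = g)
  # one variance group: classical pooled t
  st1 <- glm_statistic(X, y, c(0, 1), vg = NULL)
  tt1 <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(st1$stat, unname(tt1$statistic), tolerance = 1e-10)
  # two variance groups: Welch t
  st2 <- glm_statistic(X, y, c(0, 1), vg = g)
  tt2 <- t.test(y[g == 1], y[g == 0])
  expect_equal(st2$stat, unname(tt2$statistic), tolerance = 1e-10)
  # response orthogonal to the tested column given the nuisance fit
  y0 <- rep(c(-1, 1), length.out = 14)
  y0 <- c(y0, rep(c(-1, 1), length.out = 11))
  y0 <- y0 - ave(y0, g)  # zero mean within each group
  expect_equal(glm_statistic(X, y0 + 5, c(0, 1))$stat, 0, tolerance = 1e-10)
})

test_that("sign-flip p-values agree exactly with an exhaustive oracle", {
  set.seed(71)
  for (case in 1:3) {
    n <- 8
    g <- rep(0:1, each = n / 2)
    X <- cbind(intercept = 1, dx = g)
    y <- rnorm(n) + case * 0.5 * g
    pr <- sign_flip_test(X, y, c(0, 1), vg = NULL,
                         perm_config(n_perm = 2^n, seed = 1))
    expect_true(pr$enumerated)
    # independent oracle: demean (nuisance = intercept), flip, pooled t
    fit <- mean(y)
    e <- y - fit
    tstat <- function(yy) {
      unname(t.test(yy[g == 1], yy[g == 0], var.equal = TRUE)$statistic)
    }
    obs <- tstat(y)
    cnt <- 0
    for (i in 0:(2^n - 1)) {
      s <- 1 - 2 * as.integer(intToBits(i))[1:n]
      if (abs(tstat(fit + s * e)) >= abs(obs) - 1e-8) cnt <- cnt + 1
    }
    expect_equal(pr$p, cnt / 2^n, tolerance = 1e-12)
  }
})

test_that("sampled sign-flip p-values use the +1 counting rule and bounds", {
  set.seed(10)
  n <- 50
  g <- rep(0:1, each = 25)
  X <- cbind(intercept = 1, dx = g)
  y <- rnorm(n) + 3 * g  # huge effect: no permutation should beat it
  pr <- sign_flip_test(X, y, c(0, 1), vg = g,
                       perm_config(n_perm = 99, seed = 7))
  expect_false(pr$enumerated)
  expect_equal(pr$p, 1 / 100)  # (1 + 0) / (99 + 1)
  expect_gte(pr$p, 1 / (pr$n_perm + 1))
  # determinism under the seed
  pr2 <- sign_flip_test(X, y, c(0, 1), vg = g,
                        perm_config(n_perm = 99, seed = 7))
  expect_identical(pr$perm_stats, pr2$perm_stats)
  # invariance to positive rescaling of the response
  pr3 <- sign_flip_test(X, y * 4.2, c(0, 1), vg = g,
                        perm_config(n_perm = 99, seed = 7))
  expect_equal(pr3$p, pr$p, tolerance = 1e-12)
})

test_that("max-statistic FWER adjustment is coherent", {
  set.seed(20)
  n <- 30
  g <- rep(0:1, each = 15)
  X <- cbind(intercept = 1, dx = g, cov = rnorm(n))
  y <- rnorm(n)
  cfg <- perm_config(n_perm = 199, seed = 5)
  r_dx <- sign_flip_test(X, y, c(0, 1, 0), vg = g, cfg)
  r_cov <- sign_flip_test(X, y, c(0, 0, 1), vg = g, cfg)
  # single contrast: adjusted equals unadjusted
  single <- fwer_adjust(list(dx = r_dx))
  expect_equal(single$p_fwer, single$p_unadj)
  # duplicated contrast: equal adjusted p's, both >= unadjusted
  dup <- fwer_adjust(list(a = r_dx, b = r_dx))
  expect_equal(dup$p_fwer[1], dup$p_fwer[2])
  both <- fwer_adjust(list(dx = r_dx, cov = r_cov))
  expect_true(all(both$p_fwer >= both$p_unadj - 1e-12))
  # mismatched schedules refuse to combine
  r_other <- sign_flip_test(X, y, c(0, 0, 1), vg = g,
                            perm_config(n_perm = 199, seed = 6))
  expect_error(fwer_adjust(list(r_dx, r_other)), "mismatched")
})

test_that("run_pad_glms returns the three tested contrasts with FWER", {
  set.seed(61)
  n <- 80
  tbl <- two_site_table(n, seed = 61)
  part <- data.frame(subject_id = sprintf("R%03d", 1:n), age = tbl$age,
                     sex = tbl$sex, site = tbl$site, dx = tbl$diagnosis,
                     med = tbl$med, comorbid = tbl$comorbid)
  preds <- data.frame(subject_id = part$subject_id,
                      pred_ensemble = part$age + rnorm(n, sd = 4))
  pad <- compute_pad(preds, part)
  out <- run_pad_glms(pad, perm_config(n_perm = 99, seed = 2))
  expect_equal(nrow(out$table), 3)
  expect_true(all(out$table$p_fwer >= out$table$p_unadj - 1e-12))
  expect_true(all(grepl("dx", out$table$contrast)))
})

test_that("null diagnosis p-values are uniform and a mean shift is detected", {
  # uniformity: scalar PAD surrogates with zero effect through the full
  # covariate design (model 2), KS test at alpha = .01
  ps <- vapply(1:300, function(r) {
    tbl <- two_site_table(60, seed = 7000 + r)
    set.seed(8000 + r)
    y <- rnorm(60)
    ds <- suppressWarnings(build_design(tbl, model_id = 2))
    sign_flip_test(ds$X, y, ds$contrast, vg = tbl$diagnosis,
                   perm_config(n_perm = 250, seed = 8500 + r))$p
  }, 1)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # power: a 0.5 SD mean PAD shift in the clinical group is detected by the
  # diagnosis-only design in the majority of replicates at n = 600
  rej <- 0
  for (r in 1:11) {
    tbl <- two_site_table(600, seed = 8600 + r)
    set.seed(8700 + r)
    y <- rnorm(600) + 0.5 * (tbl$diagnosis == "GAD")
    ds <- build_design(tbl, model_id = 1)
    p <- sign_flip_test(ds$X, y, ds$contrast, vg = tbl$diagnosis,
                        perm_config(n_perm = 250, seed = 8800 + r))$p
    if (p < 0.05) rej <- rej + 1
  }
  expect_gte(rej, 6)
})
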