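make_participants <- function(pred, age, dx = NULL, site = "s1") {
  n <- length(age)
  data.frame(subject_id = sprintf("P%03d", seq_len(n)), age = age,
             sex = rep(c("F", "M"), length.out = n), site = site,
             dx = if (is.null(dx)) rep("HC", n) else dx,
             med = 0L, comorbid = 0L)
}

test_that("PAD is predicted minus true with the age-25 boundary rule", {
  part <- make_participants(NULL, age = c(25, 24.9, 25.0, 60))
  preds <- data.frame(subject_id = part$subject_id,
                      pred_ensemble = c(30, 24.9, 20, 60))
  pad <- compute_pad(preds, part)
  expect_equal(pad$pad, c(5, 0, -5, 0))
  expect_equal(pad$age_partition, c("over25", "under25", "over25", "over25"))
  expect_true(all(pad$pad == pad$predicted_age - pad$true_age))
  # id mismatch errors
  preds$subject_id[1] <- "NOPE"
  expect_error(compute_pad(preds, part), "missing from participants")
})

test_that("group metrics match hand arithmetic and satisfy Jensen", {
  part <- make_participants(NULL, age = c(10, 10, 50, 50),
                            dx = c("HC", "HC", "GAD", "GAD"))
  preds <- data.frame(subject_id = part$subject_id,
                      pred_ensemble = c(11, 9, 53, 53))
  pad <- compute_pad(preds, part)
  gm <- group_metrics(pad, "diagnosis")
  hc <- gm[gm$group == "HC", ]
  expect_equal(hc$mae, 1)
  expect_equal(hc$mse, 1)
  expect_equal(hc$mean_pad, 0)
  expect_equal(hc$sd_pad, sqrt(2))
  expect_equal(hc$var_pad, hc$sd_pad^2)
  gad <- gm[gm$group == "GAD", ]
  expect_equal(gad$mae, 3)
  expect_equal(gad$sd_pad, 0)
  # MSE >= MAE^2 on every group of a random table
  set.seed(31)
  part2 <- make_participants(NULL, age = runif(60, 8, 80),
                             dx = sample(c("HC", "GAD"), 60, TRUE))
  preds2 <- data.frame(subject_id = part2$subject_id,
                       pred_ensemble = runif(60, 8, 80))
  gm2 <- group_metrics(compute_pad(preds2, part2), "diagnosis")
  expect_true(all(gm2$mse >= gm2$mae^2 - 1e-12))
})

test_that("correlations handle exact, negative and degenerate cases", {
  age <- c(10, 20, 30, 40, 55)
  part <- make_participants(NULL, age = age)
  exact <- compute_pad(data.frame(subject_id = part$subject_id,
                                  pred_ensemble = age), part)
  ce <- correlations(exact)
  expect_equal(ce$r[ce$comparison == "true_vs_predicted"], 1)
  expect_false(ce$defined[ce$comparison == "true_vs_pad"])  # pad constant 0
  neg <- compute_pad(data.frame(subject_id = part$subject_id,
                                pred_ensemble = -age + 90), part)
  cn <- correlations(neg)
  expect_equal(cn$r[cn$comparison == "true_vs_predicted"], -1)
  # independent noise: r(true, pad) near zero at large n
  set.seed(88)
  agen <- runif(4000, 8, 80)
  partn <- make_participants(NULL, age = agen)
  noisy <- compute_pad(data.frame(subject_id = partn$subject_id,
                                  pred_ensemble = agen + rnorm(4000)), partn)
  cr <- correlations(noisy)
  expect_lt(abs(cr$r[cr$comparison == "true_vs_pad"]), 0.05)
})

test_that("Levene W reproduces the hand-derived value and degeneracies", {
  lt <- levene_test(list(A = c(1, 2, 3), B = c(0, 2, 4)), center = "mean")
  expect_equal(lt$W, 0.8, tolerance = 1e-12)
  expect_equal(lt$df, c(1L, 4L))
  # two identical copies -> W = 0, p = 1
  x <- c(1, 3, 7, 9)
  lt0 <- levene_test(list(x, x))
  expect_equal(lt0$W, 0)
  expect_equal(lt0$p, 1)
  expect_error(levene_test(list(c(1, 2))), "at least 2 groups")
  expect_error(levene_test(list(c(1, 2), 3)), "at least 2 values")
})

test_that("Levene agrees with the car implementation on random data", {
  skip_if_not_installed("car")
  set.seed(12)
  vals <- c(rnorm(40, sd = 1), rnorm(30, sd = 2.2), rnorm(25, sd = 0.6))
  g <- factor(rep(1:3, c(40, 30, 25)))
  for (ctr in c("mean", "median")) {
    ours <- levene_test(split(vals, g), center = ctr)
    ref <- car::leveneTest(vals, g, center = get(ctr))
    expect_equal(ours$W, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(ours$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("Levene is invariant to group shifts and scales as documented", {
  set.seed(4)
  a <- rnorm(30); b <- rnorm(25, sd = 1.7)
  w0 <- levene_test(list(a, b))$W
  # adding a group-specific constant leaves W unchanged
  expect_equal(levene_test(list(a + 5, b - 11))$W, w0, tolerance = 1e-10)
  # common positive rescaling leaves W unchanged
  expect_equal(levene_test(list(a * 2.5, b * 2.5))$W, w0, tolerance = 1e-10)
})

test_that("two-group mean-centered W equals the squared pooled t on deviations", {
  set.seed(9)
  a <- rnorm(20); b <- rnorm(35, sd = 2)
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  tt <- t.test(za, zb, var.equal = TRUE)
  expect_equal(levene_test(list(a, b))$W, unname(tt$statistic)^2,
               tolerance = 1e-10)
})

test_that("Levene detects a doubled SD with high power at n = 200", {
  set.seed(2024)
  rej <- 0
  for (r in 1:100) {
    if (levene_test(list(rnorm(200, sd = 1), rnorm(200, sd = 2)))$p < 0.05)
      rej <- rej + 1
  }
  expect_gte(rej, 95)
})

test_that("pairwise variance tests cover the 6 pairs plus the overall test", {
  set.seed(55)
  n <- 120
  age <- runif(n, 8, 80)
  dx <- rep(c("HC", "GAD"), n / 2)
  part <- make_participants(NULL, age = age, dx = dx)
  preds <- data.frame(subject_id = part$subject_id,
                      pred_ensemble = age + rnorm(n, sd = ifelse(dx == "GAD",
                                                                 6, 3)))
  pad <- compute_pad(preds, part)
  tab <- pairwise_variance_tests(pad)
  expect_equal(nrow(tab), 7)
  expect_false(any(tab$skipped))
  # overall row detects the inflated clinical spread here
  expect_lt(tab$p[tab$group1 == "GAD" & tab$group2 == "HC"], 0.05)
  # empty cell: no GAD under 25 -> pairs touching it are skipped, not errors
  pad25 <- pad[!(pad$diagnosis == "GAD" & pad$age_partition == "under25"), ]
  tab2 <- pairwise_variance_tests(pad25)
  expect_true(any(tab2$skipped))
  expect_equal(nrow(tab2), 7)
})

test_that("site age matching runs Welch tests with N/A flags for empty groups", {
  part <- make_participants(NULL, age = c(10, 10.1, 9.9, 20, 20.1, 19.9),
                            dx = rep(c("GAD", "HC"), each = 3))
  res <- site_age_matching(part)
  row <- res[res$site == "s1", ]
  expect_false(row$na_flag)
  expect_lt(row$p, 0.05)
  # identical age lists in both groups -> t = 0, p = 1
  part2 <- make_participants(NULL, age = rep(c(10, 20, 30), 2),
                             dx = rep(c("GAD", "HC"), each = 3))
  res2 <- site_age_matching(part2)
  expect_equal(res2$t[res2$site == "s1"], 0)
  expect_equal(res2$p[res2$site == "s1"], 1)
  # a site with no controls is flagged N/A rather than tested
  part3 <- rbind(part, make_participants(NULL, age = c(30, 40, 35),
                                         dx = rep("GAD", 3), site = "s2"))
  part3$subject_id <- sprintf("Q%03d", seq_len(nrow(part3)))
  res3 <- site_age_matching(part3)
  expect_true(res3$na_flag[res3$site == "s2"])
})
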