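test_that("sample_cohort honors counts, determinism, and field ranges", {
  spec <- cohort_spec(n_control = 10, n_clinical = 5, n_sites = 3, seed = 1)
  coh <- sample_cohort(spec)
  expect_equal(nrow(coh), 15)
  expect_equal(sum(coh$dx == "GAD"), 5)
  expect_true(all(coh$age > 0))
  expect_true(all(coh$sex %in% c("F", "M")))
  expect_equal(anyDuplicated(coh$subject_id), 0)
  expect_true(all(coh$med[coh$dx == "HC"] == 0))
  # identical spec + seed reproduces the cohort exactly
  expect_identical(coh, sample_cohort(spec))
  # different seed gives different draws
  coh2 <- sample_cohort(cohort_spec(n_control = 10, n_clinical = 5,
                                    n_sites = 3, seed = 2))
  expect_false(identical(coh$age, coh2$age))
  # round-robin sites are balanced to within one subject
  tab <- table(coh$site)
  expect_lte(max(tab) - min(tab), 1)
})

test_that("uniform ages have the closed-form mean within 3 standard errors", {
  spec <- cohort_spec(n_control = 400, n_clinical = 200,
                      age_range = c(8, 80), age_distribution = "uniform",
                      seed = 7)
  coh <- sample_cohort(spec)
  se <- (80 - 8) / sqrt(12) / sqrt(600)
  expect_lt(abs(mean(coh$age) - 44), 3 * se)
})

test_that("invalid cohort specs name the offending field", {
  expect_error(cohort_spec(10, 5, age_range = c(50, 20)), "age_range")
  expect_error(cohort_spec(10, 5, variance_inflation = 0.5),
               "variance_inflation")
  expect_error(cohort_spec(-1, 5), "n_control")
  expect_error(cohort_spec(10, 5, n_sites = 0), "n_sites")
})

test_that("phantom geometry is linear in age and monotone before noise", {
  fx <- small_cohort_fixture()
  pp <- fx$params
  # stated linear form: base 3.0, slope 0.05 at age 80 -> 7.0 voxels
  pbig <- phantom_params(grid_dims = c(28L, 32L, 28L),
                         brain_radii = c(12, 14, 12),
                         ventricle_base_radius = 3,
                         ventricle_age_slope = 0.05,
                         gm_base_thickness = 5, gm_age_slope = 0.03,
                         age_range = c(8, 80))
  expect_equal(ventricle_radius(pbig, 80), 7.0)
  ages <- seq(pp$age_range[1], pp$age_range[2], length.out = 9)
  expect_true(all(diff(ventricle_radius(pp, ages)) > 0))
  expect_true(all(diff(gm_thickness(pp, ages)) < 0))
})

test_that("phantom construction rejects geometry that escapes the envelope", {
  expect_error(phantom_params(ventricle_base_radius = 5,
                              ventricle_age_slope = 0.2), "envelope")
  expect_error(phantom_params(gm_base_thickness = 2, gm_age_slope = 0.05),
               "vanishes")
})

test_that("midpoint-age noise-free phantom has a constant baseline Jacobian", {
  fx <- small_cohort_fixture()
  rec <- fx$cohort[1, ]
  rec$age <- mean(fx$params$age_range)
  vs <- render_phantom(rec, fx$params, group_noise_sd = 0, seed = 5L)
  expect_true(all(vs$channels$jac == 1))
  # away from the midpoint the Jacobian deviates
  rec$age <- fx$params$age_range[2]
  vs2 <- render_phantom(rec, fx$params, group_noise_sd = 0, seed = 5L)
  expect_gt(max(abs(vs2$channels$jac - 1)), 0)
})

test_that("rendering is deterministic and validates the age range", {
  fx <- small_cohort_fixture()
  rec <- fx$cohort[2, ]
  v1 <- render_phantom(rec, fx$params, group_noise_sd = 0.2)
  v2 <- render_phantom(rec, fx$params, group_noise_sd = 0.2)
  expect_identical(v1$channels, v2$channels)
  expect_true(all(vapply(v1$channels, function(a) all(is.finite(a)), TRUE)))
  rec$age <- fx$params$age_range[2] + 10
  expect_error(render_phantom(rec, fx$params, 0.2), "outside validated range")
})

test_that("morphological variance inflation appears in rendered geometry", {
  # residual spread of total gray-matter volume (an age-regressed morphology
  # summary) grows with the inflation factor
  pp <- small_cohort_fixture()$params
  gm_summary <- function(noise_sd, seeds, age = 40) {
    vapply(seeds, function(s) {
      rec <- data.frame(subject_id = "X", age = age, seed = s)
      sum(render_phantom(rec, pp, group_noise_sd = noise_sd)$channels$gm)
    }, 1)
  }
  seeds <- 1:40
  s1 <- sd(gm_summary(0.15, seeds))
  s2 <- sd(gm_summary(0.45, seeds))
  expect_gt(s2, s1 * 1.5)
})

test_that("write_cohort emits NIfTI files that round-trip plus a tsv", {
  fx <- small_cohort_fixture()
  sub <- fx$cohort[1:3, ]
  class(sub) <- class(fx$cohort)
  attr(sub, "spec") <- attr(fx$cohort, "spec")
  attr(sub, "site_offsets") <- attr(fx$cohort, "site_offsets")
  out <- withr::local_tempdir()
  man <- write_cohort(sub, fx$volumes[1:3], out)
  expect_equal(nrow(man$volumes), 12)  # 4 channels x 3 subjects
  expect_true(all(file.exists(man$volumes$path)))
  tsv <- read.delim(man$participants)
  expect_equal(nrow(tsv), 3)
  expect_equal(names(tsv),
               c("subject_id", "age", "sex", "site", "dx", "med", "comorbid"))
  # round-trip: written channel equals the rendered array
  vs <- load_volume_set(
    setNames(man$volumes$path[man$volumes$subject_id == sub$subject_id[1]],
             man$volumes$channel[man$volumes$subject_id == sub$subject_id[1]]),
    expected_dims = fx$params$grid_dims, subject_id = sub$subject_id[1])
  expect_equal(vs$channels$gm, fx$volumes[[1]]$channels$gm,
               tolerance = 1e-6)
  expect_error(write_cohort(sub, fx$volumes[1:2], out), "one volume set")
})
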