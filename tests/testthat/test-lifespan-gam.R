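make_design <- function(n = 120, seed = 1, ssfun = function(age, sex, motion)
                        rnorm(length(age))) {
  set.seed(seed)
  age <- runif(n, 18, 88)
  sex <- rbinom(n, 1, 0.5)
  motion <- rlnorm(n, -2, 0.5)
  data.frame(ss = ssfun(age, sex, motion), age = age, sex = sex,
             motion = motion)
}

test_that("a noiseless linear age signal is reproduced on the grid", {
  d <- make_design(80, seed = 2,
                   ssfun = function(age, sex, motion) 2 - 0.01 * age)
  # REML step warnings are expected on exactly-noiseless data
  full <- suppressWarnings(fit_full_gam(d))
  grid <- seq(20, 85, length.out = 66)
  expect_lt(max(abs(gam_trajectory(full, grid) - (2 - 0.01 * grid))), 1e-6)
})

test_that("the reduced model is the covariates-only linear fit", {
  d <- make_design(100, seed = 3,
                   ssfun = function(age, sex, motion) 3 * motion)
  red <- suppressWarnings(fit_reduced_model(d))
  expect_equal(1 - sum(residuals(red)^2) / sum((d$ss - mean(d$ss))^2), 1,
               tolerance = 1e-9)
  # age-only signal leaves the reduced model near zero explained variance
  d2 <- make_design(300, seed = 4,
                    ssfun = function(age, sex, motion)
                      0.05 * age + rnorm(length(age), 0, 0.1))
  red2 <- fit_reduced_model(d2)
  tst <- age_effect_test(fit_full_gam(d2), red2)
  expect_lt(tst$r2_reduced, 0.05)
  expect_gt(tst$r2_full, 0.9)
})

test_that("a planted quadratic age effect is tracked by the smooth", {
  truthfun <- function(age) 0.002 * (age - 50)^2
  d <- make_design(455, seed = 5,
                   ssfun = function(age, sex, motion)
                     truthfun(age) + rnorm(length(age), 0, 0.3))
  full <- fit_full_gam(d)
  grid <- seq(20, 85, length.out = 66)
  expect_gt(cor(gam_trajectory(full, grid), truthfun(grid)), 0.95)
})

test_that("full model never explains less than the reduced model", {
  for (seed in 1:15) {
    d <- make_design(90, seed = seed)
    tst <- age_effect_test(fit_full_gam(d), fit_reduced_model(d))
    expect_gte(tst$delta_r2, -1e-9)
    expect_gte(tst$p_age, 0)
    expect_lte(tst$p_age, 1)
  }
})

test_that("design validation names the offending column", {
  d <- make_design(60, seed = 6)
  d$motion <- 1
  expect_error(fit_full_gam(d), "motion")
  expect_error(fit_full_gam(make_design(30)), "50")
  d2 <- make_design(60, seed = 7)
  d2$ss[3] <- NA
  expect_error(fit_full_gam(d2), "missing")
})

test_that("mismatched model rows are rejected", {
  d1 <- make_design(60, seed = 8)
  d2 <- make_design(60, seed = 9)
  expect_error(age_effect_test(fit_full_gam(d1), fit_reduced_model(d2)),
               "identical rows")
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  out <- fdr_correct(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$q, rep(0.04, 4), tolerance = 1e-12)
  expect_true(all(out$significant))
  one <- fdr_correct(0.03)
  expect_equal(one$q, 0.03)
  all1 <- fdr_correct(rep(1, 6))
  expect_true(all(all1$q == 1) && !any(all1$significant))
  p <- runif(50)
  adj <- fdr_correct(p)
  expect_true(all(adj$q >= adj$p))
  expect_error(fdr_correct(c(0.2, 1.4)), "0, 1")
})

test_that("trajectory matrices select, center and validate", {
  m <- matrix(rnorm(30), nrow = 5,
              dimnames = list(letters[1:5], NULL))
  out <- trajectory_curves(m, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(rownames(out), c("a", "c"))
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  raw <- trajectory_curves(m, center = FALSE)
  expect_identical(raw, m)
  one <- trajectory_curves(m, c(TRUE, rep(FALSE, 4)))
  expect_identical(nrow(one), 1L)
  expect_error(trajectory_curves(m, rep(FALSE, 5)), "selected")
})

test_that("parcel-level tables assemble fits, FDR and trajectories", {
  set.seed(10)
  n_sub <- 80
  subjects <- data.frame(subject_id = sprintf("s%02d", 1:n_sub),
                         age = runif(n_sub, 18, 88),
                         sex = sample(c("F", "M"), n_sub, TRUE),
                         head_motion = rlnorm(n_sub, -2, 0.5))
  ss <- rbind(5 - 0.03 * subjects$age + rnorm(n_sub, 0, 0.5),
              matrix(rnorm(3 * n_sub), nrow = 3))
  rownames(ss) <- c("10", "11", "12", "13")
  res <- parcel_gam_table(ss, subjects, exclude = "13")
  expect_identical(res$table$parcel_id, c("10", "11", "12"))
  expect_identical(ncol(res$trajectories), 66L)
  expect_lt(res$table$p_age[1], 0.001)
  expect_true(all(res$table$q >= res$table$p_age - 1e-15))
})
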