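# Penalized-likelihood LMS curve estimation.

test_that("deviance is non-increasing over outer cycles and the fit converges", {
  coh <- make_ref_cohort("boys", n_per_age = 200, seed = 11)
  m <- fit_lms(coh)
  expect_true(m$fit$converged)
  expect_true(all(diff(m$fit$deviance_trace) <= 1e-6))
})

test_that("M(13) is recovered within 2% on a reference-simulated cohort", {
  coh <- make_ref_cohort("boys", n_per_age = 300, seed = 2)
  m <- fit_lms(coh)
  expect_lt(abs(predict_lms(m, 13)$mu - 25.77) / 25.77, 0.02)
})

test_that("fitted M(t) is non-decreasing over the age domain", {
  for (sex in c("boys", "girls")) {
    m <- fit_lms(make_ref_cohort(sex, n_per_age = 300, seed = 3))
    expect_true(all(diff(predict_lms(m, seq(12, 16, 0.25))$mu) >= 0))
  }
})

test_that("lambda frozen at 1 with constant curves reproduces Gaussian MLEs", {
  set.seed(9)
  y <- rnorm(500, 30, 4)
  coh <- data.frame(age = rep(14, 500), hgs_abs_kg = y)
  m <- suppressWarnings(
    fit_lms(coh, fit_config(1, 1, 1, fix_lambda = 1)))
  mhat <- mean(y); shat <- sqrt(mean((y - mhat)^2))
  pr <- predict_lms(m, 14)
  expect_equal(pr$mu, mhat, tolerance = 1e-4)
  expect_equal(pr$sigma, shat / mhat, tolerance = 1e-4)
  expect_identical(pr$lambda, 1)
})

test_that("constant lambda is estimated near 1 on Gaussian-simulated data", {
  coh <- make_const_cohort(lambda = 1, mu = 25, sigma = 0.15,
                           n_per_age = 300, seed = 13)
  m <- fit_lms(coh, fit_config(1, 2, 1))
  expect_lt(abs(predict_lms(m, 14)$lambda - 1), 0.3)
})

test_that("constant-parameter simulation is recovered flat at every age", {
  coh <- make_const_cohort(lambda = 0.5, mu = 20, sigma = 0.2,
                           n_per_age = 400, seed = 21)
  m <- fit_lms(coh)
  pr <- predict_lms(m, 12:16)
  expect_lt(max(abs(pr$mu - 20) / 20), 0.03)
  expect_lt(max(pr$mu) - min(pr$mu), 0.04 * 20)
})

test_that("degenerate cohorts are handled: zero variance and single age", {
  coh <- data.frame(sex = "boys", age = rep(12:16, each = 40),
                    hgs_abs_kg = 20.0)
  m <- suppressWarnings(fit_lms(coh, fit_config(1, 1, 1)))
  pr <- predict_lms(m, 14)
  expect_equal(pr$mu, 20.0, tolerance = 1e-3)
  expect_lt(pr$sigma, 1e-3)  # driven to the lower bound

  set.seed(6)
  one_age <- data.frame(age = rep(13, 200),
                        hgs_abs_kg = rlnorm(200, log(20), 0.2))
  expect_warning(m1 <- fit_lms(one_age), "single age")
  expect_true(all(m1$edf == 1))
})

test_that("extrapolation and small strata trigger warnings, not errors", {
  coh <- make_ref_cohort("girls", n_per_age = 60, seed = 5)
  m <- fit_lms(coh)
  expect_warning(predict_lms(m, 18), "extrapolating")
  small <- coh[c(1:20, 61:90, 121:160, 181:230, 241:290), ]
  expect_warning(fit_lms(small), "fewer than 30")
})

test_that("select_edf picks parsimonious candidates and breaks ties by order", {
  coh <- make_const_cohort(lambda = 1, mu = 22, sigma = 0.18, n_per_age = 150,
                           seed = 31)
  # M(t) linear in age
  coh$hgs_abs_kg <- coh$hgs_abs_kg * (1 + 0.05 * (coh$age - 14))
  grid <- data.frame(edf_lambda = 1, edf_mu = 2:5, edf_sigma = 1)
  sel <- select_edf(coh, grid)
  expect_lte(sel$edf[["mu"]], 3)

  single <- list(fit_config(2, 3, 2))
  expect_identical(select_edf(coh, single)$edf, single[[1]]$edf)
  twin <- list(fit_config(1, 2, 1), fit_config(1, 2, 1))
  picked <- select_edf(coh, twin)
  expect_identical(attr(picked, "scores")$bic[1],
                   min(attr(picked, "scores")$bic))
})

test_that("model serialization round-trips to 1e-12", {
  m <- fit_lms(make_ref_cohort("girls", n_per_age = 100, seed = 8))
  f <- tempfile(fileext = ".txt")
  write_lms_model(m, f)
  m2 <- read_lms_model(f)
  expect_equal(unlist(m2$coef), unlist(m$coef), tolerance = 1e-12)
  ages <- seq(12, 16, by = 0.1)
  expect_equal(predict_lms(m2, ages), predict_lms(m, ages),
               tolerance = 1e-12)
  expect_identical(m2$sex, m$sex)
})

test_that("sex separation: fitted M(16) ratio matches the reference ratio", {
  coh <- generate_cohort(default_spec(), seed = 5)
  mb <- fit_lms(coh[coh$sex == "boys", ])
  mg <- fit_lms(coh[coh$sex == "girls", ])
  ratio <- predict_lms(mb, 16)$mu / predict_lms(mg, 16)$mu
  expect_equal(ratio, 35.47 / 20.18, tolerance = 0.05)
})
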