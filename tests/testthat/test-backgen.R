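# Back-generation cross-validation and MAPE scoring.

test_that("published validation rows and block averages are reproduced", {
  bg <- southpunjab_backgen()
  printed_rows <- list(
    boys = c(-0.03, 0.03, -0.02, 0.04, -0.05),
    girls = c(0.01, 0.04, 0.10, -0.05, -0.04))
  printed_avg <- c(boys = -0.007, girls = 0.012)
  for (s in c("boys", "girls")) {
    b <- bg[bg$sex == s, ]
    r <- backgen_test(setNames(b$actual, b$age), setNames(b$fitted, b$age))
    expect_equal(round(r$mape, 2), printed_rows[[s]])
    expect_equal(round(mean(r$mape), 3), unname(printed_avg[s]))
  }
})

test_that("sign and denominator conventions behave as documented", {
  # fitted > actual => negative row MAPE
  r <- backgen_test(c(`12` = 22.53), c(`12` = 23.20))
  expect_lt(r$mape, 0)
  # girls age 15: actual 18.16 fitted 19.10 -> -0.05 at 2 dp
  r2 <- backgen_test(c(`15` = 18.16), c(`15` = 19.10))
  expect_equal(round(r2$mape, 2), -0.05)
  # the actual-denominator variant differs on the girls block average
  bg <- subset(southpunjab_backgen(), sex == "girls")
  ra <- backgen_test(setNames(bg$actual, bg$age), setNames(bg$fitted, bg$age),
                     convention = "actual")
  rf <- backgen_test(setNames(bg$actual, bg$age), setNames(bg$fitted, bg$age))
  expect_false(isTRUE(all.equal(mean(ra$mape), mean(rf$mape))))
})

test_that("MAPE is scale invariant and zero for identical maps", {
  a <- c(`12` = 20, `13` = 25, `14` = 30)
  f <- c(`12` = 21, `13` = 24, `14` = 31)
  expect_equal(backgen_test(a, f)$mape, backgen_test(7 * a, 7 * f)$mape)
  r0 <- backgen_test(a, a)
  expect_identical(r0$mape, c(0, 0, 0))
  expect_identical(mape_interpret(mean(r0$mape)), "highly accurate")
})

test_that("mismatched age keys error", {
  expect_error(backgen_test(c(`12` = 20), c(`13` = 20)), "keys differ")
})

test_that("accuracy bands follow the interpretation scale with closed-left boundaries", {
  expect_identical(mape_interpret(-0.007), "highly accurate")
  expect_identical(mape_interpret(0.15), "good")
  expect_identical(mape_interpret(0.10), "good")
  expect_identical(mape_interpret(-0.2), "reasonable")
  expect_identical(mape_interpret(0.5), "reasonable")
  expect_identical(mape_interpret(0.51), "inaccurate")
})

test_that("stratified holdout is proportional, reproducible and warns on tiny strata", {
  coh <- generate_cohort(default_spec(), seed = 23)
  s1 <- stratified_holdout(coh, 0.2, seed = 7)
  tab <- table(s1$holdout$sex, s1$holdout$age)
  full <- table(coh$sex, coh$age)
  expect_true(all(abs(tab - 0.2 * full) <= 1))
  s2 <- stratified_holdout(coh, 0.2, seed = 7)
  expect_identical(s1$holdout_idx, s2$holdout_idx)
  s3 <- stratified_holdout(coh, 0.2, seed = 8)
  expect_false(identical(s1$holdout_idx, s3$holdout_idx))

  tiny <- data.frame(sex = "boys", age = rep(12, 11),
                     hgs_abs_kg = rlnorm(11, 3, 0.2))
  expect_warning(st <- stratified_holdout(tiny, 0.2, seed = 1), "10 records")
  expect_identical(nrow(st$holdout), 2L)  # 2.2 rounds half-up to 2
})

test_that("holdout fractions out of range and empty strata error", {
  coh <- generate_cohort(default_spec(), seed = 23)
  expect_error(stratified_holdout(coh, 1.2, seed = 1), "fraction")
  expect_error(stratified_holdout(coh, 0.2), "seed")
})

test_that("the end-to-end pipeline is reproducible and highly accurate on synthetic cohorts", {
  coh <- generate_cohort(default_spec(), seed = 29)
  vr <- run_backgeneration(coh, seed = 41)
  vr2 <- run_backgeneration(coh, seed = 41)
  expect_identical(vr$rows, vr2$rows)
  expect_true(all(abs(vr$average) < 0.05))
  expect_identical(unname(vr$band), c("highly accurate", "highly accurate"))
  # a different seed moves row MAPEs but not the qualitative band
  vr3 <- run_backgeneration(coh, seed = 43)
  expect_false(identical(vr$rows$boys$mape, vr3$rows$boys$mape))
  expect_identical(vr3$band, vr$band)
})

test_that("raw-median mode with the holdout equal to the full set gives zero MAPE", {
  coh <- generate_cohort(default_spec(), seed = 31)
  p50 <- function(dat) setNames(
    as.numeric(tapply(dat$hgs_abs_kg, dat$age, median)),
    sort(unique(dat$age)))
  boys <- coh[coh$sex == "boys", ]
  r <- backgen_test(p50(boys), p50(boys))
  expect_true(all(r$mape == 0))
})

test_that("validation report CSV carries metadata and the published layout", {
  coh <- generate_cohort(default_spec(), seed = 37)
  vr <- run_backgeneration(coh, seed = 2, medians = "raw")
  f <- tempfile(fileext = ".csv")
  write_validation_csv(vr, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# holdout_fraction: 0.2", lines)))
  expect_true(any(grepl("^# seed: 2", lines)))
  expect_identical(sum(grepl(",average,", lines)), 2L)
  body <- read.csv(f, comment.char = "#")
  expect_identical(nrow(body), 12L)
})
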