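# Health Benefit Zone construction, classification and population summaries.

ref <- southpunjab_reference()
hbz <- build_hbz_table(ref)

test_that("zone edges sit exactly on the designated reference percentiles", {
  r16 <- hbz[hbz$sex == "boys" & hbz$age == 16, ]
  expect_identical(r16$zone, hbz_zones())
  expect_identical(r16$lower[r16$zone == "Excellent"],
                   ref$P90[ref$sex == "boys" & ref$age == 16])
  g12 <- hbz[hbz$sex == "girls" & hbz$age == 12, ]
  expect_identical(g12$lower[g12$zone == "Medium"],
                   ref$P35[ref$sex == "girls" & ref$age == 12])
  expect_identical(g12$upper[g12$zone == "Medium"],
                   ref$P65[ref$sex == "girls" & ref$age == 12])
  # intervals tile (0, Inf): uppers chain into the next lowers
  for (a in 12:16) {
    r <- hbz[hbz$sex == "girls" & hbz$age == a, ]
    expect_identical(r$upper[2:4], r$lower[3:5])
    expect_identical(r$upper[5], Inf)
  }
})

test_that("formatted band strings reproduce the published cut-off table", {
  expect_identical(format_hbz_table(hbz), southpunjab_hbz_bands())
})

test_that("classification follows the closed-below/open-above convention", {
  expect_identical(classify_hgs(35.47, 16, "boys", hbz), "Medium")
  expect_identical(classify_hgs(19.87, 12, "girls", hbz), "Excellent")
  expect_identical(classify_hgs(5.0, 12, "boys", hbz), "Very Poor")
  # edge values land in the zone they open
  p10 <- ref$P10[ref$sex == "boys" & ref$age == 12]
  expect_identical(classify_hgs(p10, 12, "boys", hbz), "Poor")
  expect_identical(classify_hgs(p10 - 1e-9, 12, "boys", hbz), "Very Poor")
})

test_that("every covered value maps to exactly one zone", {
  set.seed(2)
  vals <- runif(500, 1, 80)
  z <- classify_hgs(vals, sample(12:16, 500, TRUE),
                    sample(c("boys", "girls"), 500, TRUE), hbz)
  expect_true(all(z %in% hbz_zones()))
  expect_identical(length(z), 500L)
})

test_that("uncovered ages refuse classification", {
  expect_error(classify_hgs(20, 17, "boys", hbz), "not covered")
  expect_error(classify_hgs(-3, 14, "boys", hbz), "positive")
})

test_that("the verbal P10-P50 scheme needs P50 and differs from the realized one", {
  no50 <- build_reference_table(ref[, c("sex", "age", "L", "M", "S")],
                                percentiles = c(3, 10, 35, 65, 90))
  expect_error(build_hbz_table(no50, scheme = "section27"), "P50")
  s27 <- build_hbz_table(ref, scheme = "section27")
  med <- s27[s27$sex == "boys" & s27$age == 12 & s27$zone == "Medium", ]
  expect_identical(med$lower, ref$P10[ref$sex == "boys" & ref$age == 12])
  expect_identical(med$upper, ref$P50[ref$sex == "boys" & ref$age == 12])
})

test_that("population distribution reproduces the published percentages from its counts", {
  counts <- southpunjab_zone_counts()
  rows <- list()
  for (s in c("boys", "girls")) {
    r <- hbz[hbz$sex == s & hbz$age == 12, ]
    r <- r[match(hbz_zones(), r$zone), ]
    mid <- ifelse(is.infinite(r$upper), r$lower + 1, (r$lower + r$upper) / 2)
    n <- counts[[s]]
    rows[[s]] <- data.frame(sex = s, age = 12,
                            hgs_abs_kg = rep(mid, n))
  }
  cohort <- do.call(rbind, rows)
  pd <- population_distribution(cohort, hbz)
  expect_identical(pd$n, counts$total)
  expect_identical(pd$pct, c(11.1, 22.5, 32.7, 24.6, 9.2))
  expect_identical(pd$pct_boys, c(10.0, 22.2, 37.4, 20.4, 9.9))
  expect_identical(pd$pct_girls, c(12.1, 22.8, 27.9, 28.7, 8.4))
  expect_identical(sum(pd$n), 2970L)
})

test_that("uncovered records are excluded with a warning, empty cohorts error", {
  coh <- data.frame(sex = c("boys", "boys"), age = c(14, 19),
                    hgs_abs_kg = c(25, 25))
  expect_warning(pd <- population_distribution(coh, hbz), "excluded")
  expect_identical(sum(pd$n), 1L)
  expect_identical(nrow(attr(pd, "uncovered")), 1L)
  expect_error(population_distribution(coh[0, ], hbz))
})

test_that("large model-generated cohorts hit the realized scheme's nominal masses", {
  sp <- default_spec()
  sp$n <- rep(2000, nrow(sp))
  big <- generate_cohort(sp, seed = 19)
  pd <- population_distribution(big, hbz, by_sex = FALSE)
  expect_lt(max(abs(pd$pct - c(10, 25, 30, 25, 10))), 1.2)
})

test_that("HBZ CSV round-trips including the open Excellent interval", {
  f <- tempfile(fileext = ".csv")
  write_hbz_csv(hbz, f)
  back <- read_hbz_csv(f)
  expect_equal(back$lower, hbz$lower, tolerance = 1e-12)
  expect_identical(back$upper[back$zone == "Excellent"],
                   rep(Inf, 10))
  expect_identical(classify_hgs(35.47, 16, "boys", back), "Medium")
})
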