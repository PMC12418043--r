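## Back-generation cross-validation: refit the LMS model on a stratified
## random holdout subset, compare holdout-fitted P50 medians ("fitted") to
## full-sample P50 medians ("actual") per age and sex, and score with a
## signed MAPE.  "MAPE" follows the forecasting-validation usage: the row
## statistic is a signed relative error, (actual - fitted)/fitted by
## default, averaged arithmetically; the absolute value is taken only when
## banding the average against the interpretation scale (< 10 % highly
## accurate, 10-20 % good, 20-50 % reasonable, > 50 % inaccurate).

#' Stratified random holdout split
#'
#' Samples `round-half-up(fraction x stratum size)` records from every
#' age x sex stratum, reproducibly under `seed`.
#'
#' @param cohort Cohort data frame with `sex` and `age` columns.
#' @param fraction Holdout fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with `full` (the input cohort), `holdout` (the sampled
#'   subset) and `holdout_idx` (row indices into `cohort`).
#' @export
stratified_holdout <- function(cohort, fraction = 0.2, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  key <- interaction(cohort$sex, cohort$age, drop = FALSE)
  sizes <- table(key)
  if (any(sizes == 0))
    stop("empty stratum: ", paste(names(sizes)[sizes == 0], collapse = ", "))
  take <- round_half_up(fraction * as.integer(sizes))
  if (any(take < 10))
    warning("holdout smaller than 10 records in stratum(s): ",
            paste(names(sizes)[take < 10], collapse = ", "))
  set.seed(seed)
  idx <- unlist(lapply(levels(key)[as.integer(sizes) > 0], function(k) {
    rows <- which(key == k)
    sample(rows, take[match(k, names(sizes))])
  }), use.names = FALSE)
  idx <- sort(idx)
  list(full = cohort, holdout = cohort[idx, , drop = FALSE], holdout_idx = idx)
}

#' Signed MAPE rows from actual and fitted medians
#'
#' @param actual,fitted Named numeric vectors (names = ages) or data frames
#'   with columns `age` and `value`; keys must match.
#' @param convention Denominator of the relative error: `"fitted"`
#'   (default; `(actual - fitted)/fitted`) or `"actual"`.
#' @return A data frame with `age`, `actual`, `fitted`, `mape` (signed
#'   fraction, full precision).
#' @examples
#' bg <- subset(southpunjab_backgen(), sex == "boys")
#' backgen_test(setNames(bg$actual, bg$age), setNames(bg$fitted, bg$age))
#' @export
backgen_test <- function(actual, fitted, convention = c("fitted", "actual")) {
  convention <- match.arg(convention)
  as_map <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$value, x$age) else x
  }
  actual <- as_map(actual); fitted <- as_map(fitted)
  if (is.null(names(actual)) || is.null(names(fitted)))
    stop("'actual' and 'fitted' must be named by age")
  if (!setequal(names(actual), names(fitted)))
    stop("age keys differ between 'actual' and 'fitted'")
  fitted <- fitted[names(actual)]
  if (any(actual <= 0) || any(fitted <= 0)) stop("medians must be positive")
  denom <- if (convention == "fitted") fitted else actual
  data.frame(age = as.numeric(names(actual)),
             actual = unname(actual), fitted = unname(fitted),
             mape = unname((actual - fitted) / denom))
}

#' Interpret an average MAPE on the accuracy scale
#'
#' Bands `100 x |average_mape|`: below 10 "highly accurate", 10 to below
#' 20 "good", 20 up to 50 "reasonable", above 50 "inaccurate"; boundary
#' values fall into the better band.
#'
#' @param average_mape Signed average MAPE as a fraction (e.g. -0.007).
#' @return One of `"highly accurate"`, `"good"`, `"reasonable"`,
#'   `"inaccurate"`.
#' @examples
#' mape_interpret(-0.007)  # "highly accurate"
#' @export
mape_interpret <- function(average_mape) {
  stopifnot(is.finite(average_mape))
  x <- 100 * abs(average_mape)
  if (x < 10) "highly accurate"
  else if (x < 20) "good"
  else if (x <= 50) "reasonable"
  else "inaccurate"
}

#' Run the full back-generation validation pipeline
#'
#' Splits the cohort with [stratified_holdout()], obtains per-age P50
#' medians from the full sample ("actual") and from the holdout subset
#' ("fitted") — by refitting the LMS model on each set (default) or from
#' raw per-age medians — then scores each sex with [backgen_test()] and
#' bands the averages with [mape_interpret()].
#'
#' @param cohort Cohort spanning both sexes and all ages.
#' @param config A [fit_config()] used for both fits.
#' @param fraction Holdout fraction.
#' @param seed Integer seed.
#' @param convention MAPE denominator convention, see [backgen_test()].
#' @param medians `"refit"` (LMS fit on each set, default) or `"raw"`
#'   (sample medians).
#' @return A `validation_report`: list with `rows` (per-sex data frames),
#'   `average` and `band` (named per sex), and `provenance` (fraction,
#'   seed, convention, medians mode).
#' @export
run_backgeneration <- function(cohort, config = fit_config(), fraction = 0.2,
                               seed, convention = c("fitted", "actual"),
                               medians = c("refit", "raw")) {
  convention <- match.arg(convention)
  medians <- match.arg(medians)
  sexes <- intersect(.sexes, unique(cohort$sex))
  if (length(sexes) < 2) stop("cohort must span both sexes")
  split <- stratified_holdout(cohort, fraction, seed)
  p50 <- function(dat) {
    ages <- sort(unique(dat$age))
    if (medians == "refit") {
      model <- tryCatch(fit_lms(dat, config),
                        error = function(e)
                          stop("LMS refit failed (", unique(dat$sex), "): ",
                               conditionMessage(e), call. = FALSE))
      stats::setNames(predict_lms(model, ages)$mu, ages)
    } else {
      stats::setNames(as.numeric(tapply(dat$hgs_abs_kg, dat$age,
                                        stats::median)), ages)
    }
  }
  rows <- list(); average <- c(); band <- c()
  for (s in sexes) {
    actual <- p50(split$full[split$full$sex == s, ])
    fitted <- p50(split$holdout[split$holdout$sex == s, ])
    r <- backgen_test(actual, fitted, convention)
    rows[[s]] <- r
    average[s] <- mean(r$mape)
    band[s] <- mape_interpret(average[s])
  }
  structure(list(rows = rows, average = average, band = band,
                 provenance = list(fraction = fraction, seed = seed,
                                   convention = convention,
                                   medians = medians)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Back-generation validation (holdout fraction",
      x$provenance$fraction, ", seed", x$provenance$seed, ",",
      x$provenance$convention, "denominator,", x$provenance$medians,
      "medians)\n")
  for (s in names(x$rows)) {
    r <- x$rows[[s]]
    cat("\n", s, ":\n", sep = "")
    print(data.frame(age = r$age, actual = round(r$actual, 2),
                     fitted = round(r$fitted, 2),
                     MAPE = fmt_fixed(r$mape, 2)), row.names = FALSE)
    cat("  average MAPE ", fmt_fixed(x$average[s], 3), " (", x$band[s],
        ")\n", sep = "")
  }
  invisible(x)
}

#' Write a validation report as CSV
#'
#' Mirrors the published layout: a metadata header (comment lines), then
#' age, actual, fitted, MAPE per sex block with a trailing average row.
#' Row MAPEs are written at 2 decimals, averages at 3.
#'
#' @param report A `validation_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_validation_csv <- function(report, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  p <- report$provenance
  writeLines(c(
    paste0("# holdout_fraction: ", p$fraction),
    paste0("# seed: ", p$seed),
    paste0("# convention: ", p$convention),
    paste0("# medians: ", p$medians),
    "sex,age,actual,fitted,mape"), con)
  for (s in names(report$rows)) {
    r <- report$rows[[s]]
    writeLines(sprintf("%s,%s,%.2f,%.2f,%s", s, r$age, r$actual, r$fitted,
                       fmt_fixed(r$mape, 2)), con)
    writeLines(sprintf("%s,average,,,%s", s, fmt_fixed(report$average[s], 3)),
               con)
  }
  invisible(path)
}
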