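## Published South Punjab (Pakistan) handgrip-strength reference values for
## adolescents aged 12-16: the LMS parameters with their percentile table,
## the Health Benefit Zone band strings derived from them, the population
## zone counts, the back-generation validation medians, and the per-stratum
## anthropometric medians/IQRs the synthetic cohort generator defaults to.
## All values are stored as printed (L and S to 3 dp, kg to 2 dp).

#' Published South Punjab LMS reference parameters and percentiles
#'
#' The age- and sex-specific LMS parameters (L skewness, M median, S
#' coefficient of variation) for absolute handgrip strength of South Punjab
#' adolescents aged 12--16, together with the published smoothed percentile
#' values (P3, P10, P35, P50, P65, P90) they generate.  Every percentile
#' cell is reproducible from the L, M, S columns via [bccg_quantile()] to
#' within the 3-decimal rounding of the printed parameters.
#'
#' @return A `reference_table` data frame with columns `sex` ("boys" /
#'   "girls"), `age` (years), `L`, `M`, `S`, and `P3` \ldots `P90`.
#' @seealso [build_reference_table()], [reconstruct_and_diff()]
#' @examples
#' ref <- southpunjab_reference()
#' subset(ref, sex == "boys" & age == 13)
#' @export
southpunjab_reference <- function() {
  ref <- data.frame(
    sex = rep(c("boys", "girls"), each = 5),
    age = rep(12:16, 2),
    L = c(0.227, -0.004, -0.198, -0.339, -0.413,
          0.268, 0.442, 0.615, 0.789, 0.963),
    M = c(22.53, 25.77, 29.00, 32.24, 35.47,
          14.12, 15.01, 16.48, 18.16, 20.18),
    S = c(0.483, 0.432, 0.393, 0.364, 0.345,
          0.279, 0.317, 0.331, 0.293, 0.286),
    P3  = c(8.14, 11.45, 14.55, 17.42, 19.96,  8.02, 7.51, 7.52, 8.81, 9.46),
    P10 = c(11.56, 14.82, 17.94, 20.90, 23.63,  9.59, 9.69, 10.08, 11.63, 12.84),
    P35 = c(18.63, 21.82, 24.98, 28.11, 31.17, 12.66, 13.24, 14.43, 16.14, 17.96),
    P50 = c(22.53, 25.77, 29.00, 32.24, 35.47, 14.12, 15.01, 16.48, 18.16, 20.18),
    P65 = c(27.03, 30.43, 33.82, 37.22, 40.66, 15.70, 16.90, 18.63, 20.23, 22.41),
    P90 = c(40.21, 44.86, 49.31, 53.58, 57.81, 19.87, 21.81, 24.03, 25.23, 27.62),
    stringsAsFactors = FALSE
  )
  structure(ref, class = c("reference_table", "data.frame"),
            percentile_set = c(3, 10, 35, 50, 65, 90))
}

#' Published Health Benefit Zone band strings
#'
#' The published age- and sex-specific Health Benefit Zone cut-off bands for
#' handgrip strength (kg), as display strings: closed two-decimal ranges with
#' the lower bound of each zone one display unit (0.01 kg) above the upper
#' bound of the zone below, and an open-ended "\eqn{\ge}" Excellent zone.
#' These strings are exactly what [format_hbz_table()] produces from
#' [southpunjab_reference()] under the `"table6"` banding scheme.
#'
#' @return A data frame with columns `sex`, `age`, `very_poor`, `poor`,
#'   `medium`, `good`, `excellent` (UTF-8 strings, en-dash ranges).
#' @export
southpunjab_hbz_bands <- function() {
  data.frame(
    sex = rep(c("boys", "girls"), each = 5),
    age = rep(12:16, 2),
    very_poor = c("8.14–11.56", "11.45–14.82", "14.55–17.94",
                  "17.42–20.90", "19.96–23.63",
                  "8.02–9.59", "7.51–9.69", "7.52–10.08",
                  "8.81–11.63", "9.46–12.84"),
    poor = c("11.57–18.63", "14.83–21.82", "17.95–24.98",
             "20.91–28.11", "23.64–31.17",
             "9.60–12.66", "9.70–13.24", "10.09–14.43",
             "11.64–16.14", "12.85–17.96"),
    medium = c("18.64–27.03", "21.83–30.43", "24.99–33.82",
               "28.12–37.22", "31.18–40.66",
               "12.67–15.70", "13.25–16.90", "14.44–18.63",
               "16.15–20.23", "17.97–22.41"),
    good = c("27.04–40.21", "30.44–44.86", "33.83–49.31",
             "37.23–53.58", "40.67–57.81",
             "15.71–19.87", "16.91–21.81", "18.64–24.03",
             "20.24–25.23", "22.42–27.62"),
    excellent = c("≥40.22", "≥44.87", "≥49.32", "≥53.59",
                  "≥57.82",
                  "≥19.88", "≥21.82", "≥24.04", "≥25.24",
                  "≥27.63"),
    stringsAsFactors = FALSE
  )
}

#' Published population Health Benefit Zone counts
#'
#' Zone membership counts of the South Punjab study population (n = 2,970;
#' 1,477 boys, 1,493 girls) under the published cut-off bands.
#'
#' @return A data frame with columns `zone`, `total`, `boys`, `girls`.
#' @export
southpunjab_zone_counts <- function() {
  data.frame(
    zone = hbz_zones(),
    total = c(329L, 669L, 970L, 730L, 272L),
    boys = c(148L, 328L, 553L, 302L, 146L),
    girls = c(181L, 341L, 417L, 428L, 126L),
    stringsAsFactors = FALSE
  )
}

#' Published back-generation validation medians
#'
#' The actual (full-sample) and fitted (holdout-refit) P50 handgrip-strength
#' medians per age and sex from the published internal cross-validation,
#' from which the signed row MAPEs and block averages are recomputed.
#'
#' @return A data frame with columns `sex`, `age`, `actual`, `fitted`.
#' @seealso [backgen_test()]
#' @export
southpunjab_backgen <- function() {
  data.frame(
    sex = rep(c("boys", "girls"), each = 5),
    age = rep(12:16, 2),
    actual = c(22.53, 25.77, 29.00, 32.24, 35.47,
               14.12, 15.01, 16.48, 18.16, 20.18),
    fitted = c(23.20, 25.00, 29.55, 31.10, 37.50,
               13.95, 14.50, 14.95, 19.10, 21.00),
    stringsAsFactors = FALSE
  )
}

#' Per-stratum anthropometric medians and IQRs of the study population
#'
#' Median and interquartile range of height and weight per age-sex stratum,
#' with the stratum sample sizes, used as the default location/spread inputs
#' of the synthetic cohort generator.
#'
#' @return A data frame with columns `sex`, `age`, `n`, `height_median`,
#'   `height_iqr`, `weight_median`, `weight_iqr`.
#' @export
southpunjab_anthropometry <- function() {
  data.frame(
    sex = rep(c("boys", "girls"), each = 5),
    age = rep(12:16, 2),
    n = c(291L, 295L, 298L, 298L, 295L, 299L, 298L, 295L, 300L, 300L),
    height_median = c(149, 159, 165, 165, 167, 153, 158, 162, 162, 162),
    height_iqr = c(14, 15, 11, 9, 12, 14, 14, 8, 10, 8),
    weight_median = c(35.55, 43.00, 48.00, 44.83, 49.00,
                      35.50, 38.00, 40.00, 43.50, 44.00),
    weight_iqr = c(13.00, 12.80, 9.63, 7.25, 10.00,
                   11.00, 9.00, 8.75, 9.00, 8.00),
    stringsAsFactors = FALSE
  )
}
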