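## Cohort readers/derivers, descriptive summaries, and the survey planning
## formula.

#' Required sample size for a proportion estimate
#'
#' The standard survey planning formula
#' \eqn{n = (Z^2 P Q / e^2) \times D}, ceiled: `p` the anticipated
#' proportion, `q = 1 - p`, `z` the normal deviate of the confidence level,
#' `e` the margin of error, `deff` the design effect.
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param e Margin of error, in (0, 1).
#' @param z Normal deviate for the confidence level (1.96 for 95%).
#' @param deff Design effect, positive.
#' @return Integer minimum sample size.
#' @examples
#' required_sample_size(p = 0.40, e = 0.05)  # 369
#' @export
required_sample_size <- function(p, e, z = 1.96, deff = 1.0) {
  if (p <= 0 || p >= 1) stop("'p' must be in (0, 1)")
  if (e <= 0 || e >= 1) stop("'e' must be in (0, 1)")
  if (z <= 0) stop("'z' must be positive")
  if (deff <= 0) stop("'deff' must be positive")
  as.integer(ceiling(z^2 * p * (1 - p) / e^2 * deff))
}

#' Derive computed cohort fields and validate records
#'
#' Computes absolute HGS as the mean of the left- and right-hand maxima
#' (when not already present) and BMI as weight / (height in m)^2.
#' Idempotent on already-derived records.  Rows failing validation
#' (non-positive anthropometrics, no usable HGS) are removed, attached as
#' attribute `"rejected"` with a `reason` column, and warned about — never
#' silently dropped.
#'
#' @param raw Data frame with columns `sex`, `age`, `height_cm`,
#'   `weight_kg`, and either `hgs_abs_kg` or both `hgs_left_kg` and
#'   `hgs_right_kg`.
#' @return The validated cohort with `bmi` and `hgs_abs_kg` filled in.
#' @export
derive_fields <- function(raw) {
  need <- c("sex", "age", "height_cm", "weight_kg")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  has_hands <- all(c("hgs_left_kg", "hgs_right_kg") %in% names(raw))
  if (!has_hands && !"hgs_abs_kg" %in% names(raw))
    stop("missing column(s): hgs_abs_kg (or hgs_left_kg + hgs_right_kg)")
  df <- raw
  if (is.null(df$hgs_abs_kg)) df$hgs_abs_kg <- NA_real_
  if (has_hands) {
    fill <- is.na(df$hgs_abs_kg)
    df$hgs_abs_kg[fill] <- (df$hgs_left_kg[fill] + df$hgs_right_kg[fill]) / 2
  }
  df$bmi <- df$weight_kg / (df$height_cm / 100)^2

  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(!is.finite(df$height_cm) | df$height_cm <= 0,
                "non-positive height")
  reason <- bad(!is.finite(df$weight_kg) | df$weight_kg <= 0,
                "non-positive weight")
  reason <- bad(!is.finite(df$hgs_abs_kg) | df$hgs_abs_kg <= 0,
                "missing or non-positive HGS")
  reason <- bad(!df$sex %in% .sexes, "unknown sex label")
  rejected <- df[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[!is.na(reason)]
    warning(nrow(rejected), " record(s) rejected during field derivation")
  }
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, rejected = rejected)
}

#' Median / IQR summary table
#'
#' Medians and interquartile ranges (Q3 - Q1, linear interpolation between
#' order statistics, the "type 7" quartile rule) per group for the
#' requested variables.
#'
#' @param cohort Cohort data frame.
#' @param by Grouping column names, e.g. `c("sex", "age")`; `NULL` for a
#'   single overall group.
#' @param vars Variables to summarize.
#' @return A data frame with the grouping columns, `n`, and
#'   `<var>_median` / `<var>_iqr` per variable.  Quartile rule recorded in
#'   attribute `"quartile_type"`.
#' @export
describe_cohort <- function(cohort, by = c("sex", "age"),
                            vars = c("height_cm", "weight_kg", "bmi",
                                     "hgs_abs_kg")) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  vars <- intersect(vars, names(cohort))
  if (!length(vars)) stop("none of 'vars' present in the cohort")
  groups <- if (is.null(by)) list(seq_len(nrow(cohort)))
            else split(seq_len(nrow(cohort)), cohort[by], drop = TRUE)
  rows <- lapply(groups, function(idx) {
    g <- cohort[idx, , drop = FALSE]
    row <- if (is.null(by)) data.frame(n = nrow(g))
           else cbind(g[1, by, drop = FALSE], n = nrow(g))
    for (v in vars) {
      row[[paste0(v, "_median")]] <- stats::median(g[[v]])
      row[[paste0(v, "_iqr")]] <- stats::IQR(g[[v]], type = 7)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(by)) out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, quartile_type = 7)
}

#' Read / write a cohort CSV
#'
#' Schema: `id, sex, age, height_cm, weight_kg, bmi, hgs_left_kg,
#' hgs_right_kg, hgs_abs_kg`; header required, UTF-8, decimal point.
#' Unicode minus signs and dashes in numeric fields are normalized to
#' ASCII on ingest.
#'
#' @param path File path.
#' @param derive Run [derive_fields()] on the rows after reading.
#' @return `read_cohort_csv()` returns a cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, derive = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sex", "age", "height_cm", "weight_kg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (v in setdiff(names(df), c("id", "sex"))) {
    if (is.character(df[[v]])) df[[v]] <- as.numeric(normalize_minus(df[[v]]))
  }
  if (derive) derive_fields(df) else df
}

#' @rdname read_cohort_csv
#' @param cohort Cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
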