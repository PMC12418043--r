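## Percentile reference tables and centile curves: the machine form of an LMS
## reference standard.  A reference_table is a data frame with one row per
## age, carrying the LMS triple (L, M, S) and one column per percentile rank
## (P3 ... P90).  Cells are stored at full precision; 2-dp rounding happens
## only at serialization.

#' Build a percentile reference table from LMS triples
#'
#' Evaluates [bccg_quantile()] at every requested percentile rank for each
#' age's (L, M, S) triple, producing the machine form of a published LMS
#' reference table.
#'
#' @param triples A data frame with columns `age`, `L`, `M`, `S` (one row
#'   per age) and optionally `sex`.
#' @param percentiles Ordered percentile ranks in (0, 100).  Default is the
#'   six-rank set used by the shipped reference,
#'   `c(3, 10, 35, 50, 65, 90)`.
#' @param sex Sex label attached to the table when `triples` has no `sex`
#'   column.
#' @return A `reference_table` data frame: `sex`, `age`, `L`, `M`, `S`,
#'   then one `P<rank>` column per percentile, values at full precision.
#' @examples
#' tri <- subset(southpunjab_reference(), sex == "boys",
#'               select = c(age, L, M, S))
#' build_reference_table(tri, sex = "boys")
#' @export
build_reference_table <- function(triples,
                                  percentiles = c(3, 10, 35, 50, 65, 90),
                                  sex = NULL) {
  stopifnot(is.data.frame(triples),
            all(c("age", "L", "M", "S") %in% names(triples)))
  if (is.unsorted(percentiles, strictly = TRUE) ||
      any(percentiles <= 0) || any(percentiles >= 100))
    stop("'percentiles' must be strictly increasing within (0, 100)")
  if (is.null(triples$sex)) {
    triples$sex <- if (is.null(sex)) NA_character_ else check_sex(sex)
  }
  if (anyDuplicated(triples[, c("sex", "age")]))
    stop("one row per sex and age required")
  triples <- triples[order(match(triples$sex, .sexes), triples$age), ,
                     drop = FALSE]
  out <- triples[, c("sex", "age", "L", "M", "S")]
  for (p in percentiles) {
    val <- tryCatch(
      bccg_quantile(p, triples$L, triples$M, triples$S),
      error = function(e) stop("percentile P", p, " undefined: ",
                               conditionMessage(e), call. = FALSE))
    out[[paste0("P", p)]] <- val
  }
  rownames(out) <- NULL
  structure(out, class = c("reference_table", "data.frame"),
            percentile_set = percentiles)
}

ref_percentiles <- function(ref) {
  ps <- attr(ref, "percentile_set")
  if (is.null(ps))
    ps <- as.numeric(sub("^P", "", grep("^P[0-9.]+$", names(ref), value = TRUE)))
  ps
}

#' Recompute a reference table from its own LMS columns and report drift
#'
#' Regression harness for printed reference tables: recomputes every
#' percentile cell from the stored (L, M, S) triple and reports the
#' per-row maximum absolute discrepancy against the stored cells.  With
#' parameters printed to 3 decimals a drift up to about 0.02 kg per cell is
#' legitimate rounding; anything larger flags a transcription error.
#'
#' @param ref A `reference_table` carrying both triples and cell values,
#'   e.g. [southpunjab_reference()].
#' @param tol Cell discrepancy above which a cell is flagged.
#' @return A data frame with `sex`, `age`, `max_abs_diff`, `worst_cell`,
#'   `flagged`; the full per-cell difference matrix is attached as
#'   attribute `"diffs"`.
#' @examples
#' reconstruct_and_diff(southpunjab_reference())
#' @export
reconstruct_and_diff <- function(ref, tol = 0.02) {
  ps <- ref_percentiles(ref)
  cols <- paste0("P", ps)
  stopifnot(all(cols %in% names(ref)))
  recomputed <- sapply(ps, function(p) bccg_quantile(p, ref$L, ref$M, ref$S))
  printed <- as.matrix(ref[, cols])
  diffs <- abs(recomputed - printed)
  colnames(diffs) <- cols
  report <- data.frame(
    sex = ref$sex, age = ref$age,
    max_abs_diff = apply(diffs, 1, max),
    worst_cell = cols[apply(diffs, 1, which.max)],
    stringsAsFactors = FALSE
  )
  report$flagged <- report$max_abs_diff > tol
  structure(report, diffs = diffs)
}

# interpolate per-age triples to arbitrary ages: linear in (L, log M, log S)
# between knots, guaranteeing valid triples; constant beyond the end ages
interpolate_triples <- function(triples, age) {
  triples <- triples[order(triples$age), , drop = FALSE]
  rule <- 2  # clamp outside the age range
  if (nrow(triples) == 1L) {
    return(data.frame(age = age,
                      L = triples$L, M = triples$M, S = triples$S))
  }
  data.frame(
    age = age,
    L = stats::approx(triples$age, triples$L, age, rule = rule)$y,
    M = exp(stats::approx(triples$age, log(triples$M), age, rule = rule)$y),
    S = exp(stats::approx(triples$age, log(triples$S), age, rule = rule)$y)
  )
}

#' Centile curve coordinates for plotting
#'
#' Evaluates the requested percentile curves on an age grid, either from a
#' fitted [fit_lms()] model or from a table of per-age triples (interpolated
#' linearly in L, log M, log S between ages).  Curves from a common
#' parameter set cannot cross: strict ordering is verified at every grid
#' point.
#'
#' @param object An `lms_model` from [fit_lms()], or a data frame of per-age
#'   triples with columns `age`, `L`, `M`, `S`.
#' @param age_grid Ages at which to evaluate the curves.
#' @param percentiles Percentile ranks of the curves.
#' @return A long data frame with columns `age`, `percentile`, `value`.
#' @export
centile_curves <- function(object, age_grid,
                           percentiles = c(3, 10, 35, 50, 65, 90)) {
  if (inherits(object, "lms_model")) {
    tri <- predict_lms(object, age_grid)
    tri <- data.frame(age = age_grid, L = tri$lambda, M = tri$mu, S = tri$sigma)
  } else {
    stopifnot(is.data.frame(object),
              all(c("age", "L", "M", "S") %in% names(object)))
    tri <- interpolate_triples(object, age_grid)
  }
  out <- do.call(rbind, lapply(percentiles, function(p) {
    data.frame(age = tri$age, percentile = p,
               value = bccg_quantile(p, tri$L, tri$M, tri$S))
  }))
  # non-crossing sanity check (strict at every age)
  wide <- matrix(out$value, nrow = length(age_grid))
  if (any(apply(wide, 1, function(v) any(diff(v) <= 0))))
    stop("centile curves cross: percentile ordering violated on the grid")
  rownames(out) <- NULL
  out
}

#' Write / read a reference table as CSV
#'
#' Serializes with the published precision: kg cells fixed to 2 decimals,
#' L and S to 3 decimals.  Reading restores a `reference_table` (values then
#' carry serialization precision only).
#'
#' @param ref A `reference_table`.
#' @param path File path.
#' @return `write_reference_csv()` returns `path` invisibly;
#'   `read_reference_csv()` returns a `reference_table`.
#' @export
write_reference_csv <- function(ref, path) {
  ps <- ref_percentiles(ref)
  out <- ref
  out$L <- fmt_fixed(ref$L, 3)
  out$S <- fmt_fixed(ref$S, 3)
  out$M <- fmt_fixed(ref$M, 2)
  for (p in paste0("P", ps)) out[[p]] <- fmt_fixed(ref[[p]], 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "L", "M", "S")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ps <- as.numeric(sub("^P", "", grep("^P[0-9.]+$", names(df), value = TRUE)))
  structure(df, class = c("reference_table", "data.frame"),
            percentile_set = sort(ps))
}
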