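## Health Benefit Zones: five-tier percentile-based bands (Very Poor, Poor,
## Medium, Good, Excellent) cut from a percentile reference table, a total
## classifier over them, and population zone summaries.
##
## Two banding schemes exist because the published account of the zones is
## internally inconsistent.  The realized cut-off table takes its edges at
## P3/P10/P35/P65/P90 (nominal band masses 10/25/30/25/10 %, counting the
## open tails), and the published population distribution matches those
## masses; the verbal definition instead names P3/P10/P50/P90 (Medium =
## P10-P50).  The package implements both: scheme "table6" (the realized
## one, default) and scheme "section27" (the verbal one).

#' Zone labels, poorest to strongest
#' @return Character vector of the five zone names.
#' @export
hbz_zones <- function()
  c("Very Poor", "Poor", "Medium", "Good", "Excellent")

.scheme_edges <- function(scheme) {
  switch(scheme,
    table6 = c(3, 10, 35, 65, 90),
    section27 = c(3, 10, 50, 90),
    stop("unknown banding scheme: ", scheme))
}

#' Build a Health Benefit Zone cut-off table from a reference table
#'
#' Takes the scheme's designated percentile columns of `ref` at full
#' precision as zone edges.  Under `"table6"` (default) the five zones span
#' (0, P10), \[P10, P35), \[P35, P65), \[P65, P90), \[P90, Inf); the Very
#' Poor zone additionally records P3 as its display floor.  Under
#' `"section27"` the interior edges are P3, P10, P50, P90.
#'
#' @param ref A `reference_table` containing the percentile ranks the
#'   scheme needs.
#' @param scheme `"table6"` or `"section27"`.
#' @return An `hbz_table` data frame: `sex`, `age`, `zone`, `lower`,
#'   `upper` (`upper = Inf` for Excellent; `lower` of Very Poor is the
#'   display floor P3, classification there is open below).
#' @export
build_hbz_table <- function(ref, scheme = c("table6", "section27")) {
  scheme <- match.arg(scheme)
  edges <- .scheme_edges(scheme)
  cols <- paste0("P", edges)
  miss <- setdiff(cols, names(ref))
  if (length(miss))
    stop("reference table lacks percentile rank(s) needed by scheme '",
         scheme, "': ", paste(miss, collapse = ", "))
  zones <- hbz_zones()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    e <- as.numeric(ref[i, cols])
    if (is.unsorted(e, strictly = TRUE))
      stop("percentile edges not increasing at ", ref$sex[i], " age ",
           ref$age[i])
    if (scheme == "table6") {
      lower <- c(e[1], e[2], e[3], e[4], e[5])
      upper <- c(e[2], e[3], e[4], e[5], Inf)
    } else {
      # section27: Very Poor < P3, then P3-P10, P10-P50, P50-P90, >= P90
      lower <- c(0, e[1], e[2], e[3], e[4])
      upper <- c(e[1], e[2], e[3], e[4], Inf)
    }
    data.frame(sex = ref$sex[i], age = ref$age[i], zone = zones,
               lower = lower, upper = upper, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("hbz_table", "data.frame"), scheme = scheme)
}

# classification edges for one (sex, age): the interior boundaries between
# the five zones (4 numbers); Very Poor is open below, Excellent open above
.hbz_cutpoints <- function(hbz, sex, age) {
  rows <- hbz[hbz$sex == sex & hbz$age == age, ]
  if (nrow(rows) != 5)
    stop("age ", age, " (", sex, ") not covered by the HBZ table")
  rows <- rows[match(hbz_zones(), rows$zone), ]
  rows$upper[1:4]
}

#' Classify handgrip strength into a Health Benefit Zone
#'
#' Total classifier: values below the lowest interior edge are Very Poor
#' (including values under the P3 display floor), values at or above the
#' top edge are Excellent; intervals are closed below, open above, at full
#' precision.
#'
#' @param value HGS value(s), kg, positive.
#' @param age,sex Age(s) and sex label(s), recycled against `value`; must
#'   be covered by the table (no extrapolated classification).
#' @param hbz An `hbz_table` from [build_hbz_table()].
#' @return Character vector of zone labels.
#' @examples
#' hbz <- build_hbz_table(southpunjab_reference())
#' classify_hgs(35.47, 16, "boys", hbz)   # "Medium"
#' @export
classify_hgs <- function(value, age, sex, hbz) {
  stopifnot(inherits(hbz, "hbz_table"))
  if (any(value <= 0)) stop("HGS values must be positive")
  n <- max(length(value), length(age), length(sex))
  value <- rep_len(value, n); age <- rep_len(age, n)
  sex <- rep_len(check_sex(sex), n)
  key <- paste(sex, age)
  zones <- hbz_zones()
  out <- character(n)
  for (k in unique(key)) {
    idx <- key == k
    cut <- .hbz_cutpoints(hbz, sex[idx][1], age[idx][1])
    # closed below, open above: value >= edge moves into the next zone
    out[idx] <- zones[findInterval(value[idx], cut) + 1L]
  }
  out
}

#' Summarize a cohort's zone distribution
#'
#' Counts and percentages per zone, overall and (when `by_sex`) per sex.
#' Records whose age x sex is not covered by the table are excluded with a
#' warning and listed in attribute `"uncovered"`, never silently dropped.
#' Percentages are count/n x 100, rounded half-up to 1 decimal.
#'
#' @param cohort Cohort data frame with `sex`, `age`, `hgs_abs_kg`.
#' @param hbz An `hbz_table`.
#' @param by_sex Also tabulate per sex.
#' @return A `zone_distribution` data frame: `zone`, `n`, `pct`, and when
#'   `by_sex` the per-sex columns `n_boys`, `pct_boys`, `n_girls`,
#'   `pct_girls`.
#' @export
population_distribution <- function(cohort, hbz, by_sex = TRUE) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  covered <- paste(cohort$sex, cohort$age) %in% paste(hbz$sex, hbz$age)
  uncovered <- cohort[!covered, , drop = FALSE]
  if (nrow(uncovered)) {
    warning(nrow(uncovered), " record(s) outside the HBZ table coverage ",
            "were excluded")
    cohort <- cohort[covered, , drop = FALSE]
  }
  if (!nrow(cohort)) stop("no classifiable records")
  zone <- factor(classify_hgs(cohort$hgs_abs_kg, cohort$age, cohort$sex, hbz),
                 levels = hbz_zones())
  tab <- table(zone)
  out <- data.frame(zone = hbz_zones(), n = as.integer(tab),
                    pct = round_half_up(100 * as.integer(tab) / nrow(cohort), 1),
                    stringsAsFactors = FALSE)
  if (by_sex) {
    for (s in intersect(.sexes, unique(cohort$sex))) {
      idx <- cohort$sex == s
      tabs <- table(zone[idx])
      out[[paste0("n_", s)]] <- as.integer(tabs)
      out[[paste0("pct_", s)]] <-
        round_half_up(100 * as.integer(tabs) / sum(idx), 1)
    }
  }
  structure(out, class = c("zone_distribution", "data.frame"),
            total = nrow(cohort), uncovered = uncovered)
}

#' Format an HBZ table as published-style band strings
#'
#' Serializes each zone as a closed 2-decimal range, with the lower bound
#' of each zone one display unit (0.01 kg) above the upper bound of the
#' zone below, and Excellent as an open-ended "\eqn{\ge}" bound; the Very
#' Poor band is displayed from its P3 floor.
#'
#' @param hbz An `hbz_table` (scheme `"table6"`).
#' @return A data frame with columns `sex`, `age`, `very_poor`, `poor`,
#'   `medium`, `good`, `excellent`.
#' @examples
#' format_hbz_table(build_hbz_table(southpunjab_reference()))
#' @export
format_hbz_table <- function(hbz) {
  stopifnot(inherits(hbz, "hbz_table"))
  zones <- hbz_zones()
  keys <- unique(hbz[, c("sex", "age")])
  plus1 <- function(x) (round(x * 100) + 1) / 100  # next 2-dp display unit
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    r <- hbz[hbz$sex == keys$sex[i] & hbz$age == keys$age[i], ]
    r <- r[match(zones, r$zone), ]
    lowers <- c(r$lower[1], plus1(r$upper[1:4]))
    bands <- c(paste0(fmt_fixed(lowers[1:4], 2), "–",
                      fmt_fixed(r$upper[1:4], 2)),
               paste0("≥", fmt_fixed(lowers[5], 2)))
    stats::setNames(
      data.frame(keys$sex[i], keys$age[i], t(bands), stringsAsFactors = FALSE),
      c("sex", "age", "very_poor", "poor", "medium", "good", "excellent"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an HBZ table as CSV
#'
#' Machine form: columns `sex`, `age`, `zone`, `lower`, `upper` (empty
#' upper for Excellent), full precision.
#'
#' @param hbz An `hbz_table`.
#' @param path File path.
#' @return `write_hbz_csv()` returns `path` invisibly; `read_hbz_csv()`
#'   an `hbz_table`.
#' @export
write_hbz_csv <- function(hbz, path) {
  out <- as.data.frame(hbz)
  out$upper[is.infinite(out$upper)] <- NA
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_hbz_csv
#' @param scheme Scheme label to attach on read.
#' @export
read_hbz_csv <- function(path, scheme = "table6") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$upper[is.na(df$upper)] <- Inf
  structure(df, class = c("hbz_table", "data.frame"), scheme = scheme)
}
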