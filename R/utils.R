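## small shared helpers

# round half up (away from zero for positive x) to `digits` decimals; base
# round() uses banker's rounding, which published percentage tables do not
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# fixed-point formatting, decimal point, no scientific notation
fmt_fixed <- function(x, digits = 2)
  formatC(round_half_up(x, digits), format = "f", digits = digits)

# normalize Unicode minus / dashes in numeric text to ASCII hyphen-minus
normalize_minus <- function(x) {
  x <- gsub("−", "-", x)   # minus sign
  gsub("–", "-", x)        # en dash
}

.sexes <- c("boys", "girls")

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% .sexes
  if (any(bad))
    stop("unknown sex label(s): ", paste(unique(sex[bad]), collapse = ", "),
         " (expected 'boys'/'girls')")
  sex
}
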