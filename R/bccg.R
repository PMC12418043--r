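## Box-Cox Cole-Green (BCCG) distribution: the three-parameter family behind
## the LMS method.  A positive variable Y follows BCCG(lambda, mu, sigma) when
## its Box-Cox transform z = ((Y/mu)^lambda - 1) / (lambda * sigma)  (lambda != 0)
##                      z = log(Y/mu) / sigma                        (lambda  = 0)
## is standard normal.  mu is the median, sigma the coefficient of variation,
## lambda the skewness power.  The small probability mass the transform would
## place below Y = 0 is ignored, as in standard LMS practice (negligible for
## sigma <= 0.5).

# switch to the log branch below this |lambda|: removes the removable
# singularity at lambda = 0 without precision loss
.BCCG_EPS <- 1e-7

#' Validate an LMS parameter triple
#'
#' Checks and bundles one (lambda, mu, sigma) parameter set of the BCCG
#' distribution, i.e. one row of an LMS reference table: `lambda` the
#' Box-Cox skewness power, `mu` the median (kg, positive), `sigma` the
#' coefficient of variation (positive).
#'
#' @param lambda Skewness power (dimensionless, finite).
#' @param mu Median, must be positive.
#' @param sigma Coefficient of variation, must be positive.
#' @return A list of class `"lms_triple"` with elements `lambda`, `mu`,
#'   `sigma`.
#' @examples
#' lms_triple(-0.004, 25.77, 0.432)
#' @export
lms_triple <- function(lambda, mu, sigma) {
  stopifnot(is.numeric(lambda), is.numeric(mu), is.numeric(sigma))
  if (any(!is.finite(lambda))) stop("'lambda' must be finite")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be positive")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("'sigma' must be positive")
  structure(list(lambda = lambda, mu = mu, sigma = sigma), class = "lms_triple")
}

#' Convert percentile ranks to standard-normal deviates
#'
#' @param p Percentile rank(s) in (0, 100), e.g. 3 for P3.
#' @return Standard-normal quantile(s) of `p / 100`.
#' @examples
#' pct_to_z(c(3, 50, 97))
#' @export
pct_to_z <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 100))
    stop("percentile ranks must lie strictly between 0 and 100")
  stats::qnorm(p / 100)
}

#' @rdname pct_to_z
#' @param z Standard-normal deviate(s).
#' @export
z_to_pct <- function(z) 100 * stats::pnorm(z)

.lms_args <- function(lambda, mu, sigma) {
  if (inherits(lambda, "lms_triple")) {
    tri <- lambda
    lambda <- tri$lambda; mu <- tri$mu; sigma <- tri$sigma
  }
  if (any(!is.finite(lambda))) stop("'lambda' must be finite")
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  list(lambda = lambda, mu = mu, sigma = sigma)
}

#' BCCG quantile (centile) function
#'
#' Evaluates the Cole-Green centile formula
#' \deqn{C(p) = \mu (1 + \lambda \sigma z_p)^{1/\lambda}} for
#' \eqn{\lambda \neq 0} and \eqn{C(p) = \mu e^{\sigma z_p}} at
#' \eqn{\lambda = 0}, with \eqn{z_p} the standard-normal quantile of
#' \eqn{p/100}.  This is the formula every cell of an LMS percentile
#' reference table is computed with.
#'
#' @param p Percentile rank(s) in (0, 100).
#' @param lambda,mu,sigma BCCG parameters (recycled); alternatively pass an
#'   [lms_triple()] as `lambda`.
#' @return Centile value(s), same units as `mu`.
#' @examples
#' bccg_quantile(3, -0.004, 25.77, 0.432)   # P3 for boys aged 13
#' bccg_quantile(50, 0.268, 14.12, 0.279)   # the median is mu
#' @export
bccg_quantile <- function(p, lambda, mu, sigma) {
  a <- .lms_args(lambda, mu, sigma)
  z <- pct_to_z(p)
  n <- max(length(z), length(a$lambda), length(a$mu), length(a$sigma))
  z <- rep_len(z, n)
  lambda <- rep_len(a$lambda, n); mu <- rep_len(a$mu, n); sigma <- rep_len(a$sigma, n)
  out <- numeric(n)
  lg <- abs(lambda) < .BCCG_EPS
  out[lg] <- mu[lg] * exp(sigma[lg] * z[lg])
  if (any(!lg)) {
    base <- 1 + lambda[!lg] * sigma[!lg] * z[!lg]
    if (any(base <= 0))
      stop("percentile undefined for this (lambda, mu, sigma): ",
           "1 + lambda*sigma*z <= 0")
    out[!lg] <- mu[!lg] * base^(1 / lambda[!lg])
  }
  out
}

#' BCCG z-score (the LMS z-score transform)
#'
#' Maps an observed measurement to its standard-normal deviate under the
#' age-specific BCCG parameters:
#' \eqn{z = ((y/\mu)^\lambda - 1)/(\lambda\sigma)} for \eqn{\lambda \neq 0},
#' \eqn{z = \log(y/\mu)/\sigma} at \eqn{\lambda = 0}.  Inverse of
#' [bccg_quantile()] on the z scale.
#'
#' @param y Observed value(s), must be positive.
#' @inheritParams bccg_quantile
#' @return z-score(s); 0 at the median.
#' @examples
#' bccg_zscore(27.62, 0.963, 20.18, 0.286)  # ~= qnorm(0.90)
#' @export
bccg_zscore <- function(y, lambda, mu, sigma) {
  a <- .lms_args(lambda, mu, sigma)
  if (any(!is.finite(y)) || any(y <= 0)) stop("'y' must be positive")
  n <- max(length(y), length(a$lambda), length(a$mu), length(a$sigma))
  y <- rep_len(y, n)
  lambda <- rep_len(a$lambda, n); mu <- rep_len(a$mu, n); sigma <- rep_len(a$sigma, n)
  z <- numeric(n)
  lg <- abs(lambda) < .BCCG_EPS
  z[lg] <- log(y[lg] / mu[lg]) / sigma[lg]
  z[!lg] <- ((y[!lg] / mu[!lg])^lambda[!lg] - 1) / (lambda[!lg] * sigma[!lg])
  z
}

#' BCCG log-density
#'
#' Log of the BCCG density, assembled from the Gaussian kernel in the
#' Box-Cox z-score and the Jacobian of the transform:
#' \deqn{\log f(y) = (\lambda - 1)\log y - \lambda \log \mu - \log \sigma
#'   + \log \phi(z).}
#' The truncation constant for the mass below \eqn{y = 0} is ignored
#' (standard LMS approximation, negligible for \eqn{\sigma \le 0.5}).
#'
#' @inheritParams bccg_zscore
#' @return Log-density value(s).
#' @export
bccg_logdensity <- function(y, lambda, mu, sigma) {
  a <- .lms_args(lambda, mu, sigma)
  if (any(!is.finite(y)) || any(y <= 0)) stop("'y' must be positive")
  n <- max(length(y), length(a$lambda), length(a$mu), length(a$sigma))
  y <- rep_len(y, n)
  lambda <- rep_len(a$lambda, n); mu <- rep_len(a$mu, n); sigma <- rep_len(a$sigma, n)
  z <- bccg_zscore(y, lambda, mu, sigma)
  (lambda - 1) * log(y) - lambda * log(mu) - log(sigma) +
    stats::dnorm(z, log = TRUE)
}

#' @rdname bccg_logdensity
#' @export
bccg_density <- function(y, lambda, mu, sigma)
  exp(bccg_logdensity(y, lambda, mu, sigma))

#' BCCG cumulative distribution function
#'
#' @inheritParams bccg_zscore
#' @return `P(Y <= y)` under the (untruncated) BCCG model.
#' @export
bccg_cdf <- function(y, lambda, mu, sigma)
  stats::pnorm(bccg_zscore(y, lambda, mu, sigma))

# valid percentile range for a triple: for lambda > 0 the transform bounds z
# below at -1/(lambda*sigma); for lambda < 0 it bounds z above.  Returns the
# (open) interval of attainable cumulative probabilities.
.bccg_prange <- function(lambda, mu, sigma) {
  lo <- ifelse(lambda >= .BCCG_EPS, stats::pnorm(-1 / (lambda * sigma)), 0)
  hi <- ifelse(lambda <= -.BCCG_EPS, stats::pnorm(-1 / (lambda * sigma)), 1)
  cbind(lo = lo, hi = hi)
}
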