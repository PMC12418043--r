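## Penalized-likelihood LMS fit: smooth age-dependent curves L(t), M(t), S(t)
## for one sex, estimated by maximizing the BCCG log-likelihood with the
## flexibility of each curve controlled by its effective degrees of freedom
## (edf).  The smoother is a cubic regression spline on age: edf = 1 gives a
## constant, edf = 2 a linear trend, edf >= 3 a natural cubic spline with
## edf - 1 basis columns, so each curve spends exactly its edf.  Links are
## identity for lambda and log for mu and sigma, so predicted triples are
## always valid.  Estimation is outer backfitting across the three curves
## (Cole-Green style): each outer cycle re-maximizes the likelihood over one
## curve's coefficients at a time (BFGS), so the deviance never increases
## across cycles.

.SIGMA_FLOOR <- 1e-4  # lower bound on sigma: keeps degenerate cohorts finite

#' Fitting configuration for the LMS estimator
#'
#' @param edf_lambda,edf_mu,edf_sigma Effective degrees of freedom per
#'   curve (>= 1 each; 1 = constant, 2 = linear, k = cubic spline with
#'   k - 1 basis columns).  Defaults (3, 4, 3) leave every curve below
#'   saturation on a 5-point age grid while allowing the curvature and
#'   non-monotonicity that adolescent strength references exhibit in the
#'   skewness and coefficient-of-variation profiles.
#' @param max_outer_iter Maximum outer backfitting cycles.
#' @param tol Convergence tolerance on the change in deviance between
#'   outer cycles.
#' @param fix_lambda Optional numeric: freeze the skewness power at this
#'   value instead of estimating it (e.g. 1 for a Gaussian fit).
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(edf_lambda = 3, edf_mu = 4, edf_sigma = 3,
                       max_outer_iter = 50, tol = 1e-6, fix_lambda = NULL) {
  edf <- c(lambda = edf_lambda, mu = edf_mu, sigma = edf_sigma)
  if (any(edf < 1)) stop("each edf must be >= 1")
  if (tol <= 0) stop("'tol' must be positive")
  if (!is.null(fix_lambda)) stopifnot(is.numeric(fix_lambda), is.finite(fix_lambda))
  structure(list(edf = edf, max_outer_iter = max_outer_iter, tol = tol,
                 fix_lambda = fix_lambda),
            class = "fit_config")
}

# cubic regression spline design on age for a given edf; knots computed from
# the data on first call, then reused for prediction
spline_basis <- function(age, edf, spec = NULL) {
  if (is.null(spec)) {
    ux <- sort(unique(age))
    if (edf > length(ux))
      stop("edf ", edf, " exceeds the number of distinct ages (", length(ux), ")")
    spec <- list(edf = edf, boundary = range(ux))
    if (edf >= 3) {
      # interior knots at interior quantiles of the distinct ages
      probs <- seq(0, 1, length.out = edf)[-c(1, edf)]
      spec$knots <- as.numeric(stats::quantile(ux, probs, type = 7))
    } else {
      spec$knots <- numeric(0)
    }
  }
  edf <- spec$edf
  X <- if (edf == 1) {
    matrix(1, length(age), 1)
  } else if (edf == 2) {
    cbind(1, age - mean(spec$boundary))
  } else {
    cbind(1, splines::ns(age, knots = spec$knots,
                         Boundary.knots = spec$boundary))
  }
  list(X = unname(X), spec = spec)
}

# negative log-likelihood of the whole cohort given the three coefficient
# vectors and their design matrices
.lms_negll <- function(y, Xl, Xm, Xs, cl, cm, cs) {
  lambda <- drop(Xl %*% cl)
  mu <- exp(drop(Xm %*% cm))
  sigma <- pmax(exp(drop(Xs %*% cs)), .SIGMA_FLOOR)
  ll <- bccg_logdensity(y, lambda, mu, sigma)
  if (any(!is.finite(ll))) return(1e10)
  -sum(ll)
}

#' Fit smooth LMS curves to a single-sex cohort
#'
#' Maximum-likelihood estimation of the age-dependent BCCG parameters
#' lambda(t), mu(t), sigma(t) from individual handgrip measurements, by
#' outer backfitting over the three curves.  Deviance (-2 log-likelihood)
#' is non-increasing across outer cycles; convergence is declared when the
#' change falls below `config$tol`.
#'
#' @param cohort Data frame with columns `age` (years) and `hgs_abs_kg`
#'   (> 0); must contain a single sex (column `sex`, optional).
#' @param config A [fit_config()].
#' @param sex Sex label recorded in the model when `cohort` has no `sex`
#'   column.
#' @return An object of class `"lms_model"`: coefficient vectors and spline
#'   specifications per curve, link labels, age domain, and `fit` statistics
#'   (`converged`, `iterations`, `deviance`, `deviance_trace`, `n`).
#' @seealso [predict_lms()], [select_edf()], [write_lms_model()]
#' @export
fit_lms <- function(cohort, config = fit_config(), sex = NULL) {
  stopifnot(is.data.frame(cohort), "age" %in% names(cohort),
            "hgs_abs_kg" %in% names(cohort))
  if (!is.null(cohort$sex)) {
    sx <- unique(check_sex(cohort$sex))
    if (length(sx) > 1)
      stop("fit_lms() fits one sex at a time; got: ", paste(sx, collapse = ", "))
    sex <- sx
  }
  y <- cohort$hgs_abs_kg
  age <- as.numeric(cohort$age)
  if (any(!is.finite(y)) || any(y <= 0)) stop("all HGS values must be positive")
  ages <- sort(unique(age))
  if (length(ages) < 2) {
    warning("single age group: smoothing disabled, fitting constant triples")
    config$edf[] <- 1
  }
  per_age_n <- table(age)
  if (any(per_age_n < 30))
    warning("fewer than 30 records in some age group(s): ",
            paste(names(per_age_n)[per_age_n < 30], collapse = ", "))
  edf <- pmin(config$edf, length(ages))
  if (any(edf != config$edf))
    warning("edf reduced to the number of distinct ages")

  bl <- spline_basis(age, edf["lambda"])
  bm <- spline_basis(age, edf["mu"])
  bs <- spline_basis(age, edf["sigma"])

  # initialization: lambda0 = 1; mu0 from per-age medians; sigma0 from a
  # per-age IQR-based coefficient of variation (robust, scale-free)
  med <- tapply(y, age, stats::median)
  iqr <- tapply(y, age, stats::IQR)
  cv <- pmax(iqr / (1.349 * med), 10 * .SIGMA_FLOOR)
  amed <- as.numeric(names(med))
  if (length(amed) > 1) {
    mu_i <- stats::approx(amed, as.numeric(med), age, rule = 2)$y
    s_i <- stats::approx(amed, as.numeric(cv), age, rule = 2)$y
  } else {
    mu_i <- rep(as.numeric(med), length(age))
    s_i <- rep(as.numeric(cv), length(age))
  }
  cl <- qr.coef(qr(bl$X), rep(1, length(y)))
  cm <- qr.coef(qr(bm$X), log(mu_i))
  cs <- qr.coef(qr(bs$X), log(s_i))
  cl[is.na(cl)] <- 0; cm[is.na(cm)] <- 0; cs[is.na(cs)] <- 0
  if (!is.null(config$fix_lambda)) {
    cl <- c(config$fix_lambda, rep(0, ncol(bl$X) - 1))
  }

  dev <- 2 * .lms_negll(y, bl$X, bm$X, bs$X, cl, cm, cs)
  trace <- dev
  converged <- FALSE
  iter <- 0
  opt1 <- function(par, fn) {
    if (length(par) == 1L)
      stats::optim(par, fn, method = "Brent",
                   lower = par - 20, upper = par + 20)$par
    else
      stats::optim(par, fn, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12))$par
  }
  for (iter in seq_len(config$max_outer_iter)) {
    if (is.null(config$fix_lambda))
      cl <- opt1(cl, function(p) .lms_negll(y, bl$X, bm$X, bs$X, p, cm, cs))
    cm <- opt1(cm, function(p) .lms_negll(y, bl$X, bm$X, bs$X, cl, p, cs))
    cs <- opt1(cs, function(p) .lms_negll(y, bl$X, bm$X, bs$X, cl, cm, p))
    dev_new <- 2 * .lms_negll(y, bl$X, bm$X, bs$X, cl, cm, cs)
    trace <- c(trace, dev_new)
    if (abs(dev - dev_new) < config$tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged)
    warning("fit_lms() did not converge in ", config$max_outer_iter,
            " outer cycles (last deviance change ",
            format(abs(diff(utils::tail(trace, 2)))), ")")

  structure(list(
    sex = sex,
    age_domain = range(ages),
    edf = edf,
    links = c(lambda = "identity", mu = "log", sigma = "log"),
    coef = list(lambda = unname(cl), mu = unname(cm), sigma = unname(cs)),
    basis = list(lambda = bl$spec, mu = bm$spec, sigma = bs$spec),
    fix_lambda = config$fix_lambda,
    fit = list(converged = converged, iterations = iter, deviance = dev,
               deviance_trace = trace, n = length(y))
  ), class = "lms_model")
}

#' Predict LMS triples from a fitted model
#'
#' @param model An `lms_model` from [fit_lms()].
#' @param age Ages (years) at which to evaluate the curves; ages outside
#'   the fitted domain are extrapolated with a warning.
#' @return A data frame with columns `age`, `lambda`, `mu`, `sigma`.
#' @export
predict_lms <- function(model, age) {
  stopifnot(inherits(model, "lms_model"))
  age <- as.numeric(age)
  if (any(age < model$age_domain[1]) || any(age > model$age_domain[2]))
    warning("extrapolating outside the fitted age domain [",
            model$age_domain[1], ", ", model$age_domain[2], "]")
  lam <- drop(spline_basis(age, spec = model$basis$lambda)$X %*% model$coef$lambda)
  mu <- exp(drop(spline_basis(age, spec = model$basis$mu)$X %*% model$coef$mu))
  sigma <- pmax(exp(drop(spline_basis(age, spec = model$basis$sigma)$X %*%
                           model$coef$sigma)), .SIGMA_FLOOR)
  data.frame(age = age, lambda = lam, mu = mu, sigma = sigma)
}

#' @export
print.lms_model <- function(x, ...) {
  cat("LMS curve model", if (!is.null(x$sex)) paste0("(", x$sex, ")"), "\n")
  cat("  age domain:", x$age_domain[1], "-", x$age_domain[2], "years\n")
  cat("  edf (lambda, mu, sigma):", paste(x$edf, collapse = ", "), "\n")
  cat("  n =", x$fit$n, "; deviance =", format(x$fit$deviance),
      "; converged:", x$fit$converged, "in", x$fit$iterations, "cycles\n")
  invisible(x)
}

#' Select smoothing flexibility by information criterion
#'
#' Fits each candidate edf configuration and returns the one minimizing a
#' BIC-type criterion, deviance + log(n) x total edf.  Ties break to the
#' smallest total edf, then to grid order.  Deterministic given the cohort.
#'
#' @param cohort Single-sex cohort as in [fit_lms()].
#' @param candidates A list of [fit_config()]s, or a data frame with
#'   columns `edf_lambda`, `edf_mu`, `edf_sigma`.
#' @return The selected `fit_config`, with the score table attached as
#'   attribute `"scores"`.
#' @export
select_edf <- function(cohort, candidates) {
  if (is.data.frame(candidates)) {
    candidates <- lapply(seq_len(nrow(candidates)), function(i)
      fit_config(candidates$edf_lambda[i], candidates$edf_mu[i],
                 candidates$edf_sigma[i]))
  }
  if (!length(candidates)) stop("empty candidate grid")
  n <- nrow(cohort)
  scores <- vapply(candidates, function(cfg) {
    fit <- tryCatch(suppressWarnings(fit_lms(cohort, cfg)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$fit$converged) return(c(NA_real_, NA_real_))
    c(fit$fit$deviance + log(n) * sum(fit$edf), sum(fit$edf))
  }, numeric(2))
  bic <- scores[1, ]; total_edf <- scores[2, ]
  if (all(is.na(bic)))
    stop("no candidate converged on this cohort (grid of ",
         length(candidates), ")")
  best <- order(bic, total_edf, seq_along(candidates))[1]
  structure(candidates[[best]],
            scores = data.frame(candidate = seq_along(candidates),
                                bic = bic, total_edf = total_edf))
}

#' Serialize / restore a fitted LMS model as flat text
#'
#' Writes a key/value text file (one `key: value` line per scalar field,
#' comma-separated arrays at full double precision) that restores the model
#' to within 1e-12.
#'
#' @param model An `lms_model`.
#' @param path File path.
#' @return `write_lms_model()` returns `path` invisibly;
#'   `read_lms_model()` returns the restored `lms_model`.
#' @export
write_lms_model <- function(model, path) {
  stopifnot(inherits(model, "lms_model"))
  num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = ",")
  lines <- c(
    "format: hgsref-lms-model-1",
    paste0("sex: ", if (is.null(model$sex)) "" else model$sex),
    paste0("age_domain: ", num(model$age_domain)),
    paste0("edf: ", num(model$edf)),
    paste0("fix_lambda: ", if (is.null(model$fix_lambda)) "" else num(model$fix_lambda)),
    paste0("converged: ", model$fit$converged),
    paste0("iterations: ", model$fit$iterations),
    paste0("deviance: ", num(model$fit$deviance)),
    paste0("n: ", model$fit$n)
  )
  for (par in c("lambda", "mu", "sigma")) {
    sp <- model$basis[[par]]
    lines <- c(lines,
      paste0("coef_", par, ": ", num(model$coef[[par]])),
      paste0("boundary_", par, ": ", num(sp$boundary)),
      paste0("knots_", par, ": ", if (length(sp$knots)) num(sp$knots) else ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lms_model
#' @export
read_lms_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(lines, function(l) sub("^[^:]+: ?", "", l), "",
                 USE.NAMES = FALSE)
  get <- function(k) vals[match(k, keys)]
  nums <- function(k) {
    v <- get(k)
    if (is.na(v) || v == "") numeric(0) else as.numeric(strsplit(v, ",")[[1]])
  }
  if (!identical(get("format"), "hgsref-lms-model-1"))
    stop("not an hgsref LMS model file: ", path)
  edf <- nums("edf"); names(edf) <- c("lambda", "mu", "sigma")
  basis <- list(); coef <- list()
  for (par in c("lambda", "mu", "sigma")) {
    basis[[par]] <- list(edf = unname(edf[par]),
                         boundary = nums(paste0("boundary_", par)),
                         knots = nums(paste0("knots_", par)))
    coef[[par]] <- nums(paste0("coef_", par))
  }
  fl <- nums("fix_lambda")
  structure(list(
    sex = if (get("sex") == "") NULL else get("sex"),
    age_domain = nums("age_domain"),
    edf = edf,
    links = c(lambda = "identity", mu = "log", sigma = "log"),
    coef = coef,
    basis = basis,
    fix_lambda = if (length(fl)) fl else NULL,
    fit = list(converged = as.logical(get("converged")),
               iterations = as.integer(get("iterations")),
               deviance = nums("deviance"),
               deviance_trace = NULL,
               n = as.integer(get("n")))
  ), class = "lms_model")
}
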