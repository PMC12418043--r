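---
title: "Building LMS reference standards and Health Benefit Zones for handgrip strength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building LMS reference standards and Health Benefit Zones for handgrip strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgsref)
```

## The problem and the model

Adolescent handgrip strength (HGS) is positive, right-skewed, and changes
rapidly and non-linearly between ages 12 and 16, with a widening gap
between boys and girls. A usable reference standard therefore cannot be a
mean ± SD band; it needs age- and sex-conditional centiles from a
distribution flexible enough to carry age-varying skewness.

`hgsref` uses the LMS formulation: at age $t$ the measurement $Y$ follows
the Box–Cox Cole–Green (BCCG) distribution with parameters
$\lambda(t)$ (Box–Cox skewness power), $\mu(t)$ (median, kg) and
$\sigma(t)$ (coefficient of variation). The transform

$$ z = \frac{(Y/\mu)^{\lambda} - 1}{\lambda\sigma} \quad (\lambda \neq 0),
\qquad z = \frac{\log(Y/\mu)}{\sigma} \quad (\lambda = 0) $$

is standard normal, so the $100\alpha$ centile is
$C_\alpha(t) = \mu(t)\,\bigl(1 + \lambda(t)\sigma(t) z_\alpha\bigr)^{1/\lambda(t)}$
and a measurement converts to a z-score by the inverse map. Three
assumptions matter in practice:

* **Within-age BCCG shape.** Three parameters per age capture location,
  relative spread and skewness but not kurtosis; no four-parameter (BCT /
  BCPE) extension is attempted.
* **Smoothness in age.** $\lambda$, $\log\mu$ and $\log\sigma$ vary
  smoothly with age; log links guarantee $\mu, \sigma > 0$ at any age.
* **Truncation ignored.** The BCCG formally places a small probability
  mass where $1 + \lambda\sigma z \le 0$; for $\sigma \le 0.5$ (all ages
  here) that mass is far below $10^{-4}$ and the likelihood omits the
  normalizing constant, as is standard for LMS work. The synthetic
  generator restricts its uniform draws to the attainable probability
  range, which is the matching sampling-side convention.

## Estimation

`fit_lms()` maximizes the BCCG log-likelihood of a single-sex cohort over
the coefficients of three spline curves by **outer backfitting**: each
cycle re-maximizes over one curve's coefficients at a time (BFGS; Brent
for one-dimensional curves) holding the other two fixed. Because every
inner step starts from the current value, the deviance
($-2\log L$) is non-increasing across cycles; convergence is declared
when successive cycles change it by less than `tol` ($10^{-6}$ by
default, `max_outer_iter = 50`). Initialization is robust and
scale-free: $\lambda_0 = 1$, $\mu_0$ from interpolated per-age medians,
$\sigma_0$ from per-age IQR-based coefficients of variation
(IQR / (1.349 · median)).

The smoother is a cubic regression spline in age whose flexibility is the
curve's **effective degrees of freedom** (edf): 1 = constant, 2 = linear,
$k \ge 3$ = natural cubic spline with $k-1$ basis columns and interior
knots at quantiles of the distinct ages. With measurements at five
integer ages, edf = 5 reproduces a per-age (discrete) fit, so both the
continuous and the discrete reading of "age group" are available.

**Default edf = (3, 4, 3)** for $(\lambda, \mu, \sigma)$. On a five-point
age grid this leaves every curve below saturation while permitting what
adolescent strength references actually exhibit: a visibly curved
skewness profile and a non-monotone coefficient of variation. In
repeated-seed recovery runs on cohorts simulated from the shipped
reference parameters (300 records per age), constant-or-linear choices
for $\lambda$ and $\sigma$ left systematic boundary bias in $\hat\mu$ at
age 16 of 2–3 % — larger than sampling error — whereas (3, 4, 3) keeps
the median absolute error of $\hat\mu$ under 2 %, of $\hat\sigma$ under
6 %, and of $\hat\lambda$ under 0.12 at every age. `select_edf()` offers
a data-driven alternative: it scores a candidate grid by a BIC-type
criterion, deviance $+ \log(n) \times$ total edf, breaking ties toward
the smallest total edf and then grid order.

Degenerate inputs are handled explicitly: a single-age cohort refuses
smoothing and fits constant parameters; a zero-variance cohort drives
$\hat\sigma$ to a floor of $10^{-4}$ (the lower bound that keeps the
likelihood finite) with $\hat\mu$ at the common value; strata under 30
records and out-of-domain prediction warn rather than fail. The
$\lambda \to 0$ removable singularity is switched to the log branch below
$|\lambda| = 10^{-7}$; the two branches agree to better than $10^{-6}$
relative at the threshold. All normal quantiles are computed at full
double precision — the published percentile cells do not reproduce under
the rounded 1.88/1.28-style constants.

## From curves to tables, zones and validation

`build_reference_table()` evaluates the centile formula at the percentile
set {3, 10, 35, 50, 65, 90} by default — the set the shipped reference
tables realize — rather than the {3, 10, 50, 90, 97} set sometimes quoted
for LMS work; any set in (0, 100) is accepted. Cells are kept at full
precision and rounded (2 dp for kg, 3 dp for L and S) only at CSV
serialization, so Health Benefit Zone edges never compound rounding.

`build_hbz_table()` supports two banding schemes because the shipped
standard describes its zones in two mutually inconsistent ways:

* **`"table6"` (default):** edges at P3/P10/P35/P65/P90, the edges the
  published cut-off table actually realizes. Counting the open tails, the
  nominal zone masses are 10/25/30/25/10 %, and the published population
  distribution (11.1/22.5/32.7/24.6/9.2 %) is consistent with them.
* **`"section27"`:** the verbal definition (Very Poor < P3, Medium =
  P10–P50, Good = P50–P90), nominal masses 3/7/40/40/10 %, which the
  published population shares contradict.

The package implements both and adjudicates nothing; the default merely
follows the numbers. Classification is total and deterministic:
closed-below/open-above intervals at full precision, values below the
lowest edge Very Poor (the published table leaves sub-P3 values formally
unassigned; a classifier must not), values at or above P90 Excellent.
Display serialization reproduces the published band-string convention —
each zone's printed lower bound is the zone below's upper bound plus one
display unit (0.01 kg) — and zone percentages are rounded half-up to one
decimal, matching the published table formatting.

`run_backgeneration()` is the internal cross-validation: a stratified
random holdout (per-stratum sizes rounded half-up; default fraction 0.2 —
the original description says only "a small data set", so the fraction is
configurable and recorded in every report), an LMS refit on each set, and
per-age comparison of holdout-fitted to full-sample P50 values. The
score is deliberately a **signed** mean relative error despite the MAPE
name, because the published validation table prints signed rows and
signed averages; the absolute value enters only when banding the average
(< 10 % highly accurate, 10–20 % good, 20–50 % reasonable, > 50 %
inaccurate, boundaries to the better band). The default denominator is
the *fitted* value: $(a - f)/f$ reproduces both published block averages
exactly at 3 dp (−0.007 male, 0.012 female) where the actual-denominator
variant (available via `convention = "actual"`) does not. Whether the
original "fitted" medians came from a holdout refit or from raw holdout
medians is not recorded in the source; refitting is the default and
`medians = "raw"` the flag.

## What the synthetic cohort generator does and does not emulate

`generate_cohort()` exists so that every stage is testable without raw
data, which were never deposited. Its defaults **are** the study
conditions: 10 age × sex strata with the published per-stratum sizes,
HGS drawn from the BCCG model at the published (L, M, S) per stratum,
heights and weights lognormal with the stratum's published median and a
log-scale spread solved so the IQR matches the published IQR, BMI derived
as weight/height², and left/right hand maxima split around the absolute
HGS by a zero-centred Gaussian half-difference (SD 1 kg, truncated to
keep both hands positive) — the published protocol defines absolute HGS
as the mean of the two hand maxima but reports no asymmetry data, so
1 kg is a scaffolding choice, not an estimate. The published per-stratum
sizes sum to one girl fewer than the published margins (1,493 girls,
2,970 total); `default_spec()` adds that record to the smallest girls
stratum (age 14) so the margins reproduce.

Two features of real data are deliberately **not** emulated: the joint
distribution of HGS with body size (no correlation coefficients are
published; strata are independent by default, with an optional
Gaussian-copula `couple` knob for demonstrations) and the survey's
school-level clustering and ~1 % exclusion process. Passing tests on
generated cohorts therefore certify the estimator and the pipeline under
the published marginal model — not robustness to clustering, measurement
protocol, or body-size confounding in real survey data.

## Verification scale and known limitations

The test suite runs the heavy checks at sizes chosen to balance
statistical resolution against desk-scale runtime, stated here as the
package's own choices: parameter recovery uses 20 seeds per sex at 300
records per age; distributional fidelity uses a Kolmogorov–Smirnov check
on $10^5$ draws (D < 0.01); zone-mass convergence uses $10^5$ generated
records (shares within ±0.5 points of nominal); the end-to-end
back-generation check uses full default cohorts at multiple seeds. All
stochastic tests fix explicit seeds; fitting itself is deterministic.

Known limitations. (1) The shipped printed reference contains an internal
inconsistency that `reconstruct_and_diff()` flags: the girls' age-12 and
age-13 P10 cells (9.59 / 9.69 kg) are each reproduced by the *other*
row's (L, M, S) — a transposition in the printed table. All 58 remaining
cells reconstruct to within 0.016 kg, the drift expected from
3-decimal-rounded parameters; the two flagged cells differ by ~0.1 kg,
and the published cut-off bands inherit the same two values. The package
ships the table as printed and lets the diff harness document the
discrepancy. (2) Age is modelled at the integer values the reference
reports; no mid-year offset is applied, and within-year growth is not
resolved. (3) No external-cohort validation is possible — none was
published — so the back-generation machinery measures internal
consistency only. (4) The sampling-weight, clustering and covariate
adjustments a full survey analysis might make are out of scope: age and
sex are the only covariates.
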