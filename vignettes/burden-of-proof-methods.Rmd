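---
title: "Methods: constrained ensemble dose-response meta-regression and the burden-of-proof summary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained ensemble dose-response meta-regression and the burden-of-proof summary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bopmeta)
```

This vignette is the package's own account of its model, the choices behind
it, and what the validation suite does and does not establish. The running
example is the systolic blood pressure (SBP, mm Hg) to ischemic heart
disease relationship, but every component is generic over harmful or
protective exposures observed over ranges.

## The observation model

Each row of a study table is one comparison: a log relative effect
$y_i$ with standard error $s_i$, a reference exposure range
$[a_i^{ref}, b_i^{ref}]$ and an alternative range $[a_i^{alt}, b_i^{alt}]$.
Cohort rows carry published category bounds (open-ended categories such as
"<115" are closed to a plausible window, by default 100–200 mm Hg); trial
rows carry the observed arm means as degenerate ranges. The mean log-RR
curve $f$ enters the likelihood through exact range averages,

$$ y_i \sim N\!\big(\overline f(alt_i) - \overline f(ref_i),\; s_i^2\big),
  \qquad \overline f([a,b]) = \tfrac1{b-a}\int_a^b f(x)\,dx, $$

so a comparison of wide categories is not treated as a comparison of their
midpoints. The study table also carries 0/1 *bias covariates*: study
attributes that may modify the true effect (`alpha` class), bias the
measurement (`beta` class), or alter heterogeneity (`gamma_class`,
accepted in the schema but only logged — heterogeneity modification is out
of scope).

## Curve family and constraints

$f$ is a quadratic spline with two interior knots and linear tails,
represented through its derivative: $g$ is continuous and piecewise linear
with node values at the knots, and $f(x) = \int_{x_{min}}^x g(u)\,du$. The
representation buys three things at once:

* **Monotonicity is a bound constraint.** $f$ is non-decreasing exactly
  when every node value of $g$ is nonnegative — no derivative grid is
  needed, the constraint is exact.
* **Linear tails are parameter ties.** A tail segment is linear exactly
  when its two end nodes of $g$ coincide.
* **Range averages are closed-form.** $f$ is piecewise quadratic, so
  per-piece Simpson integration of the design rows is exact.

The fit domain runs from the smallest reported range lower bound to the
largest upper bound — the smallest domain on which every range average is
defined — and the curve (and its variance) is anchored to zero there.
Reporting relative to another reference (100 mm Hg by default) is post-hoc
re-anchoring, exact on the log scale, which is why
`predict_rr(c, x2, x0) = predict_rr(c, x2, x1) * predict_rr(c, x1, x0)`
holds identically.

The *right-tail derivative prior* is a zero-mean Gaussian with sd 0.001
(log-RR per mm Hg) on the derivative of the right linear tail. It is a
deliberate flatness bias: where data thin out at high exposures, the fitted
curve flattens rather than extrapolating the last trend. Its precision
($10^6$) exceeds the information a moderately sized table carries about
the tail slope, so it visibly bends fits at the top of the exposure range —
that is its job, and it is also why parameter-recovery experiments (below)
disable it.

With bounds as the only constraints, the penalized weighted least-squares
problem is solved exactly by active-set enumeration over the at most
$2^4$ sign patterns of the free derivative nodes, checking primal
feasibility and the KKT gradient conditions. This is immune to the extreme
weight scales ($1/s_i^2$ up to $10^{20}$) that arise in noise-free test
fixtures, where iterative solvers lose precision.

## Trimming

Ten percent of rows are trimmed so the curve fits the 90% most coherent
data: with $h = \mathrm{round}(0.9\,n)$, the fit alternates concentration
steps — fit on the current inlier set, rank all rows by standardized
residual $|y_i - \hat y_i|/s_i$, keep the $h$ best — and returns the
visited size-$h$ set with the highest trimmed likelihood. On small tables
this is verified against exhaustive subset search. Two properties matter
downstream:

* exactly $n - \mathrm{round}(0.9n)$ rows get weight 0, and planted
  outliers (additive log-RR shifts) are the rows removed;
* trimming *clean* data truncates the residual distribution: a variance
  estimated from the inliers of an uncontaminated table is deflated by
  roughly the truncated-normal second moment (~40%). The heterogeneity
  recovery experiment therefore runs untrimmed; in the full pipeline,
  trimming defends against contamination, which is what the generator
  plants.

## The knot ensemble

Robustness to knot placement comes from 50 members with interior knots
drawn uniformly over the 10th–90th percentile band of pooled arm midpoints,
rejection-sampled to keep knots at least 10 mm Hg apart. Member weights
combine fit and smoothness,

$$ w_m \propto e^{-BIC_m/2} \cdot \frac{1}{1 + TV_m}, $$

where $BIC_m = -2\ell_m + p\log h$ on the member's trimmed likelihood and
$TV_m$ is the maximum absolute highest-order derivative (the slope of $g$).
The exponential likelihood weight is sharp — a clearly best-fitting knot
placement dominates — and the total-variation factor breaks ties toward
smoother members. The ensemble mean is the weighted member mean
(re-anchored at zero), and the fixed-effects variance combines the
within-member coefficient covariance with the between-member dispersion;
both are zero at the anchor by construction. The weighting formula is a
package choice (the combination rule behind "likelihood metric plus total
variation" admits alternatives); it is isolated in one place and the
ROS/star logic downstream is independent of it.

## Bias-covariate selection

Candidates are ranked by a weighted Lasso path (`glmnet`): observations
weighted $1/s_i^2$, the curve-predicted signal as a fixed offset,
standardized covariates, no intercept; the entry order along the decreasing
penalty path orders covariates from most to least impactful. Ranked
covariates are then added one at a time to a weighted linear
meta-regression of $y$ on the signal (free coefficient) plus the accepted
covariates; a covariate is retained when its t statistic is significant at
the configured level with $df = n_{studies} - n_{parameters}$ — the
study-count correction guards against over-selection when rows outnumber
studies. Standard errors use the estimated residual dispersion of the
weighted regression: under unmodeled heterogeneity this is conservative,
and it is what keeps the type-I error of the selection near nominal in the
null simulations. Selected `beta`-class effects are subtracted from the
observations (and `alpha`-class interactions divided out of the signal
term) before one final curve refit.

## Between-study heterogeneity and conservative uncertainty

Given the fitted curve (and any selected covariates), the residual of each
untrimmed row is modeled with an additive study-level random effect shared
across a study's rows: for study $s$,
$r_s \sim N(0, \mathrm{diag}(s_i^2) + \gamma\,\mathbf{1}\mathbf{1}^\top)$.
The marginal likelihood is evaluated in closed form (Woodbury identity) and
maximized over $\gamma \ge 0$; $se_\gamma$ is the inverse square root of
the observed Fisher information at the optimum. The additive form matches
the generator's planted random effects and the funnel plot's
$\sqrt{s_i^2 + \gamma}$ axis; the "random-slope" geometry — heterogeneity
scaling along the curve rather than uniformly — enters in the uncertainty
construction instead:

$$ sd_{tot}(x) = \sqrt{fixed\_var(x)} +
   \sqrt{\gamma + k\,se_\gamma}\;\frac{|f(x)|}{\max|f|}, $$

with $k = 2$ by default (configurable): the conservative band inflates
$\gamma$ by two standard errors to carry heterogeneity-estimation
uncertainty. $sd_{tot}$ vanishes at the anchor, so all quantile curves pass
through log RR 0 there.

## BPRF, ROS and stars

For a harmful exposure the burden-of-proof risk function is the 5th
quantile curve $f(x) + z_{0.05}\,sd_{tot}(x)$ — the edge of the band
closest to the null; a protective exposure uses the 95th. The direction is
declared, never auto-detected. The risk–outcome score is the average log
BPRF over the 15th–85th percentile band of pooled arm midpoints, computed
on a uniform 0.1-mm Hg grid (interpolated from the 1-mm curve grid so the
average is insensitive to grid phase). `averaged_bprf = exp(ros)` and
`percent_increase = 100(exp(ros) - 1)` hold identically. Stars follow the
threshold table `<0.0 | 0.0–0.14 | >0.14–0.41 | >0.41–0.62 | >0.62` with
upper bounds inclusive in the lower category, exactly as printed.

## Publication-bias diagnostics

The funnel plot shows residuals against $\sqrt{s_i^2 + \gamma}$, trimmed
rows hollow. Egger's test is the classic formulation on model residuals:
ordinary regression of the standardized residual on precision, two-sided t
test of the intercept with $df = n - 2$. Trimmed rows are excluded from
the test but kept in the plot; whether the original analyses included them
is not documented, and exclusion is the choice consistent with "the model
fits the 90% most coherent data". The test suite cross-checks the
implementation against `metafor::regtest` on identical inputs.

## The synthetic generator: what it emulates, what it does not

Defaults mirror the structure of the evidence base this pipeline targets:
41 studies (39 trials, 2 cohorts), exposures in 100–200 mm Hg, trial
reference-arm means centered at 121 mm Hg with alternative arms 5–30 mm Hg
higher, cohort rows built from the category grid
100/115/125/135/145/155/165/175/200 (end categories closed to the window),
one random-effect draw per study, a 10% outlier fraction planted as
additive log-RR shifts (so trimming, not down-weighting, is the correct
remedy), and dummy bias covariates drawn Bernoulli(0.5) per study. Values
the source evidence does not pin down were fixed once as realistic:
`gamma_true = 0.01` (minor heterogeneity), reported SEs uniform on
(0.05, 0.2), outlier shift +1.

What passing recovery tests therefore show: the likelihood machinery,
constraints, trimming, heterogeneity estimation and scoring recover a known
truth under Gaussian noise, study-level shifts, and additive contamination
of the kind planted. What they do not show: robustness to correlated
extraction errors, non-Gaussian effect distributions, exposure-measurement
error, selective reporting within studies, or the information density of a
real pooled-cohort extraction (whose standard errors are far smaller than
the synthetic range — one reason the real analysis can overrule the
right-tail prior where a synthetic table cannot).

## Numerical choices and degenerate inputs

* Range integration: per-piece Simpson on the quadratic pieces — exact, no
  quadrature tolerance. The generator's truth averages use adaptive
  quadrature at relative tolerance $10^{-12}$.
* Percentiles: linear interpolation between order statistics
  (`quantile type 7`), unweighted over both arms' midpoints.
* Trimming ties: ranked by standardized residual, then row order —
  deterministic.
* Ensemble consensus trimming: rows flagged by weighted member vote, ties
  broken by residual then row order, count fixed at the per-member number.
* $\gamma$ at the boundary: the optimizer is clipped at 0; the Fisher
  information is evaluated one-sided just above the boundary.
* Degenerate ranges evaluate the curve pointwise; an all-zero residual set
  short-circuits Egger's test (intercept 0, p = 1); constant covariates are
  excluded from ranking with a warning.
* Seeds: the generator consumes its config seed; `ensemble_fit` seeds knot
  placement; the pipeline sets its config seed once so identical configs
  give byte-identical summaries.

## Choices made where the design was open, and why

* **Recovery oracles run without the right-tail prior.** The prior is an
  informative flatness bias, not likelihood machinery; with it active no
  estimator could recover a steep log-linear truth to the tested tolerances
  at synthetic information levels. Its directional behavior (it shrinks the
  tail derivative, never raises it) is asserted separately.
* **Heterogeneity is additive** (see above); the slope geometry lives in
  the uncertainty construction.
* **Trimming is per ensemble member**, with a consensus set for reporting;
  trimming once before the ensemble would couple knot placement to a fixed
  outlier set.
* **Exposure percentiles are unweighted** by study size — nothing in the
  evidence base's description says otherwise; the sensitivity suite makes
  the band easy to vary.
* **Subset sensitivity runs re-anchor the reference** to the subset's
  domain minimum when the configured reference falls outside it (trial-only
  subsets do not reach 100 mm Hg), mirroring how design-restricted
  reanalyses choose their own reference.

## Problem sizes used by the validation suite

Unit and acceptance tests run the generator at 12–53 studies (200 for
heterogeneity recovery, 1000 for the generator's own variance check),
ensembles of 5–50 members, 500 replicates for the Egger size experiment
and 100 for power, and 10,000 Monte-Carlo draws for the BPRF quantile
oracle. These sizes make the full suite run in well under a minute while
keeping every stochastic tolerance derived from the Monte-Carlo standard
error at that size.

## Known limitations

Gaussian likelihood only; quadratic splines only (the derivative
parametrization generalizes, but degree is fixed at 2); `gamma_class`
covariates are logged, not modeled; J-shaped (mixed harmful/protective)
scoring is out of scope beyond declaring a direction; and the conservative
band's combination rule ($k$, the slope scaling) is one defensible policy
among several — it is config-exposed and the score logic does not depend
on it.
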