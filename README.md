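# bopmeta

Burden-of-proof dose–response meta-analysis for risk–outcome relationships
reported over exposure ranges, built around the systolic blood pressure
(SBP) → ischemic heart disease (IHD) use case: relative risks extracted from
cohorts and trials, each attached to a *reference* and an *alternative*
exposure range in mm Hg.

## What it does

Observations are log relative effects `y_i` (log RR/OR/HR) with standard
errors `s_i`. The mean log-RR curve `f(x)` is a quadratic spline with two
interior knots, linear tails, a monotonicity constraint, and a Gaussian
prior (mean 0, sd 0.001) shrinking the right-tail derivative toward
flatness. Because each observation compares exposure *ranges*, the
likelihood uses exact range integration:

```
y_i ~ N( avg(f; alt_i) - avg(f; ref_i), s_i^2 ),   avg(f; [a,b]) = 1/(b-a) ∫ f
```

Around that core the pipeline provides:

- **Trimming** — a likelihood-based concentration algorithm drops the 10%
  least coherent rows, so the curve fits the 90% most coherent data.
- **Knot ensemble** — 50 fits with random interior-knot placement, combined
  with weights `∝ exp(-BIC/2) / (1 + total variation)`.
- **Bias covariates** — dummy study attributes ranked by a weighted Lasso
  path (signal as offset) and admitted stepwise by a t test with degrees of
  freedom corrected for the number of studies.
- **Between-study heterogeneity** — profile maximum likelihood for the
  variance γ of study-level random effects, with a Fisher-information
  standard error.
- **BPRF / ROS / stars** — the burden-of-proof risk function is the 5th
  quantile curve (for a harmful risk) of the heterogeneity-inclusive
  uncertainty band; the risk–outcome score (ROS) is the average log BPRF
  over the 15th–85th percentile exposure band; the star rating maps ROS via
  `<0.0 | 0.0–0.14 | >0.14–0.41 | >0.41–0.62 | >0.62` to 1–5 stars.
- **Publication-bias diagnostics** — a modified funnel plot of model
  residuals against total s.d. `sqrt(s_i^2 + γ)` and Egger's regression of
  standardized residuals on precision.
- **Synthetic study tables** — a generator with a known true risk curve,
  planted random effects, bias shifts and outliers, so every stage is
  validated by parameter recovery.

## Worked example

```r
library(bopmeta)

truth <- make_true_curve("log_linear", slope = 0.02)   # 2% log-RR per mm Hg
sim   <- simulate_table(truth, sim_config(seed = 7))   # 41 studies, 39 RCT/2 cohort
res   <- run_pipeline(sim$table, pipeline_config(seed = 7))
print(res)
```

```
<bop_result> 53 rows / 41 studies; domain 100-200 mm Hg
  gamma 0.0074 (se 0.0039); Egger p 0.628
  band 107.7-149.4: averaged BPRF 1.661 (+66.10%), ROS 0.507, 4 star(s)
 exposure rr_mean rr_lo_fe rr_hi_fe rr_lo_het rr_hi_het rr_bprf
      110   1.268    1.227    1.310     1.176     1.368   1.190
      115   1.428    1.362    1.497     1.276     1.598   1.299
      120   1.607    1.513    1.708     1.388     1.862   1.421
      130   2.032    1.883    2.192     1.655     2.494   1.711
      140   2.520    2.366    2.684     2.000     3.176   2.076
      150   2.829    2.662    3.007     2.203     3.633   2.294
      165   3.087    2.897    3.291     2.360     4.039   2.464
```

Reading the output: `rr_mean` is the ensemble-mean RR relative to
100 mm Hg (the true value at 120 is `exp(0.4) = 1.49`; the fit sits close,
with the planted outliers trimmed). The `*_fe` columns are the 95% band
from fixed-effects uncertainty only, `*_het` adds between-study
heterogeneity (true γ here is 0.01, estimated 0.0074), and `rr_bprf` is the
conservative quantile curve. Averaging its log over the data-dense band
107.7–149.4 mm Hg gives ROS 0.507 — a 4-star ("large effect, strong
evidence") rating, consistent with the strong planted signal. Neither of
the two inert bias covariates is selected, and Egger's test finds no
asymmetry (p = 0.63), as expected under symmetric simulation.

`run_pipeline(..., out_dir = "results/")` additionally writes `curve.csv`,
`bprf.csv`, `funnel.csv`, `summary.json`, `log.txt` and the three
publication-style figures; `sensitivity_suite()` reruns the analysis with
constraints relaxed, by study design, and under alternative reference
exposures. A thin CLI lives at `inst/cli/bop.R`
(`bop.R simulate|run ...`).

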