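# mogp

Clustering sparse disease-progression trajectories with a mixture of
Gaussian processes.

## What problem this solves

Longitudinal functional scores — the ALSFRS-R total (0–48), its domain
subscores (0–12), percent-predicted forced vital capacity (0–100) — are
the workhorse outcome measures of ALS and other progressive diseases.
They are short, irregularly sampled, noisy and bounded, and clinical
practice usually compresses them into one linear slope per patient even
though real decline is often strongly nonlinear (plateaus followed by
rapid loss, or fast early decline that flattens). `mogp` is for
researchers who want to ask: *are there common patterns of decline, and
what does assuming linearity cost?*

The package clusters patients with similar trajectories and models each
cluster's mean trajectory with uncertainty, using:

* **Gaussian-process regression** per cluster: negative linear mean
  function `m(t) = b + s·t` (`s ≤ 0`) plus a squared-exponential kernel
  `k(t,t') = σ_f² exp(−(t−t')²/2ℓ²)`, so clusters can be linear or
  arbitrarily smooth-nonlinear; the length-scale `ℓ` measures stability
  of progression and `σ_f²` its amplitude;
* **Dirichlet-process clustering** (Chinese-restaurant-process
  conditionals), so the number of clusters is learned from the data;
* clinical inductive bias: an imputed **onset anchor** `(0, y_max)` on
  every trajectory, and a **monotonic admissibility constraint** — a
  subject may only join a cluster whose mean at the subject's first
  visit is not substantially below the observed score.

Alongside the model it ships the field's standard comparators (anchored
patient-specific slope SM, linear-kernel mixture LKM, two-parameter
sigmoid SG), interpolation / right-censored forecasting / cross-cohort
transfer harnesses, Kaplan–Meier survival correspondence with pairwise
logrank + FDR, hypergeometric cluster enrichment, and a synthetic-cohort
generator with ground truth for validation.

## Worked example

Simulate a sparse four-archetype ALSFRS-R cohort (fast linear, slow
linear, sigmoidal "functional cliff", concave; 30 subjects each, ~6
visits over ~2 years, 1.5-point noise), run QC, anchor, fit, and
inspect:

```r
library(mogp)

cohort <- generate_cohort(cohort_spec(), seed = 11)
qc     <- apply_qc_filters(cohort$trajectories)
fit    <- fit_mogp(anchor_cohort(qc$trajectories), seed = 1)
fit
#> <mogp_model> 120 subject(s) in 4 cluster(s) (se kernel, alpha = 1, margin = 5)
#> cluster sizes: 30, 30, 30, 30
#> log joint: -1935.258

cluster_summary(fit)
#>   cluster_id n_members first_year_slope length_scale mean_slope signal_variance
#> 1         C1        30         9.868774    0.3033344 -10.039399      0.05246406
#> 2         C2        30         2.972884   16.9588876  -2.972414      0.00010000
#> 3         C3        30         5.801109    0.5479085 -16.197709     43.82459310
#> 4         C4        30        24.313790    0.5525146 -13.565217     98.84397595
```

The fit recovers the generating structure exactly (adjusted Rand index
1.0 against `cohort$truth`). The summary reads off each cluster's
learned character: C2 is the slow, stable group — first-year decline of
3 points matching its −3 pts/yr template, and an essentially linear fit
(very long length-scale, negligible signal variance). C3 is the sigmoid
group: its first-year slope (5.8 pts/yr) looks mild, but the short
length-scale and large signal variance carry a functional cliff that a
first-year linear extrapolation badly underestimates. C4 is the concave
(fast-early) group with the steepest first-year decline.

Cluster means with 0.95 intervals, survival correspondence, and
enrichment:

```r
cluster_mean_function(fit$clusters$C2, c(0.5, 1, 2))
#>     t     mean          var    lower    upper
#> 1 0.5 46.51332 9.844791e-05 46.49388 46.53277
#> 2 1.0 45.02712 9.844526e-05 45.00767 45.04656
#> 3 2.0 42.05470 9.844802e-05 42.03526 42.07415

records <- derive_survival_records(cohort$trajectories)
pairwise_logrank(fit, records)
#> <pairwise_logrank> 6 evaluable pair(s); 66.7% differential at adjusted p < 0.05
```

Faster-declining clusters have reliably worse survival because the
generator links log survival time to the template's first-year decline.

A shell interface wrapping the same functions is installed at
`inst/scripts/mogp`:

```sh
Rscript inst/scripts/mogp simulate --out sim --seed 11
Rscript inst/scripts/mogp fit --input sim/data.csv --out fit --seed 1
Rscript inst/scripts/mogp evaluate --experiment censor --input sim/data.csv --out eval
```

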