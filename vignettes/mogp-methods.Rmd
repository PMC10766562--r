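---
title: "Modelling disease-progression trajectories with a mixture of Gaussian processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disease-progression trajectories with a mixture of Gaussian processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional rating scales such as the ALSFRS-R (0–48, higher = better
function), its four domain subscores (0–12) and percent-predicted forced
vital capacity (0–100) are the standard longitudinal outcome measures in
ALS and related progressive diseases. Observed series are short (often
3–10 visits), irregularly spaced, noisy, bounded, and start at different
disease stages for different patients. Clinical-trial practice commonly
summarises them with a single linear slope per patient, but real decline
is frequently nonlinear — periods of stability followed by rapid loss
("functional cliffs"), or fast early decline that later flattens.

`mogp` asks whether there are *common patterns* of decline: it clusters
patients whose trajectories look alike, models each cluster's average
trajectory with its uncertainty, and provides the machinery to quantify
how much the nonlinearity matters (benchmarks, interpolation and
forecasting experiments, transfer across cohorts, and survival
correspondence).

## The model

Each cluster $k$ is a Gaussian process over time from symptom onset,

$$ y(t) \sim \mathcal{GP}\!\big(m_k(t),\, k_k(t, t')\big) + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma_{n,k}^2), $$

with a **negative linear mean function** $m_k(t) = b_k + s_k t$,
$s_k \le 0$, and a **squared-exponential kernel**
$k_k(t,t') = \sigma_{f,k}^2 \exp\{-(t-t')^2 / (2\ell_k^2)\}$. The mean
function encodes the prior expectation of monotone decline; the kernel
contributes smooth, possibly nonlinear departures from it. The signal
variance $\sigma_f^2$ sets the typical amplitude of those departures, and
the length-scale $\ell$ sets how stable the trajectory is: small $\ell$
allows rapid changes of pace, large $\ell$ forces near-linear behaviour.
All four free parameters per cluster (signal variance, length-scale,
noise variance, mean slope) are learned from the cluster's pooled member
visits by type-II maximum likelihood; the mean intercept is pinned at the
scale maximum because trajectories are anchored (below).

Cluster membership follows a **Dirichlet-process mixture**: a priori an
unbounded number of clusters may exist, and the data determine how many
are used. The collapsed conditional for a subject is the
Chinese-restaurant-process rule — an existing cluster attracts the
subject with weight proportional to (cluster size) × (predictive
likelihood of the subject's visits under the cluster posterior); a new
cluster is opened with weight proportional to the concentration
$\alpha$ × (prior predictive likelihood).

Three pieces of clinical knowledge are built in:

* **Onset anchor.** Every trajectory receives an imputed observation
  $(0, y_{\max})$ — the maximum score at symptom onset. This puts all
  subjects on a common time origin and regularises sparse fits.
  (`add_onset_anchor()`; a measured visit at exactly $t = 0$ blocks
  anchoring and must be resolved by the caller, since two conflicting
  observations at one timepoint would be ambiguous.)
* **Monotonic admissibility.** A subject may only join a cluster whose
  mean function at the subject's first measured visit is no more than a
  margin below the observed score:
  $y_{\text{first}} \le m_k(t_{\text{first}}) + \text{margin}$. This
  blocks assignments that would require the cluster's declining mean to
  "come back up" to meet the subject. The margin defaults to 5 ALSFRS-R
  points, scaled proportionally for other scales
  ($5\,y_{\max}/48$); `margin = Inf` disables the constraint.
* **Negative mean slope.** The slope of every cluster's mean function is
  constrained non-positive during optimization.

## Inference

`fit_mogp()` runs collapsed Gibbs sampling over assignments interleaved
with per-cluster hyperparameter re-optimization:

1. *Initialization*: subjects enter sequentially via the CRP conditional.
2. Each sweep first re-optimizes every cluster's hyperparameters
   (L-BFGS-B on log variances and length-scale, linear mean slope, warm
   started; the update is accepted only if it does not decrease the
   objective, so the recorded log joint is non-decreasing across
   hyperparameter steps), then resamples every subject's assignment from
   the admissibility-constrained CRP conditional. Empty clusters are
   removed immediately.
3. The **maximum-log-joint state** over the whole trace is returned (not
   the last sweep), which is robust to late-chain wander. The log joint
   is the sum of per-cluster GP marginal likelihoods (plus optional
   hyperparameter log priors) and the exchangeable partition probability.
4. A deterministic **admissibility-repair pass** then re-audits every
   member against its final cluster. Because cluster means move slightly
   as members move and hyperparameters update, a handful of borderline
   members can be left violating the margin by a small amount; each is
   reassigned to the admissible cluster that best explains it (repeat
   offenders go to the cluster with the largest margin slack, which is
   stable, and a fresh singleton is opened if no cluster is admissible).
   `audit_admissibility()` verifies the final model has zero violations.

Fits are deterministic given `(config, seed)`. Sweeps default to 50 with
early stopping after 5 consecutive sweeps without an assignment change;
on well-separated synthetic cohorts convergence typically occurs within
10–20 sweeps.

### Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| `alpha` | 1.0 | neutral CRP concentration; an optional Gamma hyperprior can be resampled by the standard auxiliary-variable scheme |
| `margin` | $5\,y_{\max}/48$ points | "not substantially higher" operationalised at ~10% of the ALSFRS-R range |
| length-scale bounds | 0.05–20 yr | spans abrupt functional cliffs to near-linear decline |
| variance bounds | $10^{-4}$–$y_{\max}^2$ pts² | positivity with room for any clinical amplitude |
| jitter | $10^{-6}\sigma_f^2$ on the training diagonal | numerical safeguard far below score resolution |
| new-cluster hyperparameters | $\sigma_f^2 = (y_{\max}/6)^2$, $\ell = 1$ yr, $\sigma_n^2 = (y_{\max}/24)^2$, slope $-0.15\,y_{\max}$/yr | a mid-range ALS decline (−7.2 ALSFRS-R pts/yr) with moderate amplitude and clinic-scale noise |
| priors (`gp_priors()`) | off unless supplied; log-normal, $\ell$ centred on 1 yr, $\sigma_f^2$ on $(y_{\max}/6)^2$ | weakly-informative hook for clinically informed regularisation |

Scores are modelled on their native scale (no normalisation), so errors
are reported in instrument points.

## Quality control and conventions

`apply_qc_filters()` implements the standard inclusion rules, in order:
at least 3 complete visits; first visit within 7 years of onset; no
increase of more than 6 points between consecutive visits (declines of
any size pass — only implausible improvements suggest data-entry error).
The first failing rule is the one reported. Duplicate visit timestamps
are averaged with a warning: the paper trail for such ties is rarely
recoverable, and averaging is symmetric and deterministic. Time is in
years from symptom onset throughout; readers converting from months or
days do so via the reader's column mapping.

## Benchmarks

* **SM** (`fit_anchored_slope()`): the patient-specific least-squares
  line through the anchor, $\hat s = \sum_i t_i (y_i - y_{\max}) / \sum_i
  t_i^2$ — the field's standard linear summary.
* **LKM** (`fit_lkm()`): the identical mixture engine with the kernel
  swapped for the homogeneous linear kernel $\sigma_f^2\, t\, t'$
  (through the onset origin, consistent with anchoring). Comparing LKM
  with the full model isolates the value of allowing nonlinearity while
  holding the clustering machinery fixed.
* **SG** (`fit_sigmoid()`): the patient-specific two-parameter logistic
  $y(t) = y_{\max} / (1 + \exp\{(t - d_{50})/d_x\})$, fitted by least
  squares over a coarse grid ($d_{50} \in \{0.5,1,2,4,8\}$ yr, $d_x \in
  \{0.1,0.5,1,2\}$ yr, spanning observed ALS progression ranges) with
  box-constrained refinement on log parameters. The logistic is anchored
  at $y_{\max}$; it is fitted on measured visits, the anchor entering
  through the fixed asymptote. Flat (no-decline) series are a ridge in
  this parameterisation — any sufficiently late $d_{50}$ fits equally
  well — so tests assert the fitted curve, not the parameter.

## Evaluation harnesses

Per-patient error is always the RMSE between measured scores and the
predicted trajectory (anchor visits are never scored). For mixture
models the predicted trajectory is the subject's cluster mean function:
the training assignment for in-sample subjects, the predicted membership
(`predict_membership()`, maximum predictive log-likelihood over
admissible clusters, no new cluster at predict time) for held-out
subjects.

* **Interpolation** (`interpolation_experiment()`): 25/50/75% of each
  subject's visits are provided for training (the retained count is
  `round(fraction × n)`, drawn uniformly without forcing the baseline
  visit to be kept — the rounding and baseline conventions are the
  package's choices); error is scored on the withheld visits. Subjects
  need ≥ 10 visits.
* **Forecasting** (`censoring_experiment()`): training uses visits
  within 0.25/0.5/1/1.5/2 years of each subject's *baseline* (first
  measured visit, not onset — horizons follow enrollment); error is
  scored on later visits. Subjects need ≥ 4 visits; those with no
  post-horizon visits are skipped and logged.
* **Transfer** (`transfer_experiment()`): a reference mixture fitted on
  60% of the reference cohort scores each target cohort's held-out 40%,
  against study-specific mixtures and the shuffled-label negative
  control; 5 random splits, paired one-sided Wilcoxon tests, 0.95
  normal-approximation confidence intervals across splits. Membership is
  always predicted afresh for test subjects.
* **Meta-clustering** (`meta_cluster()`): k-means (k = 4 by default) on
  standardized (first-year slope, log length-scale) — the two learned
  parameters that characterise speed and stability — groups mixture
  components into dominant progression modes; labels are ordered by
  slope magnitude. The grouping algorithm is the package's choice.
* **First-year slope** (`first_year_slope()`):
  $(y_{\max} - \text{mean}(1\,\text{yr}))/1\,\text{yr}$, reported as a
  positive decline magnitude — comparing its linear extrapolation with
  the mean function at later times quantifies nonlinearity.
* **Statistics**: KS two-sample two-sided tests for error CDFs; paired
  one-sided Wilcoxon signed-rank for model improvement (identical paired
  samples return p = 1 by convention); hypergeometric upper-tail tests
  for cluster enrichment; Kaplan–Meier curves per cluster with pairwise
  logrank tests and FDR correction (fixed as Benjamini–Hochberg, the
  package's choice of FDR procedure). Pairs with
  fewer than two events are non-evaluable rather than p = 1. Subjects
  with no recorded death are censored at their last recorded visit.

## The synthetic cohort generator

Real ALS registries are access-restricted, so every test and experiment
runs on synthetic cohorts with known ground truth
(`cohort_spec()` / `generate_cohort()`). The generator emulates:

* **cluster structure** via five template shapes — linear, sigmoid
  (logistic), convex and concave power laws, and near-stable decline —
  all monotone non-increasing from the scale maximum;
* **sparse irregular sampling**: a uniform enrollment delay (0.2–1 yr
  from onset by default; the spread matters, because late-enrolling
  subjects carry information about later disease stages that transfers
  to early-enrolled subjects through the cluster), exponential
  inter-visit gaps (default rate 3/yr) and uniform follow-up (1.5–2.5
  yr), redrawn until at least 3 visits exist — roughly 6 visits over 2
  years, matching sparse-clinic regimes;
* **bounded noisy observation**: independent Gaussian noise (default sd
  1.5 points) added before clipping to the scale bounds, as real bounded
  instruments do;
* **linked survival**: $\log T = a - b \cdot d_1 + N(0, \sigma)$ with
  $d_1$ the template's first-year decline (defaults $a = \log 5$,
  $b = 0.07$, $\sigma = 0.35$), so faster-declining clusters die sooner
  — median survival near 3 years for a typical fast decline; deaths more
  than 3 years after the last visit are censored at the last visit;
* **metadata**: a bulbar/limb site-of-onset label whose bulbar
  probability is higher (0.30 vs 0.15) in clusters declining ≥ 12
  points in the first year, giving enrichment analyses a true signal.

The default spec is the four-archetype cohort used throughout the test
suite: fast linear (−10 pts/yr), slow linear (−3 pts/yr), sigmoid
($d_{50} = 1.5$ yr, $d_x = 0.25$ yr) and concave ($T = 4$ yr,
$\gamma = 0.5$), 30 subjects each.

What the generator does **not** emulate: treatment effects and
interventions (non-invasive ventilation, gastrostomy), item-level score
structure and its ordinal artefacts, enrollment and attrition *bias*
(attrition here is independent of disease state), measurement error that
correlates across visits, and real between-patient heterogeneity within
a cluster beyond GP noise. Passing tests therefore demonstrate that the
inference machinery recovers known structure under realistic sparsity
and noise — not that any particular clinical cohort has four clusters.

## Problem sizes and numerical choices

The test suite and the acceptance script work at desk scale: recovery
runs use 120 subjects (~7 visits each) for 50 sweeps with early
stopping, forecasting comparisons use 50 subjects per regime across
three replicates. These sizes were chosen so that every experiment has a
decisive expected outcome (ARI near 1 on well-separated archetypes,
order-of-magnitude error separation between models) while a full run
stays in the minutes range on a single core.

Numerical conventions worth knowing: Gram matrices carry a relative
jitter of $10^{-6}\sigma_f^2$; posterior variances are clipped at zero;
predictive likelihoods include observation noise; model serialization
writes doubles with 17 significant digits so a reloaded model reproduces
predictions exactly; `meta_cluster()` fixes its internal k-means seed
(restoring the caller's RNG state) so grouping is deterministic and
order-invariant.

## Known limitations

* Hyperparameters are point-estimated (type-II ML), not integrated over;
  cluster uncertainty bands reflect GP posterior variance only.
* The Gibbs chain is used as a stochastic search for a MAP partition
  rather than for full posterior inference over partitions.
* The admissibility margin is a fixed scalar; a principled probabilistic
  monotonicity constraint (e.g. derivative observations) is out of
  scope.
* The linear-kernel benchmark has no offset variance by design (it is
  anchored), so it cannot model any curvature, which is the point of the
  comparison.
* Computation is dense $O(n^3)$ per cluster; cohorts beyond a few
  thousand pooled visits per cluster would need inducing-point
  approximations, which are out of scope.
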