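---
title: "Monitoring herd states from bulk-tank milk fatty acids: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring herd states from bulk-tank milk fatty acids: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkstate)
```

## The monitoring model

Bulk tank milk pools a whole herd's production and is sampled by dairies
every one to three days, so FT-MIR predictions of its fatty-acid (FA)
composition form an almost-daily, zero-marginal-cost phenotype stream per
herd. `milkstate` treats each herd as moving through a small set of
latent *states* — interpretable mixtures of feeding regime, energy status
and stress — and reconstructs those states from the 31 predicted FAs in
four steps: unsupervised discovery (Ward.D2 clustering on a
novelty-balanced subset), supervised re-prediction (random forest or
PLS-DA, which also yields membership probabilities), dynamics (Markov
transition matrices over successive tank records), and an alert layer
mapping states to green/orange/red flags.

The package ships published Walloon reference values as defaults: the
per-state trait means (`walloon_state_means()`), whole-population trait
SDs (`walloon_trait_sds()`), and the 7-state transition matrix
(`walloon_transition_matrix()`). These parameterize the synthetic
generator and anchor the tests; they are inputs, not fitted artifacts.

## The synthetic generator and what it does (not) emulate

Real milk-payment databases are proprietary, so the generator is a
first-class module, not a test fixture. For each herd it draws

* sampling dates with i.i.d. gaps on {1, 2, 3} days (uniform by default);
* a latent state path from a first-order Markov chain (default truth: the
  Walloon matrix, rows renormalized to sum exactly to 1; initial state
  uniform, configurable);
* given the state, a multivariate-Gaussian draw of the 39 traits, with
  FAs truncated at zero — truncation rather than resampling, because
  negative predictions are exactly the artifact class the cleaning stage
  is specified to remove;
* data artifacts at configurable rates: fat/protein outside the plausible
  range, one negative FA, or one missing trait, each logged.

State covariances are `D C D` with `D = diag(fraction × population SD)`
and `C` a user-suppliable trait correlation (identity by default,
repaired to the nearest positive-definite matrix when needed). The
dispersion fraction defaults to 0.5: within-state spread must stay below
the between-state spread for seven states to be recoverable at all, and
half the population SD is the natural single-parameter choice given that
the published tables provide no within-cluster covariances.

Traits are drawn in the fat-basis state space (the published cluster
means are g/100 g fat) and emitted on the milk basis via
`fa_milk = fa_fat × fat / 100`, so the cleaning and conversion stages are
exercised end-to-end and conversion recovers the state-space values
exactly.

What the generator does **not** emulate: within-herd autocorrelation
beyond the state label (records are conditionally independent given the
state); realistic trait correlations within a state (identity default);
seasonal or pasture drivers behind the states; physically meaningful MIR
spectra (`simulate_spectra()` is a fixed random linear map plus noise,
enough to test the spectral classification pathway but nothing more).
Consequences for interpretation: passing tests demonstrate that the
*estimators* recover the *assumed* structure — they say nothing about
whether real herds have seven states, and absolute classifier accuracies
on synthetic data (often near 1 for the forest) are not comparable to
accuracies on real data, where only orderings (forest above PLS-DA,
traits above noisy spectra) are expected to transfer.

## Preprocessing decisions

* **Order of operations.** Cleaning runs on the milk basis first, then
  conversion: the plausibility bounds are defined in g/dL of milk, and
  conversion needs `fat > 0`, which cleaning guarantees.
* **Rejection precedence.** One reason code per rejected row, in the
  fixed order fat-bound → protein-bound → negative-FA → missing, making
  rejection counts deterministic.
* **PCA form.** Traits are centered and scaled to unit variance before
  decomposition (correlation-form PCA). This matters: loadings differ
  from the covariance form, and FA concentrations span two orders of
  magnitude. The retention rule is a variance threshold (default 0.95)
  rather than a fixed component count, because the count is
  data-dependent — on real, highly collinear FT-MIR predictions ~6
  components suffice; on the identity-correlation synthetic data ~24 are
  needed.
* **GH scoring.** `GH = (x − µ)ᵀ S⁻¹ (x − µ) / nPC` over the retained
  scores, with µ and S computed on the reference population only and
  frozen; projected populations reuse them unchanged. Under a Gaussian
  reference GH ≈ χ²(nPC)/nPC, so its mean is ≈ 1 and GH > 5 is a
  reasonable extremeness cut — records above it are *flagged*, never
  deleted, since extreme compositions are precisely the monitoring
  signal.
* **Serialization.** The projection round-trips through JSON with 17
  significant digits, which reproduces IEEE doubles exactly.

## Clustering decisions

Ward.D2 linkage (squared-Euclidean Ward costs, heights on the distance
scale) is computed on standardized FAs; standardization is applied here
for the same unit-heterogeneity reason as in the PCA and classifier.
The dense distance matrix restricts the input to ~30,000 rows — the
stratified subsample exists precisely to stay under that while keeping
every extreme record.

Choosing k from a dendrogram is usually a visual judgment; the codified
surrogate is the *relative* height gap `(h[n−k+1] − h[n−k]) / h[n−k]`
maximized over k ∈ [2, 15]. The relative (not absolute) gap is the right
statistic because the first merge between true groups sits far above the
last within-group merge in ratio terms even when absolute heights grow
along the dendrogram. The full diagnostics table is always returned so a
human can overrule the rule. Degenerate trees (all heights equal) fall
back to k_min with a warning. Cluster numbering out of a cut is
arbitrary, so labels are renumbered by decreasing size (ties keep the
original order) before any reporting.

## Classification decisions

* PLS-DA regresses the one-hot indicator on centered/scaled predictors;
  the component count (≤ 30) maximizes out-of-fold accuracy, with each
  fold fitted once at the maximum and evaluated at every count.
  Predicted indicator scores are clipped at zero and renormalized into
  row-stochastic probabilities — the simplest construction that
  guarantees valid probabilities (an all-non-positive row falls back to
  uniform).
* The random forest uses 500 Gini-split trees; the per-split feature
  count is CV-tuned over `{√p, p/3, p/2}`. Membership probabilities are
  tree-vote proportions, which natively satisfy the probability axioms.
* Folds are stratified by class and seeded. Unstratified folds can lose
  a rare cluster from a training fold entirely, which is fatal with
  1 %-frequency states; stratification is therefore not optional, and a
  class smaller than the fold count raises an explicit error.
* Both pooled and fold-averaged metrics are reported. They differ by
  fractions of a percentage point (the pooled confusion matrix is the
  sum over folds, while fold averaging weights folds equally), which is
  exactly the size of discrepancy to expect when comparing a printed
  accuracy with a printed confusion matrix.
* Hard labels are the probability argmax with ties broken toward the
  lowest state index, for determinism.

## Dynamics and alerts

Transitions are pooled over consecutive within-herd record pairs (never
across herds); with 1–3-day sampling no gap exclusion is applied by
default, but `max_gap_days` can drop pairs spanning long interruptions.
States never observed at time t yield NA rows and are flagged rather
than silently uniformized — on small populations a state can simply
never occur. The stationary distribution (left unit eigenvector) demands
irreducibility and errors otherwise; on the default truth chain it
reproduces the published occupancy pattern, a useful internal
consistency check between the transition and occupancy tables.

The alert layer is deliberately a pure function of configuration: a
cluster→flag map (default: state 3 red; 2, 5, 6 orange; 1, 4, 7 green,
following the field interpretation of those states as severe, stress-
related and normal respectively) plus an optional probability-threshold
mode that escalates when the mass on a red/orange state exceeds the
threshold even without an argmax switch. Because cluster numbering
depends on the fitted model, the map must be remapped after every refit;
it is shipped as data, never hard-coded. A post-filter raises the alert
only from the second consecutive non-green record (configurable),
reflecting that single-sample peaks are rarely actionable. Trait
favorability for the cluster summaries (is high C18:1 *trans* good?) is
likewise an editable orientation config with documented defaults, since
orientation is expert judgment, not a formula.

## Weather

THI uses the standard dry-bulb/relative-humidity form; its humidity term
vanishes at 14.4 °C. Station assignment is nearest-neighbour on planar
coordinates — exactly the Voronoi rule for point locations; polygon-
overlap assignment of municipalities is out of scope. Weather is daily;
a record outside coverage keeps its row and gets a missing-THI flag.

## Problem sizes and numerical choices

The test suite and analysis scripts run deliberately scaled-down
problems: populations of 10–60 herds over 70–200 days (≈ 500–6,000
records), 20 replicates of ≈ 3,000 records for state-number recovery,
and ≈ 27,000 transitions for the transition-estimator check. These sizes
were chosen so each statistical claim has comfortable sampling margin
(e.g. the 1→1 persistence estimate carries a standard error of ≈ 0.5
percentage points at 10,000 from-state-1 transitions, against a ±2-point
acceptance band) while a full run stays in the minutes range on one CPU.
Other numerical conventions: Ward merge-cost ties resolve by `hclust`'s
deterministic ordering; positive-definiteness repairs use the nearest-PD
projection; all stochastic steps take explicit integer seeds and
identical configurations reproduce byte-identical artifacts (hashed into
the run manifest of `run_pipeline()`).

## Known limitations

* Seven states and their flag semantics are properties of the reference
  population the defaults were derived from; other populations need
  their own clustering, interpretation and flag map.
* The generator's independence and identity-correlation assumptions make
  the synthetic classification problem easier than the real one; do not
  read absolute synthetic accuracies as forecasts.
* The transition estimator assumes a homogeneous first-order chain;
  seasonal non-homogeneity is averaged over.
* FT-MIR prediction equations themselves (and cross-instrument spectral
  standardization) are upstream of this package and out of scope.
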