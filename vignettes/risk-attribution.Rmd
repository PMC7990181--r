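---
title: "Attributing tumor progression risk to mutational phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing tumor progression risk to mutational phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(evorisk)
```

# The scientific question

Tumors differ not only in *which* driver genes they have mutated but in
*how* they generate genetic diversity: point-mutation hypermutability with
characteristic trinucleotide preferences, copy-number and structural
instability, and more or less branched clonal expansion. `evorisk` treats
these mutational phenotypes as first-class covariates and asks what share
of a cohort's censored progression risk (overall survival, disease-free
survival) they carry, relative to driver-gene mutation rates and clinical
covariates.

# The statistical model

## Censored outcomes and the Cox kernel

Each sample contributes `(X_i, y_i, δ_i)` with follow-up
`y_i = min(T_i, C_i)` in months and event indicator `δ_i`. Hazards are
proportional: `h_i(t) = h(t)·exp(−β′X_i)`. The package adopts the
negated-coefficient convention throughout, so the **risk score**
`η_i = −β′X_i` is the log of the parametric hazard part and larger scores
mean worse prognosis. Because only rankings and group contrasts of `η`
are ever used, the baseline `h(t)` is never estimated; the Kaplan–Meier
estimator is used only for cohort-level curves.

Fitting minimizes the Breslow-approximation negative log-partial
likelihood. Numerical choices:

* **Ties**: Breslow. Simulated times are continuous (ties measure-zero);
  on real, rounded data Breslow is the standard simple choice.
* **Unpenalized fits**: Newton with step-halving; convergence when the
  likelihood changes by `< 1e-7`; at most 500 iterations. Standard errors
  come from the inverse observed information.
* **Lasso** (`λ‖β‖₁`, λ on the grid {0.03, 0.1, 0.3, 1, 3, 10, 30}):
  proximal gradient with backtracking to `1e-6`.
* **Degenerate inputs**: an all-censored cohort raises an error (the
  partial likelihood is empty); diverging coefficients (`max|β| > 15`,
  i.e. a per-SD hazard ratio above e¹⁵ — far outside anything a real
  covariate produces) flag the model as separated instead of returning a
  silent "success".

The concordance index is computed exactly as the ratio of
strictly-concordant to comparable pairs, with `δ_i` weighting:
ties in either time or score add nothing to the numerator, and tied times
are not comparable. The logrank statistic uses the hypergeometric
variance at each distinct event time with `p` from χ²₁.

## Feature extraction

**Cumulative evolutionary features** treat all somatic events of a sample
as acquired on a single normal→tumor edge of fixed duration (default ten
years), converting counts to per-year rates. The scale is arbitrary and
cancels in ranking-based inference; no per-base normalization is applied.
Substitutions are collapsed to the 6 pyrimidine-centered classes
(purine-centered calls are reverse-complemented), and with their
immediate 5'/3' context give the 96 trinucleotide classes. Variants whose
context contains `N`, lies at a contig edge, or disagrees with the
reference base are excluded from the 6/96-class counts but still count
toward the total SNV rate. CNAs split by direction (amp/del) and by size;
"large" means *strictly above* 500,000 nt, so a CNA of exactly 500,000 nt
is small. Raw trinucleotide rates are used deliberately — no projection
onto known signature catalogs — so predictive context preferences outside
the cataloged signatures remain visible.

**Phylogenetic features** summarize a clonal tree whose edges carry
per-class mutation counts: `num_clone` counts non-root nodes (the root is
the normal founder; whether to count it is genuinely undefined upstream,
so it is documented here and fixed to "no"), edge length is the total
event count on the edge, `height` the maximum root-to-leaf length,
`branch_mean` the average edge length, `branch_mean_sv` the same using SV
counts only. Clone trees are read from a documented JSON schema rather
than Newick because per-edge multi-class counts and per-clone prevalences
do not fit Newick cleanly.

**Driver features** count events of any class whose position (SNV/indel),
span (CNA) or either breakpoint (SV) intersects a driver interval,
divided by the same edge duration; no gene-length normalization is
applied. **Clinical features** encode binary attributes as 0/1,
categorical attributes as *all-level* one-hot columns (`attr|level`;
keeping every level preserves per-level interpretability, and the induced
collinearity is exactly what the pruning stage handles), continuous
attributes pass through. Missing values are imputed mode/median — the
upstream protocol leaves imputation unspecified, so the simplest
deterministic rule is used and the per-attribute missingness is logged.

## Selection pipeline

Within every outer training fold, in order:

1. **z-scoring** of all columns using training-fold statistics only
   (held-out rows are transformed with the training parameters — never
   refit), so pooled held-out risk scores from different folds share a
   scale;
2. **collinearity pruning**: any pair with `|Pearson r| > 0.8` loses one
   member by a seeded coin flip (zero-variance columns go first);
3. **ℓ0 step-wise forward selection**: each unselected feature is scored
   joined to the current set by inner-CV concordance of a Cox fit; the
   best is accepted while the inner CI strictly increases, up to
   `max_k = 10` (a cap guarding against pathological non-termination).
   Ties break to the lowest column index for determinism. Inner CV is
   3-fold (or leave-one-out for small cohorts); held-out `η` are pooled
   across *all* inner splits before a single CI is computed — with
   leave-one-out a per-fold CI does not exist, and pooling uniformly for
   k-fold keeps the two schemes comparable;
4. a final unpenalized Cox fit on the selected set scores the held-out
   fold.

The outer loop is 3-fold, repeated five times over fresh seeded shuffles;
per-replicate CI is computed on the pooled held-out scores and reported
as mean ± SD. Outer folds are plain random splits (no event
stratification, matching the plain protocol); a draw that leaves a fold
without events is resampled with a warning. Candidate fits are cold
starts — no warm starting across candidates — so each evaluation is
independent of traversal order.

**Bootstrap importance** repeats pruning + selection on 1,000 resamples
drawing 80% of candidate features and 80% of samples; samples are drawn
*with* replacement, features *without* (drawing features with replacement
would only create duplicate columns for the pruner to re-remove).
Selection frequency over trials is the importance measure; more than 10%
failed trials aborts.

**Permutation control** permutes every feature column across samples
(independent seeded permutations) and reruns the identical pipeline: on a
predictive cohort the permuted mean CI sits at chance with visibly larger
spread.

**Leakage guard.** The design keeps every training-time statistic inside
the training fold by construction; the test suite additionally plants a
canary column equal to the event indicator whose training-fold values are
zeroed inside the CV. A leak-free pipeline sees a constant column and can
never select it; any implementation that lets outer-fold rows reach
selection or scaling would see the outcome itself and seize on it.

## Risk attribution

Held-out scores are pooled within a replicate (across outer folds — fold
models share the z-scored scale), split at the median, scores exactly at
the median going to the benign group. The hazard ratio uses the
**per-group-mean** exponent `HR = exp(mean η_M − mean η_B)`: the grouped
exponent-sum form and the mean form differ by a group-size factor that
cancels in the fraction ratios for even cohorts, and the mean form stays
well-defined for odd ones. By construction `log HR ≥ 0`; a constant score
vector is flagged uninformative with `HR = 1`.

Replicate HRs are aggregated by arithmetic mean before taking logs
(a geometric alternative sits behind `hr_aggregate = "geometric"`; it
makes scaling equivariance exact but is not the default protocol), then

```
fraction(evolutionary) = log HR(evolutionary) / log HR(full)
fraction(genomic)      = log HR(evolutionary + driver) / log HR(full)
```

Values normally fall in [0, 1]; above 1 means the added features hurt.
Whether to compute HRs per fold and average, or pool first, is an open
protocol detail; pooling first is this package's documented choice.

# The synthetic world

`simulate_cohort()` realizes the structure the analysis assumes, with
known ground truth:

* per-sample rate parameters (SNV, indel, CNA, SV) from lognormal priors;
  defaults (e.g. ~100 SNVs over the ten-year edge) sit between
  exome-scale and genome-scale somatic burdens;
* SNVs drawn per-class from a Dirichlet-jittered cohort signature mixture
  (default: aging-like C>T enrichment, strongest in NpCpG context) and
  placed only at genome positions whose actual context matches the class;
* CNA lengths lognormal around 300 kb so both size classes occur; driver
  hits are Bernoulli and may multiply phenotype rates (the
  driver↔phenotype correlation is reproduced by this multiplicative link,
  with no mechanistic claim);
* clone trees with 1–5 clones, linear or branched with probability 0.5,
  variants partitioned uniformly over edges (counts conserved exactly),
  prevalences from a Dirichlet assigned in depth order so children never
  exceed parents;
* survival by inverse transform from `h₀(t)·exp(η_true)` with exponential
  or Weibull baseline; censoring independent of covariates (the
  noninformative-censoring assumption of the likelihood; the real
  cohorts' censoring mechanisms are unknown, so the family is free
  config). Default baseline and uniform 12–120-month censoring give
  event fractions in the ~15% range typical of breast-cancer cohorts.
* `η_true = Σ β_j z_j` over cohort-standardized generative covariates;
  `beta_mixture(share)` exposes the evolutionary-vs-clinical hazard share
  as a single knob for recovery experiments.

What a green test does **not** establish: the generator has no read-level
noise, no VAF-driven deconvolution error, no subclonal mutation ordering,
no correlated censoring, and clinical covariates are independent of the
phenotype parameters by default. Recovery results therefore validate the
*machinery* (leakage-free protocol, estimator calibration, attribution
identifiability), not robustness to real-data artifacts.

# Test-world scaling

The acceptance suite must finish on one CPU, so its simulation worlds are
scaled down *a priori* (and only there — package defaults keep the full
world): a 3×100 kb toy genome, ~30 SNVs per sample, 20 driver intervals,
the compact evolutionary feature set without the 96 trinucleotide
columns, and 2 outer repeats inside the fraction-recovery grid (the
permutation control keeps the full 5). The fraction-recovery grid reuses
one simulated cohort per seed and redraws only the outcomes for each
generative share, which is statistically equivalent for the quantity
under test and an order of magnitude cheaper. None of these knobs was
chosen by looking at test outcomes; thresholds come from the stated
acceptance bands.

# Known limitations

* Exact ℓ0 optimization (mixed-integer) is out of scope; forward
  selection is a heuristic that can overfit the inner CV, which the outer
  loop absorbs by design.
* Efron ties, stratified and time-varying Cox models are not provided.
* Multi-sample tumors are treated as one sample each; aggregation across
  regions is the caller's concern.
* Driver-only attribution fractions are deliberately not reported:
  evolutionary and driver features are correlated, so their fractions do
  not decompose additively.
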