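# evorisk

**How much of a tumor's future progression risk is carried by *how* it
mutates, rather than by *which* genes it has hit?**

`evorisk` is an R package for attributing censored cancer-progression risk
(overall survival, disease-free survival) to three classes of covariates:

* **evolutionary features** — quantifications of the tumor's mutational
  phenotype: the total SNV rate, the 6 collapsed substitution-class rates,
  the 96 trinucleotide-context rates `N_l[N_x>N_y]N_r`, indel/CNA/SV rates
  (CNAs split by direction and by size at 500,000 nt), and clonal-phylogeny
  statistics (clone number, tree height, mean branch length, SV branch
  length) derived from per-edge mutation counts;
* **driver features** — per-gene somatic mutation rates over a catalog of
  known cancer genes;
* **clinical features** — encoded patient covariates (binary, categorical
  one-hot, continuous).

It is aimed at computational biologists who have per-sample somatic calls
(VCF), clonal trees from a deconvolution tool, and censored outcome
tables, and who want a leakage-safe estimate of each feature class's share
of the explainable risk.

## The model

Outcomes are censored pairs `(y_i, δ_i)` with `y_i = min(T_i, C_i)`.
Hazards follow the proportional-hazards form

```
h_i(t) = h(t) · exp(−β′X_i),        η_i = −β′X_i  (risk score)
```

fit by minimizing the Breslow negative log-partial likelihood, either
unpenalized, with an ℓ1 penalty `λ‖β‖₁` (proximal gradient, λ tuned on
the grid {0.03, 0.1, 0.3, 1, 3, 10, 30}), or under an ℓ0 constraint
`‖β‖₀ ≤ k` solved heuristically by step-wise forward selection tuned by
inner cross-validation. Evaluation is by the concordance index

```
CI = Σ_{i,j} δ_i·1(y_j > y_i, η_j < η_i) / Σ_{i,j} δ_i·1(y_j > y_i)
```

on outer-CV test folds of a two-loop (nested) protocol: 3-fold outer CV
repeated five times, with 3-fold or leave-one-out inner CV for tuning.
Held-out risk scores are median-split into predicted-malignant and
predicted-benign groups; the hazard ratio between them,
`HR = exp(mean η_M − mean η_B) ≥ 1`, gives the attribution statistic

```
fraction(evolutionary) = log HR(evolutionary) / log HR(evolutionary+driver+clinical)
fraction(genomic)      = log HR(evolutionary+driver) / log HR(evolutionary+driver+clinical)
```

A synthetic-cohort generator (`sim_config()` / `simulate_cohort()`)
produces VCF-writable variants placed by trinucleotide signature
mixtures, clone trees conserving the realized counts, clinical
covariates, and survival times with known coefficients, so the entire
pipeline is testable without protected patient data.

## Worked example

```r
library(evorisk)

cfg <- sim_config(n_samples = 300,
                  genome = toy_genome(contig_len = 1e5),
                  beta = beta_mixture(0.5),   # half evolutionary, half clinical hazard
                  seed = 1)
co  <- simulate_cohort(cfg)
fx  <- cohort_features(co, trinucleotide = FALSE)

sel  <- selection_config(outer_repeats = 5, max_k = 5, seed = 1)
evo  <- two_loop_cv(subset_classes(fx$features, "evolutionary"), fx$outcomes, sel)
gen  <- two_loop_cv(subset_classes(fx$features, c("evolutionary", "driver")),
                    fx$outcomes, sel)
full <- two_loop_cv(fx$features, fx$outcomes, sel)
fraction_metrics(evo, gen, full)
```

This prints (seed 1, as above):

```
fraction(evolutionary) = 0.572
fraction(genomic)      = 0.514
mean HR per feature set:
evolutionary      genomic         full
       2.603        2.364        5.325
```

Read: the evolutionary features alone reproduce about 57% of the log
hazard-ratio separation achieved by the full feature set on held-out
samples, and adding drivers contributes nothing beyond them — consistent
with the generative world, where half the (standardized) log-hazard came
from mutational-phenotype parameters and none from drivers. `full`'s mean
HR of ~5.3 means the predicted-malignant half of the cohort has about
five-fold the hazard of the predicted-benign half (held-out mean CI 0.71
for the full set vs 0.58 for evolutionary features alone).

A command-line interface wraps the same pipeline:

```sh
evorisk simulate  --n 200 --seed 1 --out cohort/
evorisk extract   --cohort cohort/ --out features
evorisk select    --features features.tsv --classes features.classes.tsv \
                  --outcomes cohort/outcomes.tsv --out cv.tsv
evorisk attribute --features features.tsv --classes features.classes.tsv \
                  --outcomes cohort/outcomes.tsv --out attribution.json
```

Tiny synthetic demo inputs (a VCF, a clone-tree JSON, FASTA, clinical and
outcome tables) live in `inst/extdata/`.

## Limitations

The package consumes clonal trees, it does not infer them; variant
calling, phylogeny reconstruction and germline-reference handling are
upstream concerns. Analyses of real patient cohorts (e.g. TCGA or ICGC
data) require those controlled-access inputs, which the package neither
downloads nor bundles; the synthetic generator reproduces the statistical
structure of such cohorts, not their biology.
See the methods vignette (`vignettes/risk-attribution.Rmd`) for modeling
assumptions, numerical choices and test-world scaling.
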