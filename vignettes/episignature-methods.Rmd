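---
title: "Methods: episignature derivation, embedding and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature derivation, embedding and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episign)
```

## Scope and data model

`episign` operates downstream of array preprocessing: its input is a
normalized **beta-value matrix** (probes × samples, methylated fraction in
[0, 1], `NA` allowed) plus a **sample sheet** (sample id, group, age in
years, sex F/M, optional batch). IDAT parsing, background correction and
normalization are deliberately out of scope; the package applies only its
own documented probe QC (missingness, zero variance, optional
sex-chromosome removal via a probe manifest).

The pipeline mirrors how episignature labs evaluate a new case series:

* **Stage A** — place query samples in the context of an *established*
  episignature: calibrated SVM scores with a three-band call rule, and a
  classical MDS embedding of queries plus reference cohort restricted to
  the signature probes.
* **Stage B** — derive a *new* signature from the cases and age- and
  sex-matched controls, then validate it by MDS against a large background
  cohort, optionally training a classifier on the result.

## Differential methylation model

Statistics are computed on **M-values**, M = log2(β/(1−β)) with β clamped
into [ε, 1−ε], ε = 0.01 (`logit_clip()`). The logit transform stabilizes
the strongly heteroskedastic variance of beta values near 0 and 1; effect
sizes are nevertheless reported as **Δβ** on the beta scale, where
filtering thresholds have a direct biological reading (a 10% methylation
difference).

With few cases, per-probe variance estimates are noisy, so the two-group
t-statistic is **moderated**: per-probe pooled variances s²_g (d_g =
n₁+n₂−2 df) are shrunk toward a prior (d₀, s₀²) estimated from all probes,

s̃² = (d₀·s₀² + d_g·s²_g)/(d₀ + d_g),  t = Δx̄ / (s̃·√(1/n₁+1/n₂)),

with t referred to a t distribution on d₀ + d_g df (standard normal in the
d₀ = ∞ limit). The prior is fitted by the method of moments on the log
scale: under s² ~ s₀²·F(d_g, d₀), the mean and variance of log s² involve
digamma/trigamma terms in d_g and d₀; the excess of `var(log s²)` over
`trigamma(d_g/2)` identifies d₀ through a trigamma inversion (solved by
`uniroot` on [1e−8, 5e6] to tolerance 1e−12), and the mean equation then
gives s₀². If the observed dispersion does not exceed what chi-square
sampling alone explains, d₀ = ∞. Numerically identical variances
(var(log s²) < 1e−12) are taken at face value, s₀² = their common value,
rather than bias-corrected. Zero variances are excluded from the fit with
a warning; an all-zero input is an error. A zero *posterior* variance at a
probe yields p = 0 with a flagged warning (p = 1 when the mean difference
is also zero) rather than an exception, so one degenerate probe cannot
abort a genome-wide scan.

Tests cross-check this implementation against an independent numeric
solution of the moment equations, against `limma`'s F-distribution fit on
simulated variances, and — at d₀ = 0 — against the ordinary pooled
two-sample t-test.

## Probe selection and the independence pruning

Selection applies, in order:

1. Benjamini–Hochberg adjustment (`bh_adjust()`, verified against the
   step-up definition on all orderings of random inputs); keep
   q < `alpha` (default 0.01).
2. Effect filter |Δβ| ≥ `min_abs_delta_beta` (default 0.10).
3. Ranking by |t|·|Δβ| descending — a compromise between pure significance
   (which favours low-variance probes with small effects) and pure effect
   size (which favours noisy probes); ties break lexicographically by
   probe id. The list is capped at `max_probes` (default 1000).
4. Greedy correlation pruning to an *independent* probe set: walking the
   ranked list top-down, a probe is kept iff its absolute Pearson
   correlation with every already-kept probe is below `prune_r`
   (default 0.90).

One design point deserves emphasis. In a case/control cohort every truly
differential probe co-varies with the group indicator, so *raw*
correlations between two signature probes are dominated by the shared
disease effect even when their residual noise is independent — with a
strong signature, most pairs exceed |r| = 0.9 and raw pruning would
discard probes that are biologically independent. "Independent" here is
meant to exclude *co-methylation* (neighbouring CpGs moving together), not
probes that share the phenotype effect. The pipeline therefore centres
values **within group** before computing the pruning correlation
(`prune_correlated(..., groups = )`), which estimates exactly the residual
probe–probe dependence. The function retains a `groups = NULL` raw mode
for probe sets without group structure. Probes with zero variance across
the training samples cannot be assessed and are treated as uncorrelated
(kept-eligible) with a warning.

## Matched-control selection

`select_matched_controls()` is greedy without replacement: cases are
visited in input order and each takes the `ratio` (default 3) exact-sex
pool samples with the smallest |age difference|; exact ties break by a
seeded shuffle, then by id. Greedy matching is transparent and
reproducible, and the returned match table (case id, control id, age gap
in years) makes every choice auditable; an optimal-assignment matcher was
deliberately not used since the gain is negligible with realistic pools.
Explicit control id lists are accepted wherever matching runs, so designs
with other control counts (e.g. 27 controls for 8 cases) are expressible
directly.

## Embedding and separation

`classical_mds()` is Torgerson principal-coordinates analysis: B =
−½·J·D²·J, eigendecomposition, coordinates = top-k eigenvectors scaled by
√eigenvalue (k defaults to 2, matching the usual two-dimensional MDS
plot). It is deterministic — no stress optimization — and exact on
Euclidean-realizable input. Two numerical conventions are fixed for
reproducibility: each coordinate column is oriented so its
largest-magnitude entry is positive, and k is validated against the count
of positive eigenvalues (threshold: eigenvalue > max(eig)·1e−10), with
negative eigenvalues counted in the output for diagnostics.

Separation is quantified by silhouette coefficients (Euclidean, on the
embedding coordinates, via `cluster::silhouette`) and by the ratio of
between-centroid distance to mean within-group spread. Singleton groups
have no defined silhouette; they are excluded and flagged rather than
failing the run.

## Classifier

`train_classifier()` fits a nu-parameterised **linear** SVM (via `e1071`,
`nu-classification`) over the signature probes. The samples are split into
a stratified 75% training / 25% test portion; on the training portion a
stratified 5-fold CV evaluates each nu in {0.05, 0.1, 0.15, 0.2, 0.3, 0.4,
0.5}; the best mean CV accuracy wins, ties going to the smallest nu
(smaller nu = fewer margin errors allowed, preferred when equivalent). nu
values infeasible for the class balance (nu-SVMs require nu ≤
2·min(n₊,n₋)/n) are skipped with a warning; if all are infeasible the
function errors. The winning nu is refit on the full training portion.

Margins are mapped to [0, 1] scores by a Platt-style sigmoid fitted to the
*out-of-fold* margins (so calibration never sees its own training fit),
with Platt's smoothed targets (N₊+1)/(N₊+2) and 1/(N₋+2) and the slope
parameterised as exp(a) ≥ 0, guaranteeing a monotone nondecreasing map;
optimization is BFGS from (a, b) = (0, 0). Calls follow the three-band
rule: score < 0.25 → control, > 0.5 → pathogenic, and the closed interval
[0.25, 0.5] → inconclusive (both boundaries deliberately inconclusive).

In `run_stage_b(train = TRUE)` the classifier is trained on the
*derivation cohort* (cases + matched controls) rather than cases against
the entire background: with a handful of cases against hundreds of
negatives, every nu in the standard grid is infeasible, while the matched
design (1:3) keeps the grid usable and the resulting model transfers to
background and query samples through the calibrated score.

## Synthetic cohorts: what they emulate, and what they do not

`simulate_cohort()` generates the data structure the analysis assumes,
with every choice exposed in `cohort_config()`:

* **Cohort geometry** (defaults): 8 cases, a 200-sample healthy control
  pool, and 100 further reference-disorder samples (a ~300-sample
  in-house background); 20,000 probes of which 175 carry the planted case
  signature at |Δβ| = 0.2. These sizes mirror a realistic episignature
  study in which a small atypical case series is screened against a large
  in-house database; probe count is scaled to desk size from the ~850k of
  a real array.
* **Baseline means** from a three-component mixture — low (≈0.1),
  intermediate (≈0.5), high (≈0.9) beta with weights (0.35, 0.30, 0.35)
  and SD-0.02 jitter — resembling the bimodal-with-shoulder distribution
  of array data. The weights are an artifact choice, not a measured
  quantity.
* **Noise** is Gaussian on the M-value scale (SD `noise_sd`, default 0.4
  log2 units), reproducing the compressed beta-scale variance near 0/1
  and guaranteeing emitted values stay in [0, 1].
* **Planted signature**: each signature probe gets a random
  hyper-/hypomethylation direction (real episignatures contain both); the
  case mean is solved on the logit scale so the expected case−control
  difference equals `delta_beta` on the *beta* scale, clipped into
  [0.02, 0.98] (direction flipped when the shift will not fit; residual
  clipping is recorded in the truth object, as a warning count, not an
  error).
* **Nuisance structure**: 500 probes drift linearly with age (0.02 log2
  units/year about the age-range midpoint), 500 probes shift by 1 log2
  unit in females, and an optional batch shift hits a seeded 10% probe
  subset in a random half of samples. These overlap freely with the
  signature probes, as they would on a real array.
* **Determinism**: one master seed spawns fixed-order child seeds per
  component, so outputs are bit-identical across runs and robust to
  internal reordering. `simulate_carriers()` draws new samples on an
  existing cohort's baseline — carrying the same planted signature
  (identical per-probe shifts), none, or a newly planted one — enabling
  held-out carrier and disjoint-signature experiments.

The generator does **not** emulate probe cross-reactivity, SNPs under
probes, cell-type composition shifts, spatially correlated co-methylation
blocks, or real manifest content. Passing recovery tests on this model
therefore demonstrates the pipeline's statistical machinery — not
robustness to those artefacts, which real studies must address during
preprocessing and interpretation.

## Validation design and problem sizes

The test suite validates each component against independent oracles
(brute-force BH, direct moment-equation solutions, double-loop distances,
hand eigendecompositions, the pooled t-test at d₀ = 0) and the pipeline
end to end on planted cohorts: signature recovery and MDS separation on a
20,000-probe cohort (8 cases, 24 matched controls from a 200-sample pool,
270 background samples, seed 1); the empty-signature rate over 100
seeded 5,000-probe null cohorts; and classifier band behaviour with 40
training carriers and 40-sample held-out groups on 10,000 probes. The
same computations are re-run from scratch by `scripts/acceptance.R`,
which writes every quantity it measures to JSON; neither the vignette nor
the README report numbers that script and the tests do not themselves
compute.

## Known limitations

* Covariate adjustment is by matching only; the linear model has no
  design-matrix covariates (age/sex/batch) beyond the two-group contrast.
* Greedy matching and greedy pruning are order-dependent heuristics,
  chosen for transparency over optimality; both record enough provenance
  to audit their choices.
* Calibration quality depends on the out-of-fold margin pool, which is
  small when the positive class is small; scores remain monotone in the
  margin regardless.
* The three-band thresholds (0.25/0.5) are conventions of the assay being
  modelled, exposed in `band_thresholds()` but not re-derived from data.
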