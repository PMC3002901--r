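---
title: "Methods: multivariate candidate-gene screening and network inference for CRHR1 time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate candidate-gene screening and network inference for CRHR1 time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crhnet)
```

This vignette documents the models and procedures the package
implements, the parameters that matter and their defaults, the design
choices made where the design was genuinely open, and what the
synthetic benchmarks do and do not demonstrate.

## The experimental design the package assumes

Two-color spotted arrays hybridized with CRH-treated vs. untreated
samples at five time points (1, 3, 6, 12, 24 h), six technical
replicates per time point, three per dye orientation (dye swap), for 30
arrays. Spots are grouped by the printing pin (48 print-tip groups on
the real platform). All stages assume this balanced 5 × 2 layout and
refuse unbalanced input rather than silently choosing a sum-of-squares
type.

## Normalization

Per spot, `M = log2(treated) - log2(control)` (orientation-resolved via
the dye label) and `A` is the average log2 intensity. Within each
(array, print-tip) group a robust local regression of M on A (degree 2,
symmetric family with 4 robustness iterations, span 0.75) is fitted and
subtracted; the span is the only parameter fixed by the original
protocol, the rest follow the classical robust-smoother defaults and
are configurable. Groups with fewer than 10 present spots fall back to
a whole-array fit (with a warning) because a local quadratic on fewer
points is dominated by noise. Before normalization, the lowest 10% of
intensities per array *and per channel* are erased as background and
the spot is masked on that array — a ratio with one background channel
has no meaning. The quantile level is applied per array per channel
(the protocol did not state the level; this is the configurable
default), and ties at the boundary are resolved by a stable sort on
(intensity, spot order) so exactly `floor(0.10 n)` values are erased,
deterministically. Only spots present on all 30 arrays enter the ratio
matrix.

Local regression is not a projection, so "normalize twice" is not an
exact identity in general; it is one (to 1e-6) whenever the trend lies
in the span of the local model, which is what the tests assert on
smooth fixtures.

## Univariate prefilter

Per gene, a two-way fixed-effects ANOVA with factors time (5 levels)
and dye orientation (2 levels). Stage 1 fits the model *with*
interaction (residual df 20) and excludes genes with interaction
p < 0.01 — a dye-dependent expression profile over time is a labeling
artifact, not biology. Stage 2 fits the model *without* interaction
(residual df 24) on the remainder and keeps genes with time-effect
p < 0.01. Both cuts act on raw p-values; the Benjamini–Hochberg FDR
achieved at each cut is reported alongside, because the published
thresholds of this design are raw-p cuts whose FDR is an outcome, not
an input. The dye main effect is estimated but never used for
selection. Genes with numerically zero residual variance are flagged
degenerate and get `NaN` p-values; they can never enter the preselected
pool.

Assumption checks use the same tools as the original protocol: per-gene
Shapiro–Wilk on the 30 ratios, and a Brown–Forsythe-style Levene test
on absolute deviations from the 25%-trimmed time-group means.

## The discriminant kernel and its wrappers

The shared classifier is the maximum-likelihood discriminant: class
means, pooled within-class covariance `S`, equal priors (the design is
balanced), score `d_g(x) = μ_g' S⁻¹ x − ½ μ_g' S⁻¹ μ_g`, predict by
argmax — linear discriminant analysis. Fitness of a gene subset is its
LOOCV accuracy: 30 refits, each predicting the held-out replicate. A
singular pooled covariance receives a ridge of `1e-8 × mean(diag)`
(escalated once to `1e-4` before erroring); the ridge is a guard, not a
regularization parameter — with 5-gene subsets and 24 residual df it
essentially never triggers.

Subset size is fixed at five genes: the generalization-curve diagnostic
(random subsets of size 2–30, training error by resubstitution vs. test
error by LOOCV) shows the test error rising well above its minimum
beyond roughly 20 variables while the training error pins at zero —
the small-n-large-p overfitting signature. Five observations per
predictor (30 samples / 5 genes) keeps the discriminant honest.

Four search strategies share this fitness:

* **Genetic algorithm** — independent restarts, each evolving a
  population of 100 five-gene chromosomes by shifted-fitness
  proportional selection, single-point crossover on the sorted-id
  representation (rate 1.0, duplicate repair by random replacement),
  per-slot mutation 0.05, one elite, at most 200 generations; a restart
  "solves" when some chromosome reaches LOOCV accuracy 1. Up to 2500
  restarts are collected at full scale. The GA internals are not fixed
  by the published protocol; the population size of 100 was chosen for
  reliable convergence on instances whose optimum is known by
  exhaustive search, and all settings are exposed in `ga_params()`.
* **Simulated annealing (INSEL)** — energy = LOOCV error; neighbor =
  exchange one gene against a random outside gene; Metropolis
  acceptance `min(1, exp(-ΔE/T))`; 1000 energy evaluations per search.
  The starting temperature is the mean absolute difference between
  successive energies of 10 000 random chromosomes ("mean variation" in
  the classical recipe; the standard deviation of the calibration
  energies is available behind a flag in spirit — the calibration
  stream is exposed, so any summary can be recomputed). Cooling follows
  the logarithmic schedule `T_t = T0 / ln(((t−1) ÷ t_max)·t_max + e)`
  with `t_max = 10` evaluations per temperature — the published variant
  names this schedule family without constants, so both are
  configurable. Returned chromosomes are re-scored from scratch and
  kept only at accuracy 1 (no stale caches).
* **Greedy Wilks-Λ forward selection** — `Λ = det(W)/det(T)`; a
  candidate's partial Λ against the current model is tested with
  `F = ((n−G−p)/(G−1)) (1−Λp)/Λp`; genes enter while p < 0.001, at most
  10 per fold (a logged safety valve; typical data-driven sizes are
  5–10). Wrapped in LOOCV: selection is repeated on each 29-sample
  training set, an LDA is fitted on the selected genes and the held-out
  sample predicted; the gene ranking counts how often each gene was
  picked across the 30 folds. A fold with an empty selection predicts
  the majority class and is flagged, so both accountings of the error
  are available.
* **Random forest** — 500 trees, `mtry` = all genes, node size 1,
  ranking by mean Gini decrease (permutation importance available), OOB
  error reported. This is the comparison method that ignores the
  dimensionality problem; it goes through the canonical `randomForest`
  implementation.

Rankings are frequency-based: count solution chromosomes containing
each gene, sort descending, break ties by gene id (the original
procedure does not state a tie rule; determinism matters more than any
particular choice). Duplicate solution chromosomes are counted as
occurrences; unique-chromosome accounting is a matter of passing
`unique(solutions)`. The consensus rule keeps genes in the top-50 of at
least 3 of 4 repetitions, each repetition seeded independently from a
master seed. The "up to 2500 solutions" are independent restarts (the
staged description restarts from random chromosomes once a solution is
banked), not milestones of one population.

## Network inference on the candidates

PCA: the candidate × sample matrix is row-centered (each gene's mean
ratio removed) and decomposed; gene scores and sample loadings on the
first two components give the biplot, and the explained-variance
fractions and exact reconstruction are part of the object's contract.

The graphical Gaussian model uses shrinkage partial correlations.
Observations are weighted by the share of the time axis they cover —
a trapezoid rule on the 1/3/6/12/24 h grid with the ends reflected, so
an equally spaced grid yields uniform weights; replicates split their
time point's weight. On the paper grid the time-point weights are
(2, 2.5, 4.5, 9, 12)/30. This realizes the "dynamic", time-aware
estimation mode; passing `time_h = NULL` gives the static estimator.
The weighted correlation matrix is shrunk toward the identity with the
analytic intensity `λ* = Σ var̂(r_ij) / Σ r_ij²` (clipped to [0, 1];
var̂ is the unbiased plug-in for the variance of each correlation), the
shrunk matrix is inverted, and
`r_p(i,j) = −Ω_ij/√(Ω_ii Ω_jj)`.

Edge significance: under the null a partial correlation with κ
effective degrees of freedom has density `∝ (1−r²)^((κ−3)/2)`
(equivalently `r² ~ Beta(½, (κ−1)/2)`). κ is estimated by maximum
likelihood from the full ensemble of off-diagonal partial correlations
— valid when most edges are null, which is the sparse-network regime
the method targets. With fewer than 5 edges the fit is unstable and
κ = n − (p − 2) is used, with a warning. Edges are kept when
`|r_p| > 0.35` **and** p < 0.05 (a conjunctive filter); unconnected
nodes remain in the node set.

Two calibration properties are worth knowing. Conditional on λ* < 1
the κ-ML p-values hold their level closely (~0.048 measured at the
11-gene/30-sample scale). But under a *global* null the analytic λ* has
expectation near 1 and clips to exactly 1 in roughly half of datasets;
all partial correlations are then 0 and every p-value 1. The estimator
is therefore conservative when there is nothing to find — a deliberate
property of analytic shrinkage, not a defect, but one that makes the
marginal edge-wise type-I error fall below the nominal 5% (about 2.5%
in our null simulations).

## The synthetic-data generator

The generator emulates, with known truth: (i) per-spot two-channel
intensities with a persistent log-uniform baseline intensity per spot
(A in [6, 16], per-array jitter sd 0.5 — dim spots are dim on every
array, which is what makes a bottom-10% background rule and a
30-array complete-case filter coexist realistically), a smooth
intensity-dependent dye bias per print tip (amplitude spread over
[−a, a] across tips, linear-plus-quadratic in scaled A) injected on the
channel-space log ratio; (ii) planted DE genes with early- (peaking
1 h, decayed by 24 h), mid- (6–12 h) and late-up (24 h) unit profiles
scaled by one effect parameter; (iii) dye×time interaction genes whose
dye contrast has constant magnitude and alternating sign over time
(with five time points the residual dye main effect is effect/5 — a
zero-mean constant-magnitude assignment does not exist on an odd
grid); (iv) a sparse partial-correlation network sampled from the
precision matrix implied by the planted edge values (rejected unless
positive definite); and (v) i.i.d. Gaussian replicate noise
(default sd 0.25 log2 units, a typical technical-replicate scale).

Study-scale conditions used by the tests and the acceptance script,
chosen once as realistic analogues and then frozen:

* **Screening pool**: 400 genes standing for the univariately
  preselected set — 10 strongly regulated planted genes at effect 1.5
  log2 units (≈2.8-fold, the scale of strongly CRH-responsive
  immediate-early and metabolic genes) over a background whose genes
  carry weak random time profiles (sd 0.15 log2), because a
  preselected pool contains *only* time-regulated genes, just mostly
  weak ones. On this pool the 4 × 250-restart GA consensus, the
  500-search annealer and the forest all place the planted genes at
  the top, and the GA/annealer top-50 lists overlap at the ~2/3 level
  that repeated stochastic selectors reach on shared signal.
* **Network**: 10 genes in four clusters (a pair, a chain of three, a
  negative pair, a positive pair, one unconnected node), pair edges at
  |r_p| = 0.8 and chain edges at 0.65 — co-regulated cluster members
  share a profile up to replicate noise, and these are the magnitudes
  at which a 30-sample shrinkage estimate clears the 0.35 edge filter
  with high probability (a design-stage power analysis, not a fit to
  any observed result).
* **Oracle instance** for the optimizers: 20 genes of which exactly
  five form the unique perfectly discriminating subset — three "step"
  genes each carrying one class boundary, plus a complementary pair
  whose members are individually swamped by a shared noise component
  and only informative jointly (the configuration a greedy
  one-at-a-time selector provably misses). Exhaustive search over all
  15 504 five-subsets verifies uniqueness at run time.
* **Generalization curve**: a 100-gene weak-signal pool (no strong
  planted genes), where the curve shows its textbook shape — test
  error minimal at moderate sizes, elevated beyond ~20 variables,
  training error at zero. On a *pure-noise* pool the test error sits at
  its chance ceiling from the start, so there is no rise left to
  detect; the curve diagnostic is meaningful on preselected,
  weak-signal data, and that is what the package tests.

What passing these benchmarks does **not** show: the generator draws
independent Gaussian noise per spot and plants smooth profiles — real
arrays have spatial artifacts beyond print-tip dye bias, heavy-tailed
spot noise, correlated backgrounds and biological (not only technical)
replicate structure. Recovery rates on the synthetic conditions are
upper bounds of a sort; the pipeline's value on real data rests on the
robustness of its components (robust loess, rank-based consensus,
shrinkage estimation), not on these exact numbers.

## Numerical choices and degenerate inputs

* Balanced-design ANOVA by explicit SS decomposition (all SS types
  coincide under balance; unbalanced input errors).
* BH adjustment delegates to `p.adjust`; `NaN` p-values propagate and
  are excluded from the test count.
* Ridge guard (above) instead of a pseudo-inverse: deterministic,
  minimal, logged.
* Annealer bookkeeping counts the initial evaluation, so a search
  performs exactly `maxit` energy evaluations; `maxit = 1` returns the
  seeded chromosome.
* A constant-energy calibration stream floors the temperature at 1e-3
  with a warning rather than dividing by zero.
* λ* = 1 (identity-shrunk correlation) yields an all-zero partial
  correlation matrix and p ≡ 1, the conservative empty-graph answer.
* All stochastic functions take explicit seeds; repetitions derive
  independent sub-seeds from one master seed, and the pipeline manifest
  records every parameter and seed consumed.

## Problem sizes in the shipped checks

The test-suite and acceptance-script experiments run at the scales
stated above (400-gene pool, 250 restarts × 4 repetitions, 500
annealing searches, 50-seed network recovery, 1000-seed null
calibration, 100 draws per generalization-curve size). These sizes were
chosen so the planted effects are resolved with comfortable margins
while a full reproduction stays in the minutes range on a single core;
the full-scale settings of the original protocol (2500 solutions,
12 593 spots) are plain parameter changes.
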