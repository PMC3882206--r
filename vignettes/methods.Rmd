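---
title: "Methods: cross-species effect-size comparison and age-trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species effect-size comparison and age-trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstx)
```

`crosstx` implements a comparative-transcriptomics pipeline for asking
whether the expression signature of a lifespan-extending intervention in a
short-lived species resembles the expression divergence of a long-lived
species from its relatives. This vignette is the package's own account of
the statistical machinery: the models and their assumptions, the defaults
and why they are what they are, what the synthetic-data generators do and
do not emulate, and the numerical decisions a maintainer would want
written down.

## Effect sizes and their comparison

Every two-group contrast is summarized per gene by Cohen's *d* with the
classical Bessel-corrected pooled variance. The pooling convention is a
package decision: *d* is named in the field without a fixed variance
convention, so we use the textbook pooled-variance form and document it.
Genes with zero pooled SD carry no usable signal on this scale; they are
excluded and counted (`n_zero_sd`) rather than imputed.

Two effect vectors are compared by Pearson correlation over shared gene
ids with the two-sided t-based test. For cross-species pairs the gene
spaces must be reconciled first: `map_orthologs()` restricts to a strictly
one-to-one ortholog table and renames, and unmapped genes never enter a
correlation. The per-gene *d* estimate carries the Hedges small-sample
inflation E[d̂] = d/J(df); the correlation analysis is unaffected (it is a
per-gene monotone scaling), but the synthetic-recovery tests correct for J
when checking planted values.

### The meta-test

With many dataset pairs the unit of inference is the *count* of
positive-significant comparisons (r > 0 and p < 0.05). Two nulls are
implemented:

- an exact one-sided binomial test with success probability 0.025, the
  independence value of P(r > 0 ∧ two-sided p < 0.05). This is a
  configurable default (`null_success_prob`); 0.5 serves sign-only
  analyses.
- a label-permutation test: group labels are reshuffled independently
  within each dataset (group sizes preserved), all effect sizes and all
  pair correlations are recomputed, and the positive-significant count is
  recorded; B = 100,000 rounds by default. The empirical p is the plain
  frequency b/B (a `plus_one` flag gives (b+1)/(B+1); b = 0 prints as
  "< 1/B"), and the permutation FDR is the median null count over the
  observed count, undefined when the observed count is zero.

The permutation null preserves the dependence structure induced by
datasets that participate in several comparisons, which the binomial test
ignores — that is exactly why both are reported. An `exhaustive` mode
enumerates every distinct within-dataset assignment for tiny designs; the
test suite uses it against an independently coded enumeration oracle.

## Diet-affected genes

Per-gene two-group tests are Welch's t (the default; the statistic,
Welch–Satterthwaite df and p are computed in closed form so the B × genes
permutation loop stays vectorized, and the scalar path is oracle-checked
against `stats::t.test`) or the Mann–Whitney U (exact enumeration when
n ≤ 12 without ties, midrank normal approximation with tie-corrected
variance otherwise, no continuity correction).

The FDR machinery mirrors the meta-test: B = 1000 label permutations, a
cutoff grid equal to the sorted distinct observed p-values (the only
attainable rejection sets), FDR(α) = median permuted count at α divided by
observed count at α, and the chosen cutoff is the largest α with
FDR(α) < 10%. The median (not mean) summary matches the meta-test
convention; a `summary = "mean"` flag exists. Because ranks do not depend
on labels, the MWU permutation path precomputes the rank matrix once.

Expression-level-stratified Fisher tests (`stratified_overlap()`) guard
the known ascertainment bias of differential-expression overlaps: highly
expressed genes are less noisy, pass p-value thresholds more easily, and
can generate spurious overlap between independently derived gene lists.

## Age trajectories and stage windows

Trajectories are fitted per gene and species by `stats::smooth.spline`
with target effective df = 3 — development on log age, aging on linear
age, reflecting fast early-life and slow late-life dynamics. Two details
are package decisions:

- **log-age offset.** log(age + offset) with offset = 1 human week
  (7/365.25 y), scaled across species by the lifespan ratio (aging-window
  end over the human 98 y), so that age 0 is finite and the early-life
  compression is comparable across species.
- **fit method.** A penalized smoothing spline at fixed effective df
  cannot reproduce even a noiseless quadratic exactly (only the linear
  null space of the curvature penalty is unshrunk), so
  `method = "polynomial"` provides an ordinary cubic fit with exactly 3
  non-intercept df for situations where exact low-order reproduction
  matters; the smoothing spline remains the default.

Species stage windows default to development 0–20 / 0–12 / 0–6 years and
aging 20–98 / 12–54 / 6–27 years (human / chimpanzee / macaque), matching
ages at physical maturation; they are configurable
(`species_stage_config()`). The mouse entry carries only the gestation
offset (19 d) plus a nominal 0.16 y / 2.5 y split (sexual maturity /
lifespan) that no default analysis consumes.

Each stage window is divided into 10 equal subintervals and trajectories
are read at the subinterval **midpoints**. Midpoints rather than an
endpoint-inclusive grid is a deliberate choice: it avoids evaluating at
age 0 on the log scale and keeps every query age strictly inside the
window; an endpoint rule is available (`rule = "endpoint"`). Where the
observed ages do not quite reach a midpoint, the query is clamped to the
observed range rather than extrapolated. Stage effects then apply Cohen's
d to the two 10-point interpolated vectors (n = 10 per species);
interpolation removes inter-individual variation while age-driven
variation is retained.

## Pattern classification

The three-way taxonomy of age-related genes — P1 conserved trajectory and
level, P2 conserved trajectory with level offsets, P3 divergent trajectory
shape — is driven by polynomial ANCOVA F-tests on stage-scaled age
(fraction of the stage window), with gates p < 0.01 for a difference and
p > 0.1 for "no difference":

- **Age gate.** Whether the age test should pool species or run per
  species was genuinely open. We use a pooled ANCOVA F-test of *all*
  age-involving terms (shared cubic plus species × age interactions)
  against a species-offsets-only null. This is exact under the flat null
  (so flat genes are mislabeled at the nominal 1%), and it retains power
  for genes whose species trajectories diverge — a shared-curve-only gate
  can cancel opposing trajectories and miss exactly the P3 genes the
  taxonomy exists for.
- **Species test.** Per pair, F-test of the species terms (level offset
  plus interactions, q = 4 at cubic degree) over the shared polynomial.
- **Shape test.** Each species' vector is first normalized to the common
  mean. Because the two species are sampled at different ages, centering
  leaves a residual constant (the species means of the trajectory over
  *their own* ages differ), so the shape test keeps a species intercept in
  both models and tests **only** the age-interaction terms. Without this,
  a noiseless conserved gene with a constant species offset would be
  flagged as shape-divergent — the test suite asserts the exact
  offset-to-P2 conversion.
- The pairwise tests use the full cubic family rather than a
  forward-selected degree: species-specific shape differences can live in
  terms a parsimonious pooled fit does not need. The standalone
  `age_test()` keeps forward selection (nested F-tests at 0.05) for the
  single-series contract.

Labels are assigned in the order P1 → P2 → P3 (`classify_pattern()`),
which resolves the rare gene satisfying several definitions.

One structural consequence worth stating: P1 requires *three* pairwise
null p-values to all exceed 0.1, so even a perfectly calibrated test
recovers at most ≈ 0.9³ ≈ 73% of P1 genes (plus whatever positive
dependence the shared species contribute), and P2 faces the same ceiling
through its three shape tests. Recovery assessments should therefore pool
P1/P2/P3 genes; per-class P1 recovery above ~80% is not attainable by any
calibrated procedure under these published gates.

Module discovery standardizes each gene's concatenated 10-point
multi-species profile to zero mean and unit variance, runs k-means
(k = 8, 50 restarts, seeded) and tests each module's mean effect size
against B = 1000 random same-size gene sets (two-sided around the null
center), or against a supplied label-permuted effect ensemble.

## Pathway screen

Per gene set, Pearson correlation between the two effect vectors over
member genes present in both (the **usable** count; the > 5 filter is
strict, and a nominal-size mode exists because the published convention
does not say which was counted), Bonferroni-corrected over the number of
sets actually tested. Overlapping sets are tested independently.

## Time-shift analysis

Cross-species age alignment works on log conception age: postnatal ages
plus gestation (280 d human, 19 d mouse), which removes the prenatal
span difference. Per gene: smoothing-spline fits (df = 3) for both
species, evaluated on 100-point log-age grids spanning each species'
observed range; genes whose two standardized trajectories correlate at
r > 0.5 (strict) are retained; each retained gene is aligned by dynamic
time warping with the symmetric step pattern (diagonal/vertical/
horizontal) and squared-difference local cost. The cited warping
literature does not specify its internals, so this DTW contract is the
package's defined method, validated by synthetic warp recovery rather
than by claimed equivalence to any prior implementation.

The warp is summarized in the age domain, not the cost domain: per gene,
each query grid age maps to the mean matched reference log-age, and the
per-gene corresponding age for an arbitrary query age is linearly
interpolated. The point estimate averages per-gene log conception ages
(ages are log-normally spread, so the geometric mean is the natural
center), and the 95% CI is a percentile bootstrap over genes (n = 1000),
the gene being the resampling unit. At least 10 retained genes are
required for a reportable CI. DTW endpoints anchor both observed ranges,
so the generator used in validation places the reference ages over the
warp image of the query range — with mismatched ranges the endpoint
anchoring biases the boundary of the warp, a known limitation.

## Synthetic data: what it does and does not emulate

The generators plant exact ground truth: standardized effects enter as
mean shifts of `d * noise_sd` so the true Cohen's d is known; correlated
contrast pairs come from a bivariate normal; age-series genes follow
scaled-age cubics with species offsets (P2) or species-specific shapes
(P3); warped pairs evaluate one trajectory at warped conception ages;
probe fixtures place detectable transcripts' intensities strictly across
the GC-matched background threshold.

Defaults are chosen once as realistic study conditions: group sizes 8/7
(diet) or 5/5, trajectory amplitude 2 (log2 units) with noise 25% of
amplitude, species offsets of half the amplitude for P2, 15 individuals
per species, mouse query ages 2–904 d and a 20× conception-age warp. For
P3 genes the per-species perturbation equals the shared component in
amplitude, and draws are rejected until every species pair differs by at
least a quarter of the amplitude (RMS after centering): random scaled
cubics are frequently near-parallel, and a "divergent shape" truth label
is only meaningful when the shapes actually diverge at the stated noise.

Noise is i.i.d. Gaussian per observation. Real data violate this in ways
the generators deliberately do not model: heteroscedasticity across
expression levels, probe-affinity and batch artifacts, correlated genes,
non-polynomial trajectories, uneven age sampling. Passing recovery tests
therefore demonstrates correctness of the inference machinery under its
own assumptions, not robustness to microarray pathology; the MWU path and
the stratified overlap tests are the package's concessions to those
violations.

## Numerical conventions

- Empirical p-values are b/B by default, (b+1)/(B+1) behind a flag.
- Quantiles (probe detectability) use the linear-interpolation empirical
  quantile (type 7); the detection inequality is strict, on the mean
  intensity across samples by default (per-sample mode behind a flag) —
  the published wording fixes neither convention, so both are explicit
  configuration rather than a guessed "original".
- Quantile normalization follows the mean-of-sorted-log2 definition with
  ties receiving the mean reference value over the tied span
  (`limma::normalizeQuantiles(ties = TRUE)`). With ties the column
  multisets can differ by the tie means; the exact multiset-identity and
  idempotence properties hold for tie-free data.
- Nested F-tests resolve numerically zero residuals by convention: no
  improvement on a perfect fit → p = 1; a real improvement reaching a
  perfect fit → p = 0 (tolerance 1e-10 relative to total SS). Constant
  series are untestable (p = 1 for the age test, NA for centered shape
  tests).
- The DTW dynamic program is compiled (Rcpp); ties in the backtrack
  prefer the diagonal step. Path *cost* is unique and is what the
  enumeration oracles check.
- One global seed expands into per-stage seeds via a fixed integer hash
  kept below 2³¹; every seeded stage is bit-reproducible.

## Problem sizes used in validation

The acceptance checks run at sizes chosen to make their Monte-Carlo error
small relative to the margins being asserted: 2000 null comparisons for
the 0.025 calibration; 200 meta-test replicates at B = 200 on a 4 × 3
dataset grid (12 comparisons — with many fewer pairs the integer count
statistic makes the discrete permutation p so super-uniform that no
implementation could sit at the nominal level); 20 replicates of the
FDR recovery at 400 genes; 700 genes for pattern recovery; 50 warp
replicates at 200 genes. `scripts/acceptance.R` re-runs the same
machinery at comparable sizes from a caller-supplied seed.

## Known limitations

- The pipeline assumes one-to-one orthologs; paralog families are out of
  scope.
- Stage-window endpoints are treated as known constants; uncertainty in
  maturation ages is not propagated.
- The DTW alignment assumes both series span corresponding biological
  windows (endpoint anchoring).
- The pattern taxonomy's published gates (0.01 / 0.1) are hard
  thresholds; genes near the boundaries flip labels under resampling, and
  the P1/P2 definitions bound per-class recovery as described above.
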