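---
title: "Methods: from promoter acetylation profiles to expression change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from promoter acetylation profiles to expression change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetr)
```

`acetr` analyses promoter histone-acetylation (H3K9,14ac) time courses
measured by tiling arrays together with matched gene-expression data. This
vignette documents the statistical model behind each stage, the parameters
that matter, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## Data model and preprocessing

The probe table is long-format: one row per (probe, day, replicate) with a
gene assignment, a signed offset to the TSS (bp, 0 = TSS, positive =
downstream in gene orientation; strand is assumed already resolved), and a
background-subtracted log-scale signal. Control probes — designed to be
un-acetylated — carry no gene assignment and define the background null.
Replicates are averaged before any inference (`average_replicates()`), the
convention for two-colour array data with two ChIP and three expression
replicates.

Quality filtering (`filter_genes()`) retains genes with *strictly more than*
`min_probes = 10` distinct probes within `window_bp = 3500` bp of the TSS.
The inequality is strict by design: a gene with exactly 10 in-window probes
is dropped. The filter is idempotent.

## Island calling

**Null model.** For each day we estimate the control-probe distribution
robustly: location = median, scale = MAD-derived sigma. Day-level scales are
estimated from limited control sets, so they are shrunk toward the pooled
cross-day scale,

$$\hat\sigma_d = \lambda_d\, s_d + (1-\lambda_d)\, s_{pooled},
\qquad \lambda_d = \frac{n_d}{n_d + n_0},$$

with prior weight `n0 = 50`. A hierarchical empirical-Bayes treatment of
day-to-day variability would be a natural alternative; we use this
moment-based null because the downstream contract only needs calibrated
per-probe p-values, and the moment estimator is deterministic and
transparent. With identical controls on every day the shrinkage is
irrelevant by construction.

**Calls.** Acetylation means signal *above* the noise, so the test is
one-sided (upper tail). P-values are Benjamini–Hochberg corrected within
each day — not pooled across days, because the null is day-specific — and a
probe is called acetylated when q ≤ `fdr`. The default `fdr = 0.10` is a
package choice, exposed in every interface; under a pure null the realized
false-call rate stays at or below this nominal level (verified by
simulation over 20 seeds in the test suite). Degenerate case: a null scale
of zero (noise-free data) gives p = 0 above the location and p = 1 at or
below it.

**Transitions.** For a day pair (a, b), conditional on the state at day a:
`p_stay_ac` is the fraction of day-a-acetylated probes still acetylated at
day b, `p_stay_unac` the analogue for un-acetylated probes. Genes with fewer
than `min_state_count = 3` probes in either state at day a are flagged
`discarded` — their conditional estimates would rest on one or two probes.
The pooled summary sums transition counts over all consecutive day pairs
first and forms probabilities from pooled counts, i.e. it assumes one
change distribution for the whole course.

## Binned profiles and peaks

Genes differ in probe number and placement, so probes are averaged in 14
equi-distant 0.5 kb bins spanning −3.5 kb..+3.5 kb. Bin k (1-based) is the
half-open interval [−3500 + 500(k−1), −3500 + 500k) bp; the right window
edge is included in bin 14 so no in-window probe is lost. Only signal above
background enters: each probe contributes max(signal − location_d, 0). This
uses the null *location*, not the FDR call, so binning is independent of the
`fdr` parameter. Bins with no probes, or none above background, are zero.

A **peak** is the smallest contiguous bin interval that contains the profile
argmax and covers at least `coverage = 0.30` of total signal. The search is
greedy from the argmax: each step adds the neighbouring bin with the larger
signal; ties are broken toward the TSS, then leftward (the argmax itself is
tie-broken the same way). The procedure is deterministic and O(bins), and
by construction the covered fraction is always ≥ the coverage parameter.
Whether peaks should be found on raw probes or binned values is genuinely
ambiguous for this kind of analysis; we operate on binned values, which
makes peaks comparable across genes with different probe placements, and
report 1-based inclusive bin intervals. An all-zero profile yields a no-peak
sentinel that downstream stability categorisation flags as `undefined`.

Peak **stability** between two days is one of `identical`, `contained`,
`overlapping`, `disjoint`. With `mismatch_tol = t` each endpoint may differ
by up to t bins before a category degrades: identical if both endpoints
agree within t; contained if one interval lies inside the other extended by
t; overlapping if the gap between intervals is at most t.

## Correlation, canonical correlation, partial correlation

All change quantities are anchored on day 0: ΔE(g,t) = mean expression at t
minus at 0; ΔA(g,t) analogously from the profile summary (mean over bins by
default, median as the robust alternative). The day-pair matrix entry (s,t)
is the genome-wide correlation of ΔA on day s with ΔE on day t (Pearson
default, Spearman alternative), with the analytic p-value of the chosen
method. Because the analytic null assumes independent genes — unreasonable
genome-wide — we add a permutation test that preserves the correlation
structure within each layer: each permutation applies *one* random gene
relabelling to the whole expression matrix (all days jointly) and recomputes
the full matrix; p = (1 + #{|r_perm| ≥ |r_obs|})/(1 + n_perm).

**CCA.** With one expression dimension, canonical correlation reduces to the
multiple correlation of ΔE on the 14 bins: ρ² equals the OLS coefficient of
determination (this identity is enforced to 1e−10 against a regression
oracle in the tests), and the weight vector is scaled to unit variance of
the canonical variate. The mean-profile summary corresponds to fixing equal
weights, so ρ always dominates the mean-summary correlation in magnitude. A
rank-deficient cross-product is ridge-regularised with ε = 1e−8 times the
mean diagonal (triggered only below reciprocal condition 1e−12).

**Gaussian graphical model.** The 42 variables (14 bins × days 1, 3, 5) are
standardized; the correlation matrix is shrunk toward the identity with the
analytically estimated intensity λ* = Σ Var̂(r_ij) / Σ r_ij² (clipped to
[0,1]), which guarantees positive definiteness even with more variables than
observations; partial correlations come from the standardized inverse. With
λ forced to 0 and n ≫ p the estimate agrees with direct covariance inversion
to 1e−6 (tested). Edge significance uses the Fisher z-transform with
effective degrees of freedom n − p − 1, two-sided normal p-values, BH
correction, and an edge rule q ≤ `cutoff = 0.05`. A local-FDR mixture fit is
the classical alternative; we prefer the closed-form route because it is
deterministic and has no tuning beyond the cutoff. Group comparisons
(differential vs non-differential genes, labels from the day-5 differential
call) are elementwise matrix differences.

## Balanced classification benchmark

Four binary problems: (i) up vs down, (ii) down vs stable, (iii) up vs
stable, (iv) up∪down vs stable. Differential fractions of a few percent make
raw accuracy useless — predicting "unchanged" for everything already attains
~95% — so each problem is evaluated on balanced resamples: the minority
class is kept entire and the majority class is sampled without replacement
to the same size, 20 times. Chance level is then exactly 50%. Each resample
is scored by stratified 10-fold cross-validation (stratification keeps the
50/50 ratio inside folds; the classifier is refit per fold; accuracy is
pooled over held-out folds). The reported spread therefore mixes resampling
and fold-split variance, which is intended: it is the spread a practitioner
re-running the analysis would see.

The registry holds 18 classifiers with documented defaults: SVMs (linear,
RBF, polynomial degree 2 and 3; `coef0 = 1` because the homogeneous degree-2
kernel is an even function and cannot separate sign-symmetric classes),
linear/quadratic/diagonal-linear discriminant analysis, a
shrinkage-regularised LDA (pooled covariance shrunk 25% toward a scaled
identity) standing in for stabilised linear scores, a single tree, 25-fold
bagged trees, a 100-tree random forest, kNN with k ∈ {1, 5, 10, 15}, naive
Bayes, a single-hidden-layer neural network (5 units, decay 0.01), and
logistic regression. Hyperparameters are deliberately plain defaults — the
benchmark's purpose is breadth, not per-method optimisation.

For real data, labels come from a limma moderated t-test of day-t vs day-0
replicates with BH at q ≤ 0.05; on simulated data the generating truth is
used directly.

## Gene-set enrichment

Genes are ranked by a phenotype score (descending; ties broken by gene id so
the order is stable). The enrichment score is the signed extremum of a
running sum: hits increment by |score|^w normalized over hits (w = 1
default; w = 0 gives the classic unweighted statistic, invariant under
monotone score transforms), misses decrement by 1/(N − N_hit). Significance
is by gene-label permutation — scoring random same-size sets — with the
add-one estimate p = (1 + #extreme)/(1 + n_perm), so p is never exactly
zero. With a single score per gene, gene-label and phenotype permutation
coincide. The standard panel runs each gene set against three orderings
(mean day-0 acetylation, final-day acetylation change, final-day expression
change) with *no* multiple-testing correction: the panel is small by design
(five sets × three orderings = 15 tests) and corrected conclusions would not
change qualitatively.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the analysis assumes, at
configurable scale (defaults: ~28 probes/gene at 248 bp spacing in ±3.5 kb,
2 ChIP and 3 expression replicates, days 0/1/3/5, 2.5% up- and 2.5%
down-regulated genes, 5% ESC-like genes):

- probes sit on a jittered 248 bp grid, kept independently with probability
  chosen to match the mean probe count, giving realistic variable per-gene
  counts;
- each gene owns one contiguous acetylation island (60% of its positions,
  2 log-units above background) whose location *never* moves — only signal
  quantity changes over days;
- down-regulated genes lose signal across the whole window (1.5 units by
  day 5); up-regulated genes gain only within ±1.5 kb of the TSS and much
  more weakly (0.6 units) — the broad-strong-loss / narrow-weak-gain
  asymmetry that makes down-vs-stable intrinsically easier than
  up-vs-stable and up-vs-down easiest of all;
- ESC-like genes carry +1.5 units of baseline everywhere and a strong
  monotone loss (2 units by day 5);
- responding genes differ in effect size via a per-gene log-normal
  multiplier (sdlog 0.6): some responders are barely detectable, which
  keeps classification problems off the ceiling;
- noise has three layers: per-replicate Gaussian (sd 0.5 acetylation, 0.3
  expression), and a per-(gene, day) intercept (sd 0.15) shared by all
  probes of a gene on a day, emulating array/biology variation that
  replicate averaging cannot remove;
- expression change at day t is `coupling_by_day[t]` (default 0, 0.1, 0.3,
  0.35) times the standardized mean acetylation change *driven by the
  up/down label component*, plus noise. The ESC-specific de-acetylation is
  deliberately excluded from the coupling input: the strong chromatin loss
  of ESC-like genes is then not mirrored by concordant expression change,
  which is the biologically interesting decoupling the enrichment stage is
  meant to expose. With all couplings zero, acetylation and expression are
  exactly independent.

The imposed direction acetylation → expression is a simulation convenience;
nothing in the analysis can or does resolve causality. Other things the
generator does not attempt: sequence content, chromosome coordinates,
dye-bias or normalization artifacts, spatially correlated probe noise,
island birth/death (location change is exactly what the transition stage is
supposed to rule out, so the generator provides the null case), and
replicate-specific batch structure. Passing tests on this generator
therefore show that the pipeline recovers the intended structure under an
idealized noise model — not that it is robust to every artifact of real
arrays.

Noise magnitudes are not printed in the literature this design follows; the
defaults were chosen once so that roughly 5% of genes pass a differential
expression call and benchmark accuracies span a realistic 70–97% band
rather than saturating. All of them are config-exposed.

## Reproducibility and problem sizes

All randomness flows from one integer seed. Pipeline stages draw sub-seeds
via `derive_seed(seed, stage_tag)` — a small deterministic hash — so
skipping or re-ordering stages never changes another stage's stream, and
re-running a configuration reproduces byte-identical outputs (tested).

The test suite exercises the stages at deliberately modest sizes chosen as
the smallest that make the statistical assertions stable: 400–2000 genes
for generator and correlation properties, n = 5000 observations for the
AR(1) graph-recovery check, 20 Monte-Carlo seeds for FDR calibration,
2000 genes × 18 classifiers for the balanced-CV calibration, and ≤ 20-gene
lists for exhaustive enrichment-score enumeration. The acceptance script
reruns the two reference computations at 2000 genes / 1000 profiles.

## Known limitations

- The moment-based null assumes a unimodal, roughly Gaussian control
  distribution; heavy-tailed controls would make calls conservative.
- Partial-correlation edge tests use an effective-df normal approximation;
  for n close to p + 1 the approximation is crude (the shrinkage keeps the
  estimate finite, but p-values should then be read qualitatively).
- The CV harness reports accuracy only (the balanced design makes it
  interpretable); AUROC is not reported.
- One-dimensional CCA only: multivariate expression blocks and time-lagged
  cross-correlation are out of scope.
- Peak localisation is at bin resolution; sub-bin refinement and smoothing
  are out of scope.
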