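# acetr

Analysis of promoter histone-acetylation (H3K9,14ac) dynamics and their
coupling to gene expression over a differentiation time course.

`acetr` is aimed at epigenomics analysts working with promoter tiling-array
(ChIP-chip) acetylation measurements and matched expression data sampled at a
few time points (e.g. days 0, 1, 3, 5 of stem-cell differentiation). It
answers three questions about such data:

1. **Where is the acetylation signal, and does its location move?**
   Per-probe acetylation states are called against the control-probe
   background null (one-sided upper-tail p-values, Benjamini–Hochberg within
   day, call at q ≤ FDR), and per-gene transition summaries
   (p<sub>stay-unacetylated</sub>, p<sub>stay-acetylated</sub>) quantify
   island stability between days. Probe signal is mapped to comparable
   fixed-length profiles — 14 bins of 0.5 kb spanning ±3.5 kb of the TSS,
   above-background signal only — and a peak is the smallest contiguous bin
   interval containing the profile maximum that covers ≥ 30% of the total
   signal.
2. **How coordinated are acetylation change and expression change?**
   Anchored on day 0, the day-pair correlation matrix
   r(s,t) = cor(ΔA<sub>s</sub>, ΔE<sub>t</sub>) is computed with analytic and
   structure-preserving permutation significance (one joint gene-relabelling
   of the whole expression layer per permutation), one-dimensional canonical
   correlation generalizes the mean-profile summary
   (ρ = max<sub>a</sub> cor(X a, Δe), the multiple correlation), and a
   shrinkage-regularized Gaussian graphical model
   (ρ<sub>ij·rest</sub> = −ω<sub>ij</sub>/√(ω<sub>ii</sub>ω<sub>jj</sub>)
   from the inverse of the identity-shrunk correlation matrix) resolves the
   direct spatial and temporal dependencies among the 14 bins × 3 days.
3. **How predictive is the acetylation-change profile for the expression
   class?** A balanced, repeated cross-validation harness (20 balanced
   resamples × stratified 10-fold CV, chance level 50%) benchmarks 18
   classifiers (SVMs, discriminant analysis variants, trees/bagging/random
   forest, kNN, naive Bayes, neural network, logistic regression) on four
   binary problems: up vs down, down vs stable, up vs stable, differential
   vs stable. Gene-set enrichment analysis (weighted running-sum statistic,
   permutation p-values) characterizes where gene sets of interest fall in
   phenotype orderings.

A first-class synthetic-data generator (`simulate_dataset()`) emulates the
statistical structure such a study assumes — fixed island locations, broad
strong de-acetylation of down-regulated genes versus narrow weak TSS-proximal
gain of up-regulated genes, an ESC-like gene subset with elevated baseline
and strong uncoupled loss, and a day-increasing acetylation↔expression
coupling — so the entire pipeline is testable without external data.

## Worked example

```r
library(acetr)

d  <- simulate_dataset(sim_config(n_genes = 500, n_control_probes = 1000, seed = 7))
pt <- filter_genes(d$probe_table)           # genes with > 10 probes in ±3.5 kb
nm <- fit_null(pt)                          # control-probe background per day
st <- call_states(pt, nm, fdr = 0.10)       # per-probe acetylation calls
tr <- pooled_transition_summary(st)
mean(tr$p_stay_ac[!tr$discarded], na.rm = TRUE)
#> [1] 0.9487724
mean(tr$p_stay_unac[!tr$discarded], na.rm = TRUE)
#> [1] 0.9321635

b  <- bin_profiles(pt, nm)                  # 14-bin TSS profiles per day
ch <- build_changes(b, d$expr_table)        # day-t minus day-0, both layers
round(correlation_matrix(ch)$r, 3)
#>       expr
#> acet    day1  day3  day5
#>   day1 0.050 0.148 0.205
#>   day3 0.018 0.225 0.256
#>   day5 0.027 0.235 0.273
```

The stay-probabilities near 1 say that probes keep their acetylation state
between days — island locations are stable, so downstream analysis can focus
on quantitative signal changes. The correlation matrix shows the coupling of
acetylation change to expression change strengthening along the time course
(largest in the day-5/day-5 cell), the qualitative signature the generator
builds in and the correlation stage recovers.

`run_pipeline(pipeline_config(...), out_dir)` chains all five stages
(islands → profiles → assoc → classify → enrich), writes every result as TSV
and records a JSON manifest with versions, parameters and per-stage seeds;
re-running a configuration reproduces identical files.

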