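# gaitpatterns

Phenotyping of pathological gait from instrumented gait analysis, built
for clinical movement-analysis researchers studying heterogeneous motor
disorders (the motivating case is pediatric hereditary spastic
paraplegia, HSP). Instead of comparing a handful of spot measurements,
the package classifies **whole gait cycles** — each a multivariate time
series of sagittal joint angles over 201 epochs (0–100% of the cycle) —
and then translates the resulting classes back into the interpretable
parameters clinicians actually use.

The analysis core:

1. **Multivariate dynamic time warping (DTW).** For cycles *a*, *b* with
   channel vectors *a(i)*, *b(j)* ∈ ℝ⁵ (sagittal pelvis, hip, knee,
   ankle, forefoot), the local cost is d(i,j) = ‖a(i) − b(j)‖₂ and the
   dissimilarity is the minimal cumulative cost over monotone warping
   paths under the symmetric step pattern with diagonal weight 2,
   normalized by n + m. The dynamic program is compiled (Rcpp).
2. **Average-linkage hierarchical clustering** (UPGMA on the DTW
   dissimilarities) with an explicit cut at *k* groups; singleton
   clusters are flagged as outliers. `gait_patterns()` wraps the whole
   step and returns a classed fit with `print`/`summary`/`plot` methods.
3. **Random forests** (1000 trees, Breiman–Cutler permutation
   importance): a classification forest predicting the pattern from 43
   spatio-temporal + kinematic parameters; regression forests separating
   mildly affected cycles from healthy ones (OOB AUC) and predicting
   clinical features (age, GMFCS stage, polyneuropathy, ...).
4. **Classical statistics**: Z-scores against the healthy reference,
   linear mixed models (pattern fixed effect, subject random intercept,
   likelihood-ratio tests), log-linear pattern–clinical models with odds
   ratios, robust MM-estimator regressions of parameters on
   age × condition, and BCa bootstrap CIs for group contrasts.
5. **A synthetic cohort generator** (`generate_cohort()`) with known
   ground truth — six published-style pattern signatures applied to a
   parametric healthy template, subject/cycle noise, and clinical
   features coupled to pattern membership — so every stage of the
   pipeline is testable end to end.

## Worked example

```r
library(gaitpatterns)

coh <- generate_cohort(cohort_config(seed = 42))
hsp <- coh$cycles[coh$labels$condition == "HSP"]
pat <- gait_patterns(hsp, k = 7)
print(pat)
#> Gait pattern classification: 206 cycles, k = 7 cut
#>   7 multi-cycle pattern(s), 0 outlier cycle(s)
#>   pattern 1: 93 cycles (45.1%)
#>   pattern 2: 45 cycles (21.8%)
#>   pattern 3: 33 cycles (16.0%)
#>   pattern 4: 11 cycles (5.3%)
#>   pattern 5: 10 cycles (4.9%)
#>   pattern 6: 9 cycles (4.4%)
#>   pattern 7: 5 cycles (2.4%)

truth <- coh$labels$pattern[coh$labels$condition == "HSP"]
truth[truth == 0] <- 99           # the planted outlier
adjusted_rand_index(pattern_labels(pat), truth)
#> [1] 0.9943884
```

The printout lists each flat cluster of the dendrogram cut with its size
and share of cycles; the adjusted Rand index near 1 says the DTW
clustering recovered the generator's planted pattern labels almost
perfectly. The full analysis — forests, mixed models, contrasts — runs
as one pipeline:

```r
bundle <- run_pipeline(pipeline_config(synthetic = cohort_config(seed = 42),
                                       out_dir = "gaitrun", seed = 42))
writeLines(make_report(bundle))
```

which writes every artifact (distance matrix, Newick dendrogram,
assignments, importance tables, model tables, a 14-stage manifest) under
`gaitrun/`. A thin command-line front end with the same verbs lives at
`inst/cli/gaitpipe.R` (`simulate`, `extract`, `cluster`, `run-all`,
`report`).

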