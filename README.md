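# rhythmdiff

Differential rhythmicity analysis for circadian transcriptomes in R.

Around-the-clock expression profiling asks two questions that ordinary
differential expression cannot answer: *which genes cycle* within a
condition, and *how cycling changes* between conditions (genotypes, sexes,
treatments). `rhythmdiff` implements a complete, tested pipeline for the
two-group case:

- **Rhythm detection** — a rank-based test in the JTK_CYCLE family. Each
  gene's profile is compared against cosine reference waveforms on a
  discrete period grid (default 20–28 h at the sampling resolution; 3-h
  sampling gives 21/24/27 h) via Kendall's S with reference ties excluded.
  The p-value is exact: the permutation null of S for a tie-grouped
  reference is computed by convolving Gaussian-binomial inversion
  distributions, and matches exhaustive enumeration to machine precision.
  A single measured cycle is concatenated ×2 (a 48-h series from one
  24-h day) before testing, trading a documented false-positive inflation
  for a much lower false-negative rate. An optional Lomb–Scargle detector
  on the same grid can be Fisher-combined with the rank test.
- **Differential rhythm testing** — per gene, a harmonic (cosinor)
  regression at a fixed 24-h period in each group; a nested-model F-test of
  equal cosine/sine coefficients (mesors free) plus a robust Huber/Wald
  variant, combined by Fisher's method into a `meta_p`.
- **Classification** — a configurable decision table assigns each gene one
  category: *rhythmic in both, unchanged*; *phase change* (circular
  |Δφ| > 6 h); *other difference*; *gained*; *lost*; or *unclassified*.
  Default thresholds: adjP < 0.05 (strict group), < 0.1 (lax group),
  meta_p 0.01, phase 6 h; all inequalities strict; two meta-p orientations
  are provided.
- **Circular statistics** — mean vector (direction + resultant length R),
  Rayleigh uniformity test, large-sample 95 % confidence arcs, 3-h phase
  histograms, and an exact binomial/Fisher enrichment test against a
  background rhythmic fraction (default 16 %).
- **Simulation** — a seeded generator of pooled circadian designs
  (8 timepoints × 3 h, pools of 3 animals, two groups) with per-gene ground
  truth (category, mesor, relative amplitude, peak phase), von
  Mises-clustered phases (reference rhythms near ZT20.5, gained rhythms
  near ZT6, programmed 12-h flips) and log-normal or negative-binomial
  noise — so every stage of the pipeline is verifiable end to end.

All clock times are Zeitgeber time: ZT0 = lights on, ZT12 = lights off.

## Worked example

```r
library(rhythmdiff)

cfg <- pipeline_config(simulate = list(n_genes = 2000), seed = 11,
                       outdir = "run1")
res <- run_pipeline(cfg)
res$counts
#>        rhythmic_both_unchanged     rhythmic_both_phase_change
#>                            332                            261
#> rhythmic_both_other_difference              gained_in_g1_only
#>                             54                            140
#>                     lost_in_g1                   unclassified
#>                             75                           1138

subset(res$summary, category == "gained_in_g1_only")
#>            category   n mean_phase_h     R rayleigh_p ci_lower_h ci_upper_h
#>  gained_in_g1_only 140         6.02 0.788   1.34e-36       5.68       6.36
```

The 2,000 simulated genes were generated as 60 % arrhythmic, 20 % rhythmic
and unchanged, 10 % phase-shifted by 12 h, 7 % gaining a ZT6 rhythm in the
perturbed group and 3 % losing their rhythm. The classifier recovers that
structure: the six counts partition all genes, and the gained category's
circular mean phase sits at ZT ~6 with a tight confidence arc — the
signature of a perturbation that installs day-peaking rhythms. Stage
outputs (`expression.tsv`, `rhythm_<group>.tsv`, `diffrhythm.tsv`,
`classified.tsv`, `summary.tsv`) and a JSON manifest with content hashes
are written to `outdir`; re-running the same config and seed reproduces
them byte-identically.

Individual stages are plain functions over data frames
(`detect_rhythms()`, `compare_groups()`, `classify_all()`,
`summarize_phases()`, `enrichment_test()`, ...) and can be run separately
on TSV inputs; `read_pipeline_config()` loads the same settings from YAML.

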