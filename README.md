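# methvar

Technical variability diagnostics for Illumina-style DNA methylation
BeadChips: quantify the biases that a sample's physical position (chamber
number within a slide, and the slide itself) imprints on fluorescence
intensities and methylation beta values, correct them, and audit what they
do to downstream analyses.

The package is written for methylation-array analysts who need to know how
much of the variation between technical replicates is positional, whether
their preprocessing removed it, and whether residual positional structure
is manufacturing false positives in differential methylation testing or
instability in epigenetic-clock age predictions.

## What it computes

For probe *p* with methylated and unmethylated channel intensities *M*,
*U*, the methylation fraction is `beta = M / (M + U + offset)` (offset 100).
Around that quantity the package provides:

- **A synthetic replicate-plate generator** (`simulate_dataset()`): 4
  subjects x (8 pooled + 8 independently prepared) technical replicates on
  8-chamber slides, with ground-truth betas, per-chamber/per-channel gain
  and noise injections, and planted low-level outliers -- so every
  diagnostic is testable end to end with no external data.
- **Preprocessing stand-ins** (`run_prep()`): detection p-values from the
  out-of-band empirical distribution, normal-exponential background
  correction, per-sample linear dye-bias scaling, Grubbs screening of
  detection rates.
- **Positional-effect correction**: parametric empirical-Bayes batch
  adjustment of betas by chamber or slide (`combat_adjust()`), and a
  negative-binomial quantile-matching adjustment of intensities
  (`combat_counts_fi()`).
- **Variability diagnostics**: within-subject z-score positional profiles,
  within/across-subject SD ratios, bead-level coefficients of variation,
  intensity-binned bias curves, per-probe variance decomposition
  (chamber + slide fixed, subject random, closed-form REML with marginal
  F statistics), PCA with Ward-D2 clustering and subject purity, Grubbs
  single-outlier tests, and correlations of low-level features with beta
  variability.
- **A differential-methylation audit** (`run_audit()`,
  `build_paper_designs()`): pooled-t tests with BH correction over
  constructed designs -- consistency pairs (same subjects tested twice,
  across-array vs same-array) and position-confounded nulls in which every
  significant probe is a false positive.
- **Epigenetic-clock tooling** (`apply_clock()`,
  `clock_stability_report()`): a generic linear clock applier with the
  standard log-linear age transform, and replicate-stability reporting
  that traces aberrant age predictions to individual clock CpGs and
  channels.

## Worked example

Simulate the default biased replicate plate (chamber 1 dimmed to gain 0.8,
chambers 2-3 green-dimmed, chambers 7-8 red-dimmed, chamber-8 red noise
inflated 1.5x), then recover the injected structure:

```r
library(methvar)
dat <- simulate_dataset(paper_scenario(seed = 1))

chamber_intensity_summary(dat$lowlevel, dat$sheet, background_subtract = TRUE)
#>  group channel mean_fi ratio_to_median
#>      1   green    2827            0.80
#>      2   green    2756            0.78
#>      3   green    3003            0.85
#>      4   green    3534            1.00
#>  ...
```

The per-chamber mean intensity ratios recover the injected gains (0.80,
0.78, 0.85) to two decimals. The position-confounded null design -- both
groups contain the same two subjects, but one side sits in chambers 2-3
and the other in 7-8 -- shows how positional bias manufactures false
positives, and how empirical-Bayes chamber correction removes them:

```r
beta    <- beta_matrix(dat$lowlevel)
chamber <- dat$sheet$chamber[match(colnames(beta), dat$sheet$sample_id)]
des     <- build_paper_designs(dat$sheet)["null_position"]

run_audit(beta, dat$sheet, des)$table$n_significant
#> [1] 8604
run_audit(combat_adjust(beta, chamber), dat$sheet, des)$table$n_significant
#> [1] 0
```

8,604 of 17,600 CpGs test significant between two biologically identical
groups; all of them are positional false positives, and all vanish after
chamber adjustment. The same bias dominates the per-probe variance
decomposition and destroys subject clustering until corrected:

```r
vd <- variance_decomposition(beta, dat$sheet)
median(vd$F_chamber); median(vd$F_slide)
#> [1] 6.89
#> [1] 1.35

pca_cluster(beta, dat$sheet)$purity          # raw betas
#> [1] 0.422
beta_prep <- clean_matrix(run_prep(dat$lowlevel)$beta)
ch_prep   <- dat$sheet$chamber[match(colnames(beta_prep), dat$sheet$sample_id)]
pca_cluster(combat_adjust(beta_prep, ch_prep), dat$sheet)$purity
#> [1] 1
```

Chamber carries about five times the explainable variance of slide
(median F 6.89 vs 1.35). Raw betas cluster by position and sample-level
background rather than subject (purity 0.42); background correction
followed by chamber adjustment restores a perfect subject partition.

## Documentation

The methods vignette, `vignettes/positional-variability.Rmd`, describes
the generative model and its defaults, the preprocessing and correction
algorithms, the statistics each diagnostic reports, numerical conventions,
and known limitations.
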