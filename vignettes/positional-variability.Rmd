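---
title: "Positional variability in methylation BeadChip data: models, diagnostics and corrections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional variability in methylation BeadChip data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methvar` quantifies the technical variability that the physical layout of
Illumina-style methylation BeadChips imprints on fluorescence intensities
(FI) and on the beta values derived from them, corrects it, and audits what
it does to downstream analyses. This vignette is the package's own account
of the models and the design choices behind them.

## The measurement model

A BeadChip slide carries eight chambers (Sentrix positions R01C01..R08C01);
each chamber holds one sample. For every CpG probe the scanner reports, per
colour channel, the mean fluorescence across beads, the across-bead
standard deviation, and the bead count. Type II probes read the methylated
allele in green and the unmethylated allele in red on one bead type; Type I
probes read both alleles in a single design channel, and their signal in
the opposite channel -- the *out-of-band* (OOB) read -- is a pure
background sample. Methylation is summarised ratiometrically,

$$\beta = \frac{M}{M + U + \text{offset}},$$

with the conventional offset of 100 fluorescence units (the source data
never state theirs; the offset is exposed as a parameter).

Because the per-channel tables index one intensity per probe and channel,
a Type I probe is represented at probe level: its in-band row is the
two-bead-type total in the design channel and its OOB row the background
total opposite. Betas are therefore computed for Type II probes, and the
manifest gates all channel-wise analyses to them; Type I probes serve as
the background reference that detection and background correction need.

## The synthetic replicate plate

Every diagnostic here is exercised end to end on synthetic data with known
ground truth. The generator (`sim_config()`, `simulate_dataset()`) emulates
a replicate-plate study: 4 subjects, each measured 16 times -- 8 aliquots
of one pooled DNA sample (identical biology, chambers 1-8 covered exactly
once, spread over at least four slides) and 8 independently prepared
replicates that receive extra beta-scale preparation noise
(`prep_noise_sd`, default 0.005). The fixed 8-slide layout also guarantees
that one slide carries four pooled replicates of each of two subjects, so
that same-array, across-array and position-confounded comparisons can all
be constructed (`build_paper_designs()`).

Per probe, a baseline beta is drawn from a bimodal mixture -- 45%
Beta(0.5, 8), 45% Beta(8, 0.5), 10% Beta(5, 5) -- reflecting the mostly
unmethylated/methylated split of real arrays; subjects deviate from the
baseline by normal noise of SD `subject_effect_sd` (default 0.01, a
realistic between-individual scale for whole blood). Intensities follow

* a per-probe latent brightness $B \sim$ log-normal(log 5000, 0.8);
* channel signals $M^* = B\,\beta\,g_{c,\text{green}}$,
  $U^* = B(1-\beta)\,g_{c,\text{red}}$, where $g$ is the per-chamber,
  per-channel gain;
* one optical background level per sample (log-normal matched to mean 150,
  SD 40 FI units), added to every read -- twice for Type I probe-level
  totals;
* bead sampling: one bead count per probe and sample
  ($1 + \text{Poisson}(12)$; both channels read the same beads), and noise
  whose per-bead SD is
  $(\text{cv}\cdot S + \sqrt{k}(\text{cv}\cdot\mu_{bg} + \text{floor}))
  \cdot \text{inflation}_{c,\text{ch}}$
  with cv = 0.08 and floor = 60 FI units, divided by $\sqrt{n_\text{beads}}$
  for the mean. The additive floor makes dim probes relatively noisier,
  matching the observed inverse relation between intensity/bead count and
  beta variability.

Two modelling choices deserve emphasis. First, the background level is a
*per-sample* quantity: it is the scanner-level offset all reads on an array
share, and it is what makes raw (uncorrected) betas carry sample-level
structure -- the reason normal-exponential background correction exists.
Second, an OOB read is constructed to be distributionally identical to the
in-band total of a signal-free probe (same background units, same noise
law), which is exactly the property that makes OOB-based detection
p-values calibrated.

The default biased scenario (`paper_scenario()`, shipped as
`paper_layout.yaml`) injects a graded positional gradient: chamber 1
uniformly dimmed (gain 0.8 in both channels), chambers 2-3 green-dimmed
(0.78, 0.85), chambers 7-8 red-dimmed (0.90, 0.82), and chamber-8 red
bead noise inflated 1.5x. Equal-channel dimming cancels almost entirely in
the beta ratio; it is the *channel-asymmetric* components that push betas
down in low chambers and up in high ones, which is what the replicate data
this design emulates show at the beta level. The gradient is the
generator's definition of the study conditions and is not adjusted per
analysis.

What the generator does **not** model: bisulfite-conversion chemistry,
probe cross-hybridisation, SNP-affected probes, intensity-dependent
(nonlinear) positional effects, and spatial structure within a chamber.
Because the injected chamber bias is purely linear-multiplicative, a
linear dye-bias correction removes most of it -- real positional biases
survive preprocessing to a larger degree than these synthetic ones, so
passing tests demonstrate that the diagnostics detect and the corrections
remove the modelled bias class, not that any pipeline fully cleans real
arrays.

## Preprocessing stand-ins

`run_prep()` applies, in order: detection masking, dye-bias scaling,
background correction, then beta computation with masked entries set
missing. These are deliberately simplified stand-ins for a full
preprocessing suite, not a re-implementation of one; quality-mask
catalogues and Infinium-I channel inference are omitted because the
synthetic manifest has neither mislabeled channels nor an external mask
list.

* **Detection** (`detect_poobah()`): per sample, $p = 1 - \hat F_{oob}$
  (mid-rank empirical CDF of the OOB totals) evaluated at the probe's
  in-band total; probes with $p > \alpha$ (default 0.05) are masked.
  Calibration under the background-only null is a tested property.
* **Background** (`background_correct_normexp()`): normal-exponential
  deconvolution; the posterior expected signal is computed by
  `limma::normexp.signal`, with background mean/SD estimated robustly
  (median/MAD) from the sample's OOB totals, halved per single-channel
  read. A numerical-integration oracle checks the posterior mean in the
  tests. Background estimation uses OOB records only, so whether masking
  should gate it never arises.
* **Dye bias** (`dye_bias_scale()`): the red channel is rescaled per
  sample so the median Type II red intensity equals the median green; one
  linear factor per sample, applied to the whole channel.
* Sample QC: detection rates are screened with a single-outlier Grubbs
  test and abnormally low values flagged.

## Positional-effect correction

`combat_adjust()` is the standard parametric empirical-Bayes location/scale
batch adjustment written against one batch factor (chamber or slide, used
one at a time, with no protected covariates): features are standardised,
per-batch location and scale effects are shrunk toward method-of-moments
normal and inverse-gamma priors by iterated posterior updates (convergence
when the maximum relative change falls below 1e-4, at most 100 iterations),
removed, and back-transformed. Beta-scale output is clipped to [0, 1],
since adjusted values may stray slightly outside the unit interval.
Only the parametric mode exists. With `shrink = FALSE` the adjustment
collapses to per-batch standardise/restandardise -- the zero-prior-precision
limit, used as an exact oracle in the tests; an independently maintained
ComBat implementation is a second cross-check.

`combat_counts_fi()` carries the same idea to fluorescence intensities as
counts: per feature and channel, negative-binomial batch models with
method-of-moments dispersions (floored at 0.01, rather than GLM-fitted --
a documented simplification that keeps the adjustment dependency-light),
mapped by mid-rank quantile matching onto a batch-free target whose mean is
the geometric mean of batch means and whose dispersion is the
sample-size-weighted pool. Features with an all-zero batch pass through
unadjusted and are logged.

ComBat operates on beta values (not M-values, not logits) because beta is
the quantity the replicate analyses report; the count-style variant covers
the intensity route.

## Variability diagnostics

* `within_subject_zscores()` centres and scales each probe within each
  subject's replicates (sample SD, $n-1$, everywhere); constant probes
  become non-finite and are omitted. `chamber_profile()` averages the
  z-scores per chamber or slide, keeping probes with finite values in more
  than 90% of samples.
* `chamber_intensity_summary()` is the uncentred companion: per-chamber
  mean Type II intensity and its ratio to the median across chambers. The
  median reference keeps a handful of biased chambers from contaminating
  the baseline. With `background_subtract = TRUE` the OOB-estimated
  per-sample background is removed first; this matters for quantitative
  gain recovery, because an additive background dilutes a multiplicative
  gain ratio (a 0.8 gain reads as ~0.81-0.82 raw).
* `sd_ratio()`: per probe, mean within-subject replicate SD over the
  across-subject SD plus an offset of 1e-4 guarding low-variability CpGs.
* `bead_cv()`: bead-level SD over mean per Type II probe/sample/channel,
  aggregated per chamber; boxplot-style summaries hide values beyond 1.96
  IQR outside the quartiles and zero-mean records are excluded and counted.
* `intensity_bin_bias()`: probes binned per subject into 100 percentile
  bins of median within-subject FI (stable ranks break ties; fewer probes
  than bins reduces the bin count with a warning). FI mode averages the
  deviation from the probe's within-subject median, after subtracting each
  sample's scalar median deviation -- the centring isolates the
  intensity-dependent component from per-sample offsets and leaves a
  multiplicative gain's slope untouched. Beta mode averages absolute
  deviations of beta from the within-subject median.
* `variance_decomposition()`: per probe, a linear mixed model with chamber
  and slide fixed and subject random, fitted by closed-form REML -- the
  restricted likelihood is profiled over
  $\lambda = \sigma^2_{subj}/\sigma^2_e$ using one eigendecomposition of
  the subject structure projected on the fixed-effect complement (shared
  across probes), a 62-point grid on $\lambda \in \{0\} \cup [10^{-3},
  10^3]$ and local refinement. Marginal (Type III-style) Wald F statistics
  use $n - \mathrm{rank}(X)$ residual degrees of freedom, which makes the
  F collapse exactly to one-way ANOVA when the subject component hits the
  zero boundary; `lme4` is the cross-check for the variance components.
  Degenerate weighted designs are flagged per probe rather than failing
  the run. Note the F *ordering* across factors is the reported quantity;
  p-values would shift under other denominator-df conventions.
* `pca_cluster()`: PCA of samples (50 components by default, truncated
  with a warning past $n-1$), Ward-D2 clustering on the scores, a fixed
  cut at $k$ = number of subjects, and subject-purity = fraction of
  samples agreeing with their cluster's majority subject. The fixed cut
  substitutes a number for what is otherwise a visual dendrogram judgment.
* `grubbs_test()`: $G = \max|x - \bar x|/s$ with the standard two-sided
  t-bound p-value; past the statistic's attainable boundary the p-value is
  0 by convention.
* `lowlevel_correlations()`: Pearson and Spearman correlations of
  per-probe bead count, channel intensities and bead-level SDs against a
  per-probe beta SD.

## The differential-methylation audit

`dmp_test()` is the pooled-variance two-sample t-test (the linear-model
form two-group array testers reduce to; Welch sits behind a flag),
`bh_adjust()` the Benjamini-Hochberg step-up, with zero-variance probes
excluded from the family and counted rather than assigned an extreme
p-value. `run_audit()` counts BH-significant probes at $\alpha = 0.05$ per
design and compares consistency pairs by overlap and Jaccard index.

The canonical designs encode three questions. Two *consistency pairs* test
the same two subjects twice -- once with every replicate on a different
slide, once with all replicates sharing a slide -- so any disagreement
between the two significant sets is technical. The *position-confounded
null* balances subject composition across groups (two replicates of each
subject per side) while seating one side in low chambers (2-3) and the
other in high chambers (7-8): the biology is identical, so every
significant probe is a false positive attributable to position. A
*within-subject null* splits one subject's eight pooled replicates 4/4 and
is the global null on which unadjusted p-values should be uniform.

One calibration subtlety: the subject-balanced null's pooled SD contains
between-subject variance that the balanced numerator cancels, so its
p-values are conservative rather than uniform even without bias -- fine
for false-positive counting, wrong for a uniformity check; the
within-subject split exists for the latter. A second one: on *raw* betas
the shared per-sample background shifts every probe of a sample coherently,
so raw-data p-values are visibly non-uniform -- an expected property of
uncorrected array data -- and the uniformity check therefore runs on
background-corrected betas. Even there, uniformity is approximate: bead
counts differ across replicates, making beta noise a scale mixture, and
the resulting t statistics are very slightly heavy-tailed.

## Epigenetic clocks

`apply_clock()` evaluates a linear clock -- intercept plus coefficients on
CpG betas -- and inverts the standard piecewise log-linear age transform
where the clock uses one: $s < 0 \mapsto (1+a)e^s - 1$, otherwise
$a + s(1+a)$, with knot `adult_age`. Missing clock entries follow an
explicit policy (`error` or cohort-mean imputation); probes absent from
the matrix count against a coverage threshold. `clock_stability_report()`
summarises each clock CpG's mean and range across every subject's
replicates, ranks CpGs by influence (range x |coefficient|), reports each
subject's SD of predicted age, and screens flagged CpGs' low-level mean
and SD in both channels with Grubbs tests across samples -- the screen
that localises a single aberrant replicate (low bead count, shifted FI) to
a specific CpG and channel. The shipped 30-CpG clock
(`inst/extdata/synthetic_clock30.csv`, `synthetic_clock()`) is synthetic:
a fixed heavy-tailed coefficient profile with one dominant CpG, built for
tests, not a published model.

## Numerical conventions and degenerate inputs

Sample standard deviations ($n-1$) throughout; lower-median imputation for
even counts (configurable); missingness threshold strictly greater than
10%; matrices stored probes x samples in probe-manifest order; numeric
TSVs written with `%.17g` so round-trips are bit-identical. Degenerate
cases fail loudly and by name: singleton batches, zero-variance features
under standardisation, all-missing probes at imputation, zero channel
medians, OOB pools with zero spread, constant input to the Grubbs test.

## Problem sizes used in the validation suite

The acceptance-style checks run the full study design -- 4 subjects x 16
replicates x 20,000 probes (17,600 Type II) -- once per scenario, with the
false-positive ordering repeated over 20 independently seeded plates and
the planted-outlier screen over 100 seeded repetitions at 400 probes;
module-level tests use smaller instances chosen so each property is still
decisively measurable. These sizes are the package's validation design
choices; all of them complete on a single CPU in minutes.

## Known limitations

Simplified preprocessing (no quality-mask catalogue, no channel
inference, linear dye correction only); parametric ComBat only; pooled- or
Welch-t two-group testing only (no continuous phenotypes, no region-level
analysis); no ICC estimation; no genomic annotation of probes; clock
coefficients are user-supplied. The binary array-file format is out of
scope -- the package consumes the per-channel tabular summaries documented
in `read_lowlevel()`, and an external importer can produce them.
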