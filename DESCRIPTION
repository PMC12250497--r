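Package: methvar
Title: Technical Variability Diagnostics for Illumina Methylation BeadChips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies positional (chamber and slide) biases in Illumina-style
    DNA methylation BeadChip data from low-level fluorescence summaries, and
    audits their downstream consequences. Provides a synthetic replicate-plate
    generator that emulates a pooled/independent technical-replicate design;
    simplified preprocessing stand-ins (out-of-band detection p-values,
    normal-exponential background correction, dye-bias scaling); parametric
    empirical-Bayes batch adjustment of beta values and a negative-binomial
    quantile-matching adjustment of fluorescence intensities; variability
    diagnostics (within-subject z-score profiles, SD ratios, bead-level
    coefficients of variation, intensity-binned bias curves, per-probe
    variance decomposition with a subject random effect, PCA/Ward clustering,
    Grubbs outlier tests); a differential-methylation consistency and
    false-positive audit over constructed replicate designs; and a generic
    linear epigenetic-clock applier with replicate-stability reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    lme4,
    jsonlite
Config/testthat/edition: 3
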