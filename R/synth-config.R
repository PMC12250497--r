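#' Simulation configuration for replicate-plate datasets
#'
#' Defines a technical-replicate BeadChip experiment: `n_subjects` subjects,
#' each measured as `n_pooled_per_subject` aliquots of a pooled DNA sample
#' plus `n_independent_per_subject` independently prepared replicates, laid
#' out over 8-chamber slides. Positional bias enters through per-chamber,
#' per-channel multiplicative gains on fluorescence and multipliers on
#' bead-level noise.
#'
#' @param n_subjects number of biological subjects.
#' @param n_pooled_per_subject pooled technical replicates per subject.
#' @param n_independent_per_subject independently prepared replicates per
#'   subject; these receive extra beta-scale preparation noise.
#' @param n_probes total probes on the array (Type I probes are the last
#'   `floor(frac_type1 * n_probes)` of them).
#' @param frac_type1 fraction of Type I probes (out-of-band providers).
#' @param chamber_gain 8 x 2 matrix (columns `green`, `red`) of multiplicative
#'   brightness factors per chamber; default all 1 (bias-free).
#' @param chamber_cv_inflation 8 x 2 matrix of multipliers on bead-level
#'   noise per chamber and channel; default all 1.
#' @param subject_effect_sd SD (beta scale) of per-subject, per-probe
#'   deviations from the probe's baseline methylation.
#' @param prep_noise_sd SD (beta scale) of extra noise applied to
#'   independently prepared replicates before intensity synthesis.
#' @param bead_count_mean mean bead count; counts are `1 + Poisson(mean - 1)`.
#' @param bead_cv baseline bead-level coefficient of variation of
#'   fluorescence (multiplicative component of per-bead noise).
#' @param fi_noise_floor additive per-bead noise floor (FI units); makes dim
#'   probes relatively noisier, as bead-level data show.
#' @param background_mean,background_sd mean and SD (FI units) of the optical
#'   background per single-channel read.
#' @param brightness_meanlog,brightness_sdlog log-normal parameters of the
#'   per-probe latent brightness.
#' @param mixture_weights,mixture_shapes baseline-beta mixture: weights of the
#'   unmethylated, methylated and mid-range components, and a 3 x 2 matrix of
#'   Beta shape pairs.
#' @param n_slides number of slides to lay samples on, or `NULL` to derive
#'   from the sample count.
#' @param outlier_plan `NULL` or a data.frame with columns
#'   `probe_id, sample_id, n_beads, fi_shift`; see [simulate_intensities()].
#' @param seed integer seed; a fixed seed makes the generated dataset
#'   byte-identical across runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 4,
                       n_pooled_per_subject = 8,
                       n_independent_per_subject = 8,
                       n_probes = 20000,
                       frac_type1 = 0.12,
                       chamber_gain = NULL,
                       chamber_cv_inflation = NULL,
                       subject_effect_sd = 0.01,
                       prep_noise_sd = 0.005,
                       bead_count_mean = 13,
                       bead_cv = 0.08,
                       fi_noise_floor = 60,
                       background_mean = 150,
                       background_sd = 40,
                       brightness_meanlog = log(5000),
                       brightness_sdlog = 0.8,
                       mixture_weights = c(0.45, 0.45, 0.10),
                       mixture_shapes = rbind(c(0.5, 8), c(8, 0.5), c(5, 5)),
                       n_slides = NULL,
                       outlier_plan = NULL,
                       seed = 1L) {
  unit <- function(m) {
    if (is.null(m)) m <- matrix(1, 8, 2)
    m <- as.matrix(m)
    stopifnot(nrow(m) == 8, ncol(m) == 2)
    colnames(m) <- c("green", "red")
    m
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_pooled_per_subject = as.integer(n_pooled_per_subject),
    n_independent_per_subject = as.integer(n_independent_per_subject),
    n_probes = as.integer(n_probes),
    frac_type1 = frac_type1,
    chamber_gain = unit(chamber_gain),
    chamber_cv_inflation = unit(chamber_cv_inflation),
    subject_effect_sd = subject_effect_sd,
    prep_noise_sd = prep_noise_sd,
    bead_count_mean = bead_count_mean,
    bead_cv = bead_cv,
    fi_noise_floor = fi_noise_floor,
    background_mean = background_mean,
    background_sd = background_sd,
    brightness_meanlog = brightness_meanlog,
    brightness_sdlog = brightness_sdlog,
    mixture_weights = mixture_weights / sum(mixture_weights),
    mixture_shapes = as.matrix(mixture_shapes),
    n_slides = if (is.null(n_slides)) NULL else as.integer(n_slides),
    outlier_plan = outlier_plan,
    seed = as.integer(seed)
  )
  stopifnot(all(cfg$chamber_gain > 0), all(cfg$chamber_cv_inflation > 0),
            cfg$frac_type1 >= 0, cfg$frac_type1 < 1,
            cfg$subject_effect_sd >= 0, cfg$prep_noise_sd >= 0,
            cfg$bead_count_mean >= 1, cfg$bead_cv >= 0,
            cfg$background_mean >= 0, cfg$background_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Load a simulation scenario from a YAML file
#'
#' @param path YAML file with `sim_config` fields; `chamber_gain` and
#'   `chamber_cv_inflation` may be given sparsely as lists of
#'   `{chamber, channel, value}` entries.
#' @param seed optional seed overriding the file's.
#' @return A [sim_config].
#' @export
load_scenario <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  expand <- function(entries) {
    m <- matrix(1, 8, 2, dimnames = list(NULL, c("green", "red")))
    for (e in entries) m[e$chamber, e$channel] <- e$value
    m
  }
  if (!is.null(y$chamber_gain)) y$chamber_gain <- expand(y$chamber_gain)
  if (!is.null(y$chamber_cv_inflation)) y$chamber_cv_inflation <- expand(y$chamber_cv_inflation)
  if (!is.null(seed)) y$seed <- seed
  do.call(sim_config, y)
}

#' The default replicate-plate scenario
#'
#' Four subjects, 8 pooled + 8 independent replicates each (64 assays over
#' eight slides). With `biased = TRUE` (the shipped `paper_layout.yaml`
#' scenario) positional bias is injected: chamber 1 dimmed to gain 0.8 in
#' both channels, chamber 2 dimmed asymmetrically (green 0.78, red 0.95),
#' chamber 8 red gain 0.82 with bead-level CV inflated 1.5x in red. The
#' asymmetric components give chambers 2 and 8 systematic beta-scale biases
#' of opposite sign; equal-channel dimming alone cancels in the beta ratio.
#'
#' @param seed integer seed.
#' @param biased inject the positional biases above, or none.
#' @param ... overrides passed to [sim_config()].
#' @return A [sim_config].
#' @export
paper_scenario <- function(seed = 1L, biased = TRUE, ...) {
  if (biased) {
    path <- system.file("extdata", "paper_layout.yaml", package = "methvar")
    cfg <- load_scenario(path, seed = seed)
    over <- list(...)
    if (length(over)) {
      args <- cfg[setdiff(names(cfg), NULL)]
      class(args) <- NULL
      args[names(over)] <- over
      cfg <- do.call(sim_config, args)
    }
    cfg
  } else {
    sim_config(seed = seed, ...)
  }
}
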