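clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Lay replicates out on slides and chambers
#'
#' Builds a [sample_sheet] realising the replicate-plate design: each
#' subject's pooled replicates cover every chamber number exactly once and
#' span at least four slides; independently prepared replicates fill the
#' remaining (slide, chamber) cells with no collisions. For the canonical
#' 4-subject, 8+8 design a fixed grid is used in which subjects 2 and 4
#' ("B" and "D") share one slide with four pooled replicates each and also
#' appear on four distinct slides each, so that same-array, across-array and
#' position-confounded null comparisons can all be formed
#' (see [build_paper_designs()]). The layout is deterministic.
#'
#' @param config a [sim_config].
#' @return A [sample_sheet] with `n_subjects * (pooled + independent)` rows.
#' @export
emulate_paper_layout <- function(config) {
  S <- config$n_subjects
  P <- config$n_pooled_per_subject
  I <- config$n_independent_per_subject
  if (P > 8) stop("layout error: pooled replicates per subject cannot exceed 8 chambers")
  total <- S * (P + I)
  min_slides <- if (P > 0) max(min(4, P), ceiling(total / 8)) else ceiling(total / 8)
  n_slides <- if (is.null(config$n_slides)) min_slides else config$n_slides
  if (n_slides < min_slides) {
    stop("layout error: ", n_slides, " slide(s) cannot hold ", total,
         " samples with pooled replicates on at least ", min(4, P), " slides")
  }
  subjects <- LETTERS[seq_len(S)]
  slides <- sprintf("2058%08d", seq_len(n_slides))

  grid <- matrix(NA_character_, n_slides, 8, dimnames = list(slides, NULL))
  pooled_grid <- matrix(FALSE, n_slides, 8)

  if (S == 4 && P == 8) {
    # canonical grid: B/D interleaved on slide 1, remainders fanned out so
    # every subject's pooled replicates span >= 4 slides
    put <- function(si, ch, subj) {
      grid[si, ch] <<- subj
      pooled_grid[si, ch] <<- TRUE
    }
    for (ch in 1:8) put(1, ch, if (ch %% 2 == 1) "B" else "D")
    fan <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8))  # chambers per slide 2..5
    for (k in 1:4) {
      si <- k + 1
      put(si, 2 * k - 1, "D")           # D takes odd chambers 1,3,5,7
      put(si, 2 * k, "B")               # B takes even chambers 2,4,6,8
      a_ch <- fan[[(k %% 4) + 1]]       # A: 3,4 / 5,6 / 7,8 / 1,2
      c_ch <- fan[[((k + 1) %% 4) + 1]] # C: 5,6 / 7,8 / 1,2 / 3,4
      put(si, a_ch[1], "A"); put(si, a_ch[2], "A")
      put(si, c_ch[1], "C"); put(si, c_ch[2], "C")
    }
  } else {
    n_ps <- max(min(4, P), S, ceiling(S * P / 8))
    if (P > 0 && n_ps > n_slides) stop("layout error: not enough slides for pooled replicates")
    for (s in seq_len(S)) {
      for (ch in seq_len(P)) {
        si <- ((ch - 1 + (s - 1)) %% n_ps) + 1
        if (!is.na(grid[si, ch])) stop("layout error: pooled collision")
        grid[si, ch] <- subjects[s]
        pooled_grid[si, ch] <- TRUE
      }
    }
  }

  free <- which(is.na(grid), arr.ind = TRUE)
  free <- free[order(free[, 1], free[, 2]), , drop = FALSE]
  need <- S * I
  if (need > nrow(free)) stop("layout error: more samples than (slide, chamber) cells")
  if (I > 0) {
    subj_seq <- rep(subjects, length.out = need)  # round-robin fill
    for (k in seq_len(need)) grid[free[k, 1], free[k, 2]] <- subj_seq[k]
  }

  occ <- which(!is.na(grid), arr.ind = TRUE)
  occ <- occ[order(occ[, 1], occ[, 2]), , drop = FALSE]
  subj <- grid[occ]
  pooled <- pooled_grid[occ]
  rep_no <- stats::ave(seq_along(subj), subj, pooled, FUN = seq_along)
  sheet <- sample_sheet(
    sample_id = sprintf("%s_%s%d", subj, ifelse(pooled, "P", "I"), rep_no),
    subject = subj,
    slide = slides[occ[, 1]],
    chamber = occ[, 2],
    pooled = pooled
  )
  if (P > 0) {
    for (s in subjects) {
      rows <- sheet$pooled & sheet$subject == s
      if (length(unique(sheet$chamber[rows])) != P) {
        stop("layout error: pooled replicates of subject ", s, " do not cover ", P, " chambers")
      }
      if (length(unique(sheet$slide[rows])) < min(4, P)) {
        stop("layout error: pooled replicates of subject ", s, " span fewer than ",
             min(4, P), " slides")
      }
    }
  }
  sheet
}

#' Draw the ground-truth methylation state
#'
#' Per-probe baseline betas come from a bimodal mixture (components near 0
#' and 1 plus a minority mid-range component); each subject deviates from the
#' baseline by independent normal noise of SD `subject_effect_sd`, clipped to
#' `[0, 1]`. Also fixes the probe manifest: the last
#' `floor(frac_type1 * n_probes)` probes are Type I (alternating green/red
#' design channel), the rest Type II.
#'
#' @param config a [sim_config].
#' @return A list of class `ground_truth` with `true_beta`
#'   (probes x subjects), `baseline_beta`, `manifest`, `chamber_gain`, and
#'   the configured `outlier_plan`.
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed)
  n <- config$n_probes
  S <- config$n_subjects
  probes <- sprintf("cg%08d", seq_len(n))
  k1 <- floor(config$frac_type1 * n)
  type <- rep("II", n)
  dsgn <- rep("both", n)
  if (k1 > 0) {
    idx <- (n - k1 + 1):n
    type[idx] <- "I"
    dsgn[idx] <- rep(c("green", "red"), length.out = k1)
  }
  manifest <- probe_manifest(probes, type, dsgn)

  comp <- sample.int(nrow(config$mixture_shapes), n, replace = TRUE,
                     prob = config$mixture_weights)
  base <- stats::rbeta(n, config$mixture_shapes[comp, 1], config$mixture_shapes[comp, 2])
  dev <- matrix(stats::rnorm(n * S, 0, config$subject_effect_sd), n, S)
  true_beta <- clip01(base + dev)
  dimnames(true_beta) <- list(probes, LETTERS[seq_len(S)])
  structure(
    list(true_beta = true_beta, baseline_beta = stats::setNames(base, probes),
         manifest = manifest, chamber_gain = config$chamber_gain,
         outlier_plan = config$outlier_plan),
    class = "ground_truth"
  )
}

#' Synthesise low-level fluorescence summaries
#'
#' Per probe, a latent brightness `B` is drawn log-normally. Type II probes
#' emit methylated signal `B * beta * gain[chamber, green]` in green and
#' unmethylated signal `B * (1 - beta) * gain[chamber, red]` in red; Type I
#' probes emit their full in-band total in the design channel and a pure
#' background read (out-of-band) in the opposite channel. Each sample has one
#' optical background level (log-normal, matched to mean `background_mean`
#' and SD `background_sd`) shared by both channels; each read adds `k` units
#' of it plus bead-sampling noise whose per-bead SD is
#' `(bead_cv * signal + sqrt(k) * (bead_cv * background_mean +
#' fi_noise_floor)) * cv_inflation[chamber, channel]`, divided by
#' `sqrt(n_beads)` for the mean; `k` is the number of background units in the
#' read (1 for Type II entries, 2 for Type I probe-level totals), which makes
#' an out-of-band read distributionally identical to the in-band total of a
#' signal-free probe -- the property detection p-values calibrate against.
#' `sd_fi` records the realised bead-level SD (0 whenever `n_beads <= 1`).
#' Independently prepared replicates receive extra beta-scale noise
#' (`prep_noise_sd`) before synthesis. The `outlier_plan` is applied last:
#' each planned entry sets the record's bead count and adds `fi_shift` to the
#' mean FI of the probe's dimmer channel (the configuration that maximally
#' perturbs the beta ratio), inflating that channel's `sd_fi` by
#' `|fi_shift| / 2`.
#'
#' @param truth a `ground_truth` from [simulate_truth()].
#' @param sheet a [sample_sheet].
#' @param config the [sim_config] used for `truth`.
#' @return A [lowlevel_set].
#' @export
simulate_intensities <- function(truth, sheet, config) {
  sheet <- validate_sample_sheet(sheet)
  set.seed(config$seed + 1L)
  man <- truth$manifest
  n <- nrow(man)
  N <- nrow(sheet)
  probes <- man$probe_id
  samples <- sheet$sample_id
  subj_idx <- match(sheet$subject, colnames(truth$true_beta))
  if (anyNA(subj_idx)) stop("sheet has subjects absent from the ground truth")

  beta <- truth$true_beta[, subj_idx, drop = FALSE]
  ind <- !sheet$pooled
  if (any(ind) && config$prep_noise_sd > 0) {
    beta[, ind] <- clip01(beta[, ind] +
      matrix(stats::rnorm(n * sum(ind), 0, config$prep_noise_sd), n, sum(ind)))
  }
  B <- stats::rlnorm(n, config$brightness_meanlog, config$brightness_sdlog)

  t2 <- man$probe_type == "II"
  t1g <- man$probe_type == "I" & man$design_channel == "green"
  t1r <- man$probe_type == "I" & man$design_channel == "red"
  kdraws <- ifelse(t2, 1, 2)  # background units per read

  gain <- config$chamber_gain[sheet$chamber, , drop = FALSE]
  infl <- config$chamber_cv_inflation[sheet$chamber, , drop = FALSE]

  channel_signal <- function(ch) {
    S <- matrix(0, n, N)
    g <- gain[, ch]
    if (ch == "green") {
      S[t2, ] <- t(t(B[t2] * beta[t2, , drop = FALSE]) * g)
      S[t1g, ] <- B[t1g] %o% g
    } else {
      S[t2, ] <- t(t(B[t2] * (1 - beta[t2, , drop = FALSE])) * g)
      S[t1r, ] <- B[t1r] %o% g
    }
    S
  }

  clip_lo <- function(m) { m[m < 0] <- 0; m }
  # one optical background level per sample, shared by both channels: the
  # scanner-level offset every read on the array sees; per-read background
  # fluctuation lives in the bead-noise floor
  bg_level <- if (config$background_mean <= 0) rep(0, N) else {
    cv_bg <- config$background_sd / config$background_mean
    sdl <- sqrt(log1p(cv_bg^2))  # lognormal matched to the requested mean/SD
    stats::rlnorm(N, log(config$background_mean) - sdl^2 / 2, sdl)
  }
  # one bead count per probe and sample: both channels (and a Type I probe's
  # in-band and out-of-band reads) come from the same physical beads
  nb <- matrix(1L + stats::rpois(n * N, config$bead_count_mean - 1), n, N)
  synth_channel <- function(ch) {
    S <- channel_signal(ch)
    bg <- kdraws %o% bg_level
    sigma <- (config$bead_cv * S +
                sqrt(kdraws) * (config$bead_cv * config$background_mean +
                                  config$fi_noise_floor))
    sigma <- t(t(sigma) * infl[, ch])
    mean_fi <- clip_lo(S + bg + matrix(stats::rnorm(n * N, 0, 1), n, N) * sigma / sqrt(nb))
    df <- pmax(nb - 1L, 1L)
    sd_fi <- sigma * sqrt(matrix(stats::rchisq(n * N, df), n, N) / df)
    sd_fi[nb <= 1L] <- 0
    dimnames(mean_fi) <- dimnames(sd_fi) <- dimnames(nb) <- list(probes, samples)
    list(mean = mean_fi, sd = sd_fi, beads = nb)
  }

  g <- synth_channel("green")
  r <- synth_channel("red")

  plan <- config$outlier_plan
  if (!is.null(plan) && nrow(plan)) {
    for (k in seq_len(nrow(plan))) {
      i <- match(plan$probe_id[k], probes)
      j <- match(plan$sample_id[k], samples)
      if (is.na(i) || is.na(j)) stop("outlier_plan references unknown probe or sample")
      nb <- as.integer(plan$n_beads[k])
      shift_green <- g$mean[i, j] <= r$mean[i, j]  # perturb the dimmer channel
      for (ch in c("g", "r")) {
        tgt <- if (ch == "g") g else r
        tgt$beads[i, j] <- nb
        if (xor(ch == "r", shift_green)) {
          tgt$mean[i, j] <- max(0, tgt$mean[i, j] + plan$fi_shift[k])
          tgt$sd[i, j] <- tgt$sd[i, j] + abs(plan$fi_shift[k]) / 2
        }
        if (nb <= 1L) tgt$sd[i, j] <- 0
        if (ch == "g") g <- tgt else r <- tgt
      }
    }
  }

  lowlevel_set(
    mean_fi = list(green = g$mean, red = r$mean),
    sd_fi = list(green = g$sd, red = r$sd),
    n_beads = list(green = g$beads, red = r$beads),
    manifest = man
  )
}

#' Generate a complete synthetic replicate-plate dataset
#'
#' @param config a [sim_config].
#' @return List with `config`, `sheet`, `truth` and `lowlevel`.
#' @export
simulate_dataset <- function(config) {
  sheet <- emulate_paper_layout(config)
  truth <- simulate_truth(config)
  lowlevel <- simulate_intensities(truth, sheet, config)
  list(config = config, sheet = sheet, truth = truth, lowlevel = lowlevel)
}
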