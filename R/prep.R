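# Simplified preprocessing stand-ins. This module deliberately is NOT a
# re-implementation of a full BeadChip preprocessing suite: detection uses
# the out-of-band empirical-distribution principle, background correction is
# plain normal-exponential deconvolution with out-of-band-estimated
# parameters, and dye-bias correction is a linear per-sample channel
# rescaling. Quality-mask lists and Infinium-I channel inference are out of
# scope (the synthetic manifest has neither mislabeled channels nor an
# external mask catalogue).

oob_pool <- function(lowlevel, j) {
  man <- lowlevel$manifest
  oobch <- oob_channel(man)
  c(lowlevel$mean_fi$green[which(oobch == "green"), j],
    lowlevel$mean_fi$red[which(oobch == "red"), j])
}

inband_total <- function(lowlevel) {
  man <- lowlevel$manifest
  tot <- lowlevel$mean_fi$green + lowlevel$mean_fi$red
  t1g <- man$probe_type == "I" & man$design_channel == "green"
  t1r <- man$probe_type == "I" & man$design_channel == "red"
  tot[t1g, ] <- lowlevel$mean_fi$green[t1g, , drop = FALSE]
  tot[t1r, ] <- lowlevel$mean_fi$red[t1r, , drop = FALSE]
  tot
}

#' Detection p-values from the out-of-band empirical distribution
#'
#' Per sample, the Type I probes' out-of-band intensities form an empirical
#' background sample; a probe's detection p-value is one minus the mid-rank
#' empirical CDF of that sample evaluated at the probe's in-band total
#' intensity. Probes with `p > alpha` are masked (undetected).
#'
#' @param lowlevel a [lowlevel_set] containing out-of-band records.
#' @param alpha detection threshold (default 0.05).
#' @return A list of class `detection_mask` with probes-by-samples matrices
#'   `p` and `masked`, and `alpha`.
#' @export
detect_poobah <- function(lowlevel, alpha = 0.05) {
  man <- lowlevel$manifest
  if (!any(man$probe_type == "I")) {
    stop("no out-of-band records: the manifest has no Type I probes")
  }
  tot <- inband_total(lowlevel)
  p <- matrix(NA_real_, nrow(tot), ncol(tot), dimnames = dimnames(tot))
  for (j in seq_len(ncol(tot))) {
    pool <- sort(oob_pool(lowlevel, j))
    n <- length(pool)
    lt <- findInterval(tot[, j], pool, left.open = TRUE)  # strictly below
    le <- findInterval(tot[, j], pool)                    # at or below
    p[, j] <- 1 - (lt + 0.5 * (le - lt)) / n
  }
  structure(list(p = p, masked = p > alpha, alpha = alpha), class = "detection_mask")
}

# robust per-sample background parameters from the out-of-band totals;
# an OOB total is the sum of two single-channel background reads, so the
# single-read parameters are mu/2 and mad/sqrt(2)
background_params <- function(lowlevel, j) {
  pool <- oob_pool(lowlevel, j)
  mu2 <- stats::median(pool)
  s2 <- stats::mad(pool)
  if (!is.finite(s2) || s2 <= 0) {
    stop("degenerate background: out-of-band spread is zero for sample ",
         lowlevel$samples[j])
  }
  list(mu1 = mu2 / 2, sigma1 = s2 / sqrt(2), mu2 = mu2, sigma2 = s2)
}

#' Normal-exponential background correction
#'
#' Models each in-band intensity as exponential true signal plus normal
#' optical background, with background mean/SD estimated robustly
#' (median/MAD) from the sample's out-of-band records, and replaces the
#' intensity by the posterior expected signal, which is strictly positive.
#' Type I probe-level totals carry two background units and use the doubled
#' background parameters. Out-of-band records are left unchanged.
#'
#' @param lowlevel a [lowlevel_set] containing out-of-band records.
#' @return A corrected [lowlevel_set].
#' @export
background_correct_normexp <- function(lowlevel) {
  man <- lowlevel$manifest
  if (!any(man$probe_type == "I")) {
    stop("no out-of-band records: cannot estimate background")
  }
  oobch <- oob_channel(man)
  out <- lowlevel
  for (j in seq_along(lowlevel$samples)) {
    bp <- background_params(lowlevel, j)
    for (ch in c("green", "red")) {
      x <- lowlevel$mean_fi[[ch]][, j]
      t2 <- man$probe_type == "II"
      t1_in <- man$probe_type == "I" & man$design_channel == ch
      for (grp in list(list(idx = t2, mu = bp$mu1, sig = bp$sigma1),
                       list(idx = t1_in, mu = bp$mu2, sig = bp$sigma2))) {
        if (!any(grp$idx)) next
        v <- x[grp$idx]
        alpha_hat <- max(mean(v) - grp$mu, 10)
        x[grp$idx] <- limma::normexp.signal(c(grp$mu, log(grp$sig), log(alpha_hat)), v)
      }
      out$mean_fi[[ch]][, j] <- x
    }
  }
  out
}

#' Linear dye-bias correction
#'
#' Rescales the red channel per sample so that the median Type II red
#' intensity equals the median Type II green intensity. All red-channel
#' records (including Type I in-band and out-of-band rows) are scaled by the
#' same factor; `sd_fi` is scaled along with the means.
#'
#' @param lowlevel a [lowlevel_set] with Type II probes present.
#' @return A corrected [lowlevel_set]; per-sample scale factors are attached
#'   as attribute `"dye_scale"`.
#' @export
dye_bias_scale <- function(lowlevel) {
  t2 <- lowlevel$manifest$probe_type == "II"
  if (!any(t2)) stop("no Type II probes: dye-bias scaling undefined")
  med_g <- apply(lowlevel$mean_fi$green[t2, , drop = FALSE], 2, stats::median)
  med_r <- apply(lowlevel$mean_fi$red[t2, , drop = FALSE], 2, stats::median)
  if (any(med_g == 0) || any(med_r == 0)) {
    bad <- lowlevel$samples[med_g == 0 | med_r == 0]
    stop("degenerate channel: zero median Type II intensity in sample ",
         paste(bad, collapse = ", "))
  }
  f <- med_g / med_r
  out <- lowlevel
  out$mean_fi$red <- sweep(lowlevel$mean_fi$red, 2, f, `*`)
  out$sd_fi$red <- sweep(lowlevel$sd_fi$red, 2, f, `*`)
  attr(out, "dye_scale") <- stats::setNames(f, lowlevel$samples)
  out
}

#' Run the full preprocessing stand-in pipeline
#'
#' Applies, in order: detection masking against the out-of-band distribution,
#' dye-bias scaling, and normal-exponential background correction; then
#' computes beta values (Type II probes), setting masked entries to `NA`.
#' Also reports per-sample detection rates and screens them for abnormally
#' low values with a single-outlier Grubbs test.
#'
#' @param lowlevel a [lowlevel_set].
#' @param alpha detection threshold.
#' @param offset beta-value offset, see [compute_beta()].
#' @return A list with `lowlevel` (corrected), `beta` (Type II
#'   probes-by-samples, masked entries `NA`), `mask` (the
#'   [detect_poobah()] result on the input), and `sample_qc` (per-sample
#'   detection rate with the Grubbs flag).
#' @export
run_prep <- function(lowlevel, alpha = 0.05, offset = 100) {
  mask <- detect_poobah(lowlevel, alpha)
  ll <- dye_bias_scale(lowlevel)
  ll <- background_correct_normexp(ll)
  beta <- beta_matrix(ll, offset)
  beta[mask$masked[rownames(beta), , drop = FALSE]] <- NA
  rate <- colMeans(!mask$masked)
  qc <- data.frame(sample_id = lowlevel$samples, detect_rate = rate,
                   flagged = FALSE, row.names = NULL)
  if (length(rate) >= 3 && stats::sd(rate) > 0) {
    gt <- grubbs_test(rate)
    if (gt$p.value < 0.05 && rate[gt$outlier] == min(rate)) {
      qc$flagged[gt$outlier] <- TRUE
    }
    attr(qc, "grubbs") <- gt
  }
  list(lowlevel = ll, beta = beta, mask = mask, sample_qc = qc)
}
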