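#' Beta value from a methylated/unmethylated intensity pair
#'
#' The methylation fraction is the ratiometric summary
#' `beta = m / (m + u + offset)`, with the conventional Illumina stabilising
#' offset (default 100) guarding against near-zero totals.
#'
#' @param m methylated-channel mean fluorescence intensity (>= 0); vectorised.
#' @param u unmethylated-channel mean fluorescence intensity (>= 0).
#' @param offset non-negative stabiliser added to the denominator.
#' @return Numeric in `[0, 1]`, same length as the inputs.
#' @examples
#' compute_beta(300, 100, offset = 100)  # 0.6
#' @export
compute_beta <- function(m, u, offset = 100) {
  if (length(offset) != 1L || !is.finite(offset) || offset < 0) {
    stop("offset must be a single non-negative number")
  }
  if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  if (offset == 0 && any(m == 0 & u == 0, na.rm = TRUE)) {
    stop("undefined ratio: m = u = 0 with offset 0")
  }
  m / (m + u + offset)
}

#' Beta matrix from a low-level array set
#'
#' Computes beta values for Type II probes, whose methylated and unmethylated
#' signals are read in the green and red channels respectively. Type I probes
#' carry both alleles in a single channel in the probe-level aggregate
#' representation and are excluded (the manifest gates channel-wise analyses).
#'
#' @param lowlevel a [lowlevel_set].
#' @param offset stabilising offset, see [compute_beta()].
#' @return Probes-by-samples matrix of beta values for Type II probes.
#' @export
beta_matrix <- function(lowlevel, offset = 100) {
  t2 <- type2_probes(lowlevel$manifest)
  g <- lowlevel$mean_fi$green[t2, , drop = FALSE]
  r <- lowlevel$mean_fi$red[t2, , drop = FALSE]
  b <- compute_beta(g, r, offset)
  dimnames(b) <- dimnames(g)
  b
}

#' Drop high-missingness probes and median-impute the rest
#'
#' Probes whose fraction of missing values strictly exceeds
#' `max_na_fraction` are removed (a probe exactly at the threshold is kept);
#' remaining missing entries are replaced by the probe's median over
#' non-missing samples. For an even number of non-missing values the lower
#' median (lower of the two middle order statistics) is used by default.
#'
#' @param beta probes-by-samples numeric matrix, `NA` for missing.
#' @param max_na_fraction maximum tolerated NA fraction per probe, in `[0,1]`.
#' @param median_convention `"lower"` (default) or `"standard"` (midpoint
#'   average) for even counts.
#' @return Complete matrix with the surviving probes.
#' @export
clean_matrix <- function(beta, max_na_fraction = 0.1,
                         median_convention = c("lower", "standard")) {
  median_convention <- match.arg(median_convention)
  stopifnot(is.matrix(beta), max_na_fraction >= 0, max_na_fraction <= 1)
  na_frac <- rowMeans(is.na(beta))
  keep <- na_frac <= max_na_fraction
  out <- beta[keep, , drop = FALSE]
  all_na <- rowSums(!is.na(out)) == 0
  if (any(all_na)) {
    stop("cannot impute probe(s) with no observed values: ",
         paste(utils::head(rownames(out)[all_na], 5), collapse = ", "))
  }
  need <- which(rowSums(is.na(out)) > 0)
  for (i in need) {
    v <- out[i, ]
    obs <- sort(v[!is.na(v)])
    k <- length(obs)
    med <- if (median_convention == "lower") obs[floor((k + 1) / 2)] else stats::median(obs)
    out[i, is.na(v)] <- med
  }
  out
}
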