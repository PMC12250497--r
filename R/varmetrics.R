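# Variability diagnostics: within-subject z-score positional profiles,
# SD-ratio reliability, bead-level CV, intensity-binned bias, per-probe
# variance decomposition with a subject random effect, PCA/Ward clustering,
# Grubbs outlier testing, and correlations of low-level features with beta
# variability. Sample (n-1) standard deviations are used throughout.

row_sds <- function(x) {
  k <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  sqrt(rowSums((x - m)^2, na.rm = TRUE) / pmax(k - 1, 1))
}

match_sheet <- function(x, sheet) {
  ord <- match(colnames(x), sheet$sample_id)
  if (anyNA(ord)) {
    stop("samples absent from sheet: ",
         paste(colnames(x)[is.na(ord)], collapse = ", "))
  }
  sheet[ord, , drop = FALSE]
}

#' Within-subject z-scores of a feature matrix
#'
#' Centres and scales each probe within each subject's technical replicates
#' (subtract the within-subject mean, divide by the within-subject sample
#' SD). Probes constant within a subject become non-finite and are omitted
#' by downstream profile summaries.
#'
#' @param x probes-by-samples matrix.
#' @param sheet a [sample_sheet]; every subject needs >= 2 replicates.
#' @return Matrix of the same shape with z-scores (possibly `NaN`/`Inf`).
#' @export
within_subject_zscores <- function(x, sheet) {
  sh <- match_sheet(x, validate_sample_sheet(sheet))
  z <- x
  for (s in unique(sh$subject)) {
    jj <- which(sh$subject == s)
    if (length(jj) < 2) stop("subject ", s, " has fewer than 2 replicates")
    xs <- x[, jj, drop = FALSE]
    m <- rowMeans(xs)
    sdv <- sqrt(rowSums((xs - m)^2) / (length(jj) - 1))
    z[, jj] <- (xs - m) / sdv
  }
  z
}

#' Positional z-score profile
#'
#' Averages within-subject z-scores per probe over the samples of each
#' chamber (or slide). Probes with finite z-scores in fewer than 90% of
#' samples are dropped, non-finite values are omitted from means, and empty
#' groups are dropped with a warning.
#'
#' @param zscores output of [within_subject_zscores()].
#' @param sheet a [sample_sheet].
#' @param group_by `"chamber"` or `"slide"`.
#' @param min_completeness minimum fraction of finite values per probe.
#' @return List of class `position_profile`: `profile` (probes x groups),
#'   `summary` (per group: mean, se, n of all finite profile values), and
#'   `group_by`.
#' @export
chamber_profile <- function(zscores, sheet, group_by = c("chamber", "slide"),
                            min_completeness = 0.9) {
  group_by <- match.arg(group_by)
  sh <- match_sheet(zscores, validate_sample_sheet(sheet))
  z <- zscores
  z[!is.finite(z)] <- NA
  keep <- rowMeans(!is.na(z)) > min_completeness
  z <- z[keep, , drop = FALSE]
  g <- factor(sh[[group_by]])
  counts <- table(g)
  if (any(counts == 0)) {
    warning("dropping empty group(s): ", paste(names(counts)[counts == 0], collapse = ", "))
    g <- droplevels(g)
  }
  prof <- vapply(levels(g), function(l) {
    rowMeans(z[, g == l, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(z)))
  prof <- matrix(prof, nrow = nrow(z), dimnames = list(rownames(z), levels(g)))
  summ <- do.call(rbind, lapply(levels(g), function(l) {
    v <- prof[, l]
    v <- v[is.finite(v)]
    data.frame(group = l, mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
               n = length(v), stringsAsFactors = FALSE)
  }))
  structure(list(profile = prof, summary = summ, group_by = group_by),
            class = "position_profile")
}

#' Per-position mean fluorescence intensity
#'
#' Averages Type II in-band intensities per sample, then per chamber (or
#' slide), without centring or scaling, and reports each group's ratio to
#' the median across groups -- the direct readout of multiplicative
#' positional brightness differences (a chamber dimmed by gain `g` shows a
#' ratio close to `g`).
#'
#' @param lowlevel a [lowlevel_set].
#' @param sheet a [sample_sheet].
#' @param group_by `"chamber"` or `"slide"`.
#' @param background_subtract subtract each sample's out-of-band-estimated
#'   optical background (median of the OOB totals, halved per single-channel
#'   read) before averaging; this removes the background's dilution of
#'   multiplicative gain estimates. Requires Type I probes.
#' @return data.frame with columns group, channel, mean_fi, ratio_to_median.
#' @export
chamber_intensity_summary <- function(lowlevel, sheet, group_by = c("chamber", "slide"),
                                      background_subtract = FALSE) {
  group_by <- match.arg(group_by)
  sheet <- validate_sample_sheet(sheet)
  t2 <- lowlevel$manifest$probe_type == "II"
  sh <- sheet[match(lowlevel$samples, sheet$sample_id), , drop = FALSE]
  g <- factor(sh[[group_by]])
  bg_hat <- rep(0, length(lowlevel$samples))
  if (background_subtract) {
    if (!any(lowlevel$manifest$probe_type == "I")) {
      stop("background_subtract needs Type I (out-of-band) probes")
    }
    bg_hat <- vapply(seq_along(lowlevel$samples), function(j) {
      stats::median(oob_pool(lowlevel, j)) / 2
    }, numeric(1))
  }
  out <- list()
  for (ch in c("green", "red")) {
    per_sample <- colMeans(lowlevel$mean_fi[[ch]][t2, , drop = FALSE]) - bg_hat
    grp_mean <- tapply(per_sample, g, mean)
    out[[ch]] <- data.frame(
      group = names(grp_mean), channel = ch, mean_fi = as.numeric(grp_mean),
      ratio_to_median = as.numeric(grp_mean) / stats::median(as.numeric(grp_mean)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' SD ratio: within-subject over across-subject variability
#'
#' Per probe, the standard deviations of each subject's technical replicates
#' are averaged over subjects and divided by the standard deviation of all
#' replicates across all subjects, plus a small offset guarding
#' low-variability probes.
#'
#' @param x probes-by-samples matrix.
#' @param sheet a [sample_sheet]; >= 2 subjects, each with >= 2 replicates.
#' @param offset denominator offset (default 1e-4).
#' @return Named numeric vector, one ratio per probe.
#' @export
sd_ratio <- function(x, sheet, offset = 1e-4) {
  sh <- match_sheet(x, validate_sample_sheet(sheet))
  subs <- unique(sh$subject)
  if (length(subs) < 2) stop("need >= 2 subjects")
  within <- vapply(subs, function(s) {
    jj <- which(sh$subject == s)
    if (length(jj) < 2) stop("subject ", s, " has fewer than 2 replicates")
    row_sds(x[, jj, drop = FALSE])
  }, numeric(nrow(x)))
  rowMeans(matrix(within, nrow = nrow(x))) / (row_sds(x) + offset)
}

#' Bead-level coefficients of variation
#'
#' CV = bead-level SD over bead-level mean of fluorescence intensity, per
#' Type II probe, sample and channel, with per-chamber medians and IQRs.
#' Records with zero mean intensity are excluded and counted. Boxplot-style
#' summaries treat values further than `hide_beyond` IQRs outside the
#' quartiles as hidden outliers.
#'
#' @param lowlevel a [lowlevel_set].
#' @param sheet a [sample_sheet].
#' @param hide_beyond IQR multiplier for hiding extreme values (default 1.96).
#' @return List of class `bead_cv`: `cv` (per-channel matrices), `summary`
#'   (chamber x channel median/IQR with exclusion counts).
#' @export
bead_cv <- function(lowlevel, sheet, hide_beyond = 1.96) {
  sheet <- validate_sample_sheet(sheet)
  t2 <- lowlevel$manifest$probe_type == "II"
  sh <- sheet[match(lowlevel$samples, sheet$sample_id), , drop = FALSE]
  ch_f <- factor(sh$chamber)
  cvs <- list()
  summ <- list()
  for (ch in c("green", "red")) {
    m <- lowlevel$mean_fi[[ch]][t2, , drop = FALSE]
    s <- lowlevel$sd_fi[[ch]][t2, , drop = FALSE]
    cv <- s / m
    excluded <- m == 0
    cv[excluded] <- NA
    cvs[[ch]] <- cv
    for (l in levels(ch_f)) {
      v <- as.vector(cv[, ch_f == l, drop = FALSE])
      v <- v[!is.na(v)]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      hidden <- sum(v < q[1] - hide_beyond * iqr | v > q[3] + hide_beyond * iqr)
      summ[[length(summ) + 1]] <- data.frame(
        chamber = l, channel = ch, median = q[2], q1 = q[1], q3 = q[3],
        n = length(v), n_zero_mean = sum(excluded[, ch_f == l, drop = FALSE]),
        n_hidden = hidden, stringsAsFactors = FALSE
      )
    }
  }
  structure(list(cv = cvs, summary = do.call(rbind, summ)), class = "bead_cv")
}

#' Intensity-binned positional bias
#'
#' Bins Type II probes, per subject, into percentile bins of the median
#' within-subject fluorescence intensity in one colour channel, and
#' summarises within each bin either the deviation of intensities from the
#' probe's within-subject median (`mode = "fi_deviation"`, FI units) or the
#' mean absolute deviation of beta values from the probe's within-subject
#' median beta (`mode = "beta_absdev"`). Bin summaries are averaged over the
#' samples of each chamber.
#'
#' @param lowlevel a [lowlevel_set].
#' @param sheet a [sample_sheet].
#' @param bin_channel `"green"` or `"red"`: the channel whose median FI
#'   defines the bins.
#' @param mode `"fi_deviation"` or `"beta_absdev"`.
#' @param values beta matrix over Type II probes (required for
#'   `beta_absdev`; ignored otherwise).
#' @param n_bins number of percentile bins (default 100; reduced with a
#'   warning when there are fewer probes than bins).
#' @return data.frame with columns bin, chamber, mean_dev, se, n_samples and
#'   mean_bin_fi; per-sample bin means are attached as attribute
#'   `"per_sample"`.
#' @export
intensity_bin_bias <- function(lowlevel, sheet, bin_channel = c("green", "red"),
                               mode = c("fi_deviation", "beta_absdev"),
                               values = NULL, n_bins = 100L) {
  bin_channel <- match.arg(bin_channel)
  mode <- match.arg(mode)
  sheet <- validate_sample_sheet(sheet)
  t2 <- lowlevel$manifest$probe_type == "II"
  fi <- lowlevel$mean_fi[[bin_channel]][t2, , drop = FALSE]
  if (mode == "beta_absdev") {
    if (is.null(values)) stop("mode 'beta_absdev' requires a beta matrix in `values`")
    values <- values[rownames(fi), colnames(fi), drop = FALSE]
  }
  G <- nrow(fi)
  if (G < n_bins) {
    warning("fewer probes than bins; reducing to ", G, " bins")
    n_bins <- G
  }
  sh <- sheet[match(lowlevel$samples, sheet$sample_id), , drop = FALSE]
  N <- ncol(fi)
  per_sample <- matrix(NA_real_, n_bins, N, dimnames = list(NULL, colnames(fi)))
  bin_fi <- matrix(NA_real_, n_bins, length(unique(sh$subject)))
  for (si in seq_along(unique(sh$subject))) {
    s <- unique(sh$subject)[si]
    jj <- which(sh$subject == s)
    med_fi <- apply(fi[, jj, drop = FALSE], 1, stats::median)
    bins <- ceiling(rank(med_fi, ties.method = "first") * n_bins / G)
    counts <- tabulate(bins, n_bins)
    bin_fi[, si] <- rowsum(med_fi, bins)[, 1] / counts
    dev <- if (mode == "fi_deviation") {
      d <- fi[, jj, drop = FALSE] - med_fi
      # remove each sample's scalar offset (e.g. its optical background
      # level) so the curve isolates the intensity-dependent component
      sweep(d, 2, apply(d, 2, stats::median))
    } else {
      med_b <- apply(values[, jj, drop = FALSE], 1, stats::median)
      abs(values[, jj, drop = FALSE] - med_b)
    }
    per_sample[, jj] <- rowsum(dev, bins) / counts
  }
  ch_f <- factor(sh$chamber)
  rows <- list()
  for (l in levels(ch_f)) {
    cols <- which(ch_f == l)
    v <- per_sample[, cols, drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      bin = seq_len(n_bins), chamber = l, mean_dev = rowMeans(v),
      se = apply(v, 1, stats::sd) / sqrt(length(cols)),
      n_samples = length(cols), mean_bin_fi = rowMeans(bin_fi),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "per_sample") <- per_sample
  out
}

#' Per-probe variance decomposition with a subject random effect
#'
#' Fits, per probe, a linear mixed model with chamber and slide as fixed
#' effects and subject as a random effect, by closed-form REML: the
#' restricted likelihood is profiled over the variance ratio
#' `lambda = sigma2_subject / sigma2_resid` using a single eigendecomposition
#' of the subject structure projected onto the fixed-effect complement
#' (shared by all probes), a grid search over `lambda` and a local
#' refinement. Marginal (Type III-style) Wald F-statistics are reported for
#' each fixed factor, with `n - rank(X)` residual degrees of freedom.
#'
#' @param x probes-by-samples matrix (complete).
#' @param sheet a [sample_sheet].
#' @param fixed fixed-effect factors, a subset of `c("chamber", "slide")`;
#'   single-level factors are dropped automatically.
#' @return data.frame of class `variance_decomposition` with per-probe
#'   F-statistics and p-values per fixed factor, `sigma2_subject`,
#'   `sigma2_resid` and `lambda`. Probes with a rank-deficient weighted
#'   design are flagged `NA`.
#' @export
variance_decomposition <- function(x, sheet, fixed = c("chamber", "slide")) {
  sh <- match_sheet(x, validate_sample_sheet(sheet))
  if (anyNA(x)) stop("matrix must be complete; run clean_matrix() first")
  fixed <- match.arg(fixed, c("chamber", "slide"), several.ok = TRUE)
  fdf <- data.frame(row.names = seq_len(nrow(sh)))
  for (f in fixed) {
    v <- factor(sh[[f]])
    if (nlevels(v) >= 2) fdf[[f]] <- v
  }
  X <- if (ncol(fdf)) stats::model.matrix(~ ., data = fdf) else
    matrix(1, nrow(sh), 1, dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  r <- qrX$rank
  n <- ncol(x)
  if (r >= n) stop("no residual degrees of freedom")
  asg <- attr(X, "assign")
  subj <- factor(sh$subject)
  Z <- stats::model.matrix(~ 0 + subj)
  ZZt <- tcrossprod(Z)

  # REML contrasts orthogonal to X, shared across probes
  K <- qr.Q(qrX, complete = TRUE)[, (r + 1):n, drop = FALSE]
  ea <- eigen(crossprod(K, ZZt %*% K), symmetric = TRUE)
  d <- pmax(ea$values, 0)
  W2 <- (x %*% (K %*% ea$vectors))^2          # squared REML contrasts, G x (n-r)
  nr <- n - r
  grid <- c(0, exp(seq(log(1e-3), log(1e3), length.out = 61)))
  ll_grid <- vapply(grid, function(lam) {
    as.vector(-0.5 * (nr * log(W2 %*% (1 / (1 + lam * d))) + sum(log1p(lam * d))))
  }, numeric(nrow(x)))
  ll_grid <- matrix(ll_grid, nrow = nrow(x))
  bi <- max.col(ll_grid, ties.method = "first")
  lambda <- grid[bi]
  refine <- which(bi > 1)
  for (i in refine) {
    lo <- grid[max(bi[i] - 1, 1)]
    hi <- grid[min(bi[i] + 1, length(grid))]
    w2 <- W2[i, ]
    opt <- stats::optimize(function(lam) {
      -0.5 * (nr * log(sum(w2 / (1 + lam * d))) + sum(log1p(lam * d)))
    }, lower = lo, upper = hi, maximum = TRUE, tol = 1e-8)
    if (opt$objective > ll_grid[i, bi[i]]) lambda[i] <- opt$maximum
  }

  ez <- eigen(ZZt, symmetric = TRUE)
  D <- pmax(ez$values, 0)
  Xt <- crossprod(ez$vectors, X)
  Yt <- x %*% ez$vectors
  terms_lab <- attr(stats::terms(~ ., data = fdf), "term.labels")
  fcols <- lapply(seq_along(terms_lab), function(k) which(asg == k))
  names(fcols) <- terms_lab

  G <- nrow(x)
  sigma2_e <- as.vector((W2 %*% rep(1, nr)))  # placeholder, filled per probe
  Fmat <- matrix(NA_real_, G, length(terms_lab), dimnames = list(rownames(x), terms_lab))
  for (i in seq_len(G)) {
    v <- 1 + lambda[i] * D
    sw <- 1 / sqrt(v)
    Xw <- Xt * sw
    yw <- Yt[i, ] * sw
    XtX <- crossprod(Xw)
    s2 <- sum(W2[i, ] / (1 + lambda[i] * d)) / nr
    sigma2_e[i] <- s2
    ok <- TRUE
    cov_u <- tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(cov_u)) next
    bhat <- cov_u %*% crossprod(Xw, yw)
    for (k in seq_along(fcols)) {
      cc <- fcols[[k]]
      Fmat[i, k] <- tryCatch(
        drop(t(bhat[cc]) %*% solve(cov_u[cc, cc, drop = FALSE], bhat[cc])) /
          (length(cc) * s2),
        error = function(e) NA_real_
      )
    }
  }
  out <- data.frame(probe_id = rownames(x), stringsAsFactors = FALSE)
  for (k in seq_along(terms_lab)) {
    f <- terms_lab[k]
    out[[paste0("F_", f)]] <- Fmat[, k]
    out[[paste0("p_", f)]] <- stats::pf(Fmat[, k], length(fcols[[k]]), nr, lower.tail = FALSE)
  }
  out$sigma2_resid <- sigma2_e
  out$sigma2_subject <- lambda * sigma2_e
  out$lambda <- lambda
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' PCA and Ward-D2 hierarchical clustering of samples
#'
#' Computes the top principal components of the samples-by-probes matrix,
#' clusters samples on the PC scores with Ward's D2 linkage, cuts the tree
#' at `k` clusters (default: the number of subjects) and reports
#' subject-purity: the fraction of samples whose cluster's majority subject
#' matches their own.
#'
#' @param x probes-by-samples matrix (complete).
#' @param sheet a [sample_sheet].
#' @param n_components number of principal components (default 50; truncated
#'   with a warning if it exceeds `n_samples - 1`).
#' @param k number of clusters to cut at (default: number of subjects).
#' @return List of class `pca_cluster`: `scores`, `hclust`, `clusters`,
#'   `purity`, `var_explained`.
#' @export
pca_cluster <- function(x, sheet, n_components = 50L, k = NULL) {
  sh <- match_sheet(x, validate_sample_sheet(sheet))
  if (anyNA(x)) stop("matrix must be complete; run clean_matrix() first")
  n <- ncol(x)
  if (n_components > n - 1) {
    warning("n_components reduced to ", n - 1)
    n_components <- n - 1
  }
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE, rank. = n_components)
  hc <- stats::hclust(stats::dist(pr$x), method = "ward.D2")
  if (is.null(k)) k <- length(unique(sh$subject))
  cl <- stats::cutree(hc, k = k)
  agree <- 0
  for (c0 in unique(cl)) {
    subjects <- sh$subject[cl == c0]
    agree <- agree + max(table(subjects))
  }
  structure(
    list(scores = pr$x, hclust = hc, clusters = cl, purity = agree / n,
         var_explained = pr$sdev^2 / sum(pr$sdev^2)),
    class = "pca_cluster"
  )
}

#' Grubbs test for a single outlier
#'
#' `G = max |x - mean| / sd`; the two-sided p-value uses the standard
#' t-distribution bound for the one-outlier Grubbs statistic.
#'
#' @param x numeric vector, `n >= 3`, not all equal.
#' @return List with `statistic` (G), `p.value`, and `outlier` (index of the
#'   most extreme value).
#' @export
grubbs_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("Grubbs test needs at least 3 values")
  s <- stats::sd(x)
  if (s == 0) stop("undefined statistic: all values equal")
  dev <- abs(x - mean(x))
  G <- max(dev) / s
  denom <- (n - 1)^2 - n * G^2
  p <- if (denom <= 0) 0 else {
    t2 <- n * (n - 2) * G^2 / denom
    min(1, 2 * n * stats::pt(sqrt(t2), n - 2, lower.tail = FALSE))
  }
  list(statistic = G, p.value = p, outlier = which.max(dev))
}

#' Correlate low-level features with per-probe beta variability
#'
#' For Type II probes, correlates per-probe averages of bead count, green
#' and red mean FI, and green and red bead-level SD with a supplied
#' per-probe beta standard deviation, by Pearson's R and Spearman's rho.
#'
#' @param lowlevel a [lowlevel_set].
#' @param beta_sd named numeric vector of per-probe beta SDs (names matching
#'   Type II probe ids).
#' @return data.frame with columns feature, pearson, spearman; zero-variance
#'   features get `NA` and are listed in attribute `"degenerate"`.
#' @export
lowlevel_correlations <- function(lowlevel, beta_sd) {
  t2 <- type2_probes(lowlevel$manifest)
  t2 <- intersect(t2, names(beta_sd))
  if (!length(t2)) stop("no Type II probes with beta SD values")
  feats <- list(
    n_beads = rowMeans(lowlevel$n_beads$green[t2, , drop = FALSE] +
                         lowlevel$n_beads$red[t2, , drop = FALSE]) / 2,
    green_fi = rowMeans(lowlevel$mean_fi$green[t2, , drop = FALSE]),
    red_fi = rowMeans(lowlevel$mean_fi$red[t2, , drop = FALSE]),
    green_sd_fi = rowMeans(lowlevel$sd_fi$green[t2, , drop = FALSE]),
    red_sd_fi = rowMeans(lowlevel$sd_fi$red[t2, , drop = FALSE])
  )
  y <- beta_sd[t2]
  degenerate <- character(0)
  rows <- lapply(names(feats), function(f) {
    v <- feats[[f]]
    if (stats::sd(v) == 0 || stats::sd(y) == 0) {
      degenerate <<- c(degenerate, f)
      return(data.frame(feature = f, pearson = NA_real_, spearman = NA_real_))
    }
    data.frame(feature = f,
               pearson = stats::cor(v, y, method = "pearson"),
               spearman = stats::cor(v, y, method = "spearman"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- degenerate
  out
}
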