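# Positional-effect correction. combat_adjust implements the standard
# parametric empirical-Bayes location/scale batch adjustment (feature-wise
# standardisation, method-of-moments normal / inverse-gamma priors, iterated
# posterior updates, back-transformation). combat_counts_fi is a count-style
# variant for fluorescence intensities: per-feature negative-binomial batch
# models with method-of-moments dispersions and quantile matching to a
# batch-free target distribution. Batch factor is one of chamber or slide
# per run; no covariates are protected.

aprior <- function(d2) { m <- mean(d2); s2 <- stats::var(d2); (2 * s2 + m^2) / s2 }
bprior <- function(d2) { m <- mean(d2); s2 <- stats::var(d2); (m * s2 + m^3) / s2 }

#' Empirical-Bayes batch adjustment of a feature matrix
#'
#' Standardises each feature, estimates per-batch location (`gamma`) and
#' scale (`delta^2`) effects, shrinks them toward method-of-moments priors
#' (normal for location, inverse-gamma for scale) by iterated posterior
#' updates, removes the shrunken effects and back-transforms. With
#' `shrink = FALSE` the raw batch estimates are used, which reduces the
#' adjustment to a per-batch standardise/restandardise; this is also the
#' zero-prior-precision limit of the EB estimates.
#'
#' @param x complete features-by-samples numeric matrix (run
#'   [clean_matrix()] first if it has missing values).
#' @param batch factor-like batch label per sample (e.g. chamber or slide);
#'   at least two batches, each with at least two samples.
#' @param shrink apply empirical-Bayes shrinkage (default) or use the raw
#'   per-batch estimates.
#' @param clip numeric length-2 range to clip the adjusted values to
#'   (default `c(0, 1)` for beta matrices), or `NULL` for no clipping.
#' @param tol relative-change convergence tolerance of the EB iteration.
#' @param maxit maximum EB iterations per batch.
#' @return Adjusted matrix of the same shape and dimnames.
#' @export
combat_adjust <- function(x, batch, shrink = TRUE, clip = c(0, 1),
                          tol = 1e-4, maxit = 100L) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("matrix must be complete; run clean_matrix() first")
  batch <- factor(batch)
  if (length(batch) != ncol(x)) stop("batch must have one label per sample")
  nb <- table(batch)
  if (length(nb) < 2) stop("need at least 2 batches")
  if (any(nb < 2)) {
    stop("singleton batch(es) ", paste(names(nb)[nb < 2], collapse = ", "),
         ": per-batch scale is undefined")
  }
  n <- ncol(x)
  G <- nrow(x)
  levs <- levels(batch)
  idx <- lapply(levs, function(l) which(batch == l))

  batch_means <- vapply(idx, function(ii) rowMeans(x[, ii, drop = FALSE]), numeric(G))
  batch_means <- matrix(batch_means, nrow = G)
  alpha_hat <- as.vector(batch_means %*% (as.numeric(nb) / n))
  fitted <- batch_means[, as.integer(batch), drop = FALSE]
  var_pooled <- rowSums((x - fitted)^2) / n
  if (any(var_pooled <= 0)) {
    stop("feature(s) with zero pooled variance cannot be standardised: ",
         paste(utils::head(rownames(x)[var_pooled <= 0], 5), collapse = ", "))
  }
  sd_pooled <- sqrt(var_pooled)
  Z <- (x - alpha_hat) / sd_pooled

  out <- Z
  for (k in seq_along(levs)) {
    ii <- idx[[k]]
    nk <- length(ii)
    Zk <- Z[, ii, drop = FALSE]
    g_hat <- rowMeans(Zk)
    d_hat <- rowSums((Zk - g_hat)^2) / (nk - 1)
    if (shrink && G >= 2) {
      g_bar <- mean(g_hat)
      t2 <- stats::var(g_hat)
      a <- aprior(d_hat)
      b <- bprior(d_hat)
      usable <- is.finite(t2) && t2 > 0 && is.finite(a) && is.finite(b) && a > 1
      if (usable) {
        g_star <- g_hat
        d_star <- d_hat
        for (it in seq_len(maxit)) {
          g_new <- (nk * t2 * g_hat + d_star * g_bar) / (nk * t2 + d_star)
          sum2 <- rowSums((Zk - g_new)^2)
          d_new <- (0.5 * sum2 + b) / (nk / 2 + a - 1)
          change <- max(abs(g_new - g_star) / (abs(g_star) + 1e-12),
                        abs(d_new - d_star) / d_star)
          g_star <- g_new
          d_star <- d_new
          if (change < tol) break
        }
      } else {
        g_star <- g_hat
        d_star <- d_hat
      }
    } else {
      g_star <- g_hat
      d_star <- d_hat
    }
    out[, ii] <- (Zk - g_star) / sqrt(d_star)
  }
  out <- out * sd_pooled + alpha_hat
  if (!is.null(clip)) {
    out[out < clip[1]] <- clip[1]
    out[out > clip[2]] <- clip[2]
  }
  dimnames(out) <- dimnames(x)
  out
}

# mid-rank NB CDF quantile map for one batch of one channel
nb_quantile_map <- function(counts, mu_b, size_b, mu_t, size_t) {
  u <- 0.5 * (stats::pnbinom(counts - 1, mu = mu_b, size = size_b) +
                stats::pnbinom(counts, mu = mu_b, size = size_b))
  u <- pmin(u, 1 - 1e-12)
  stats::qnbinom(u, mu = mu_t, size = size_t)
}

#' Count-style batch adjustment of fluorescence intensities
#'
#' Rounds each channel's mean intensities to integer counts, fits per
#' feature a negative-binomial model with batch-specific means and
#' method-of-moments dispersions (floored at `dispersion_floor`), and maps
#' every observed count through mid-rank quantile matching onto the
#' batch-free target distribution whose mean is the geometric mean of the
#' batch means and whose dispersion is the sample-size-weighted pooled
#' dispersion. Features with an all-zero batch in a channel are passed
#' through unadjusted and recorded in the `"passthrough"` attribute.
#'
#' @param lowlevel a [lowlevel_set].
#' @param batch factor-like batch label per sample.
#' @param dispersion_floor lower bound for the moment dispersion estimate.
#' @return A [lowlevel_set] with adjusted `mean_fi` (bead counts and
#'   `sd_fi` are untouched); recompute betas with [beta_matrix()].
#' @export
combat_counts_fi <- function(lowlevel, batch, dispersion_floor = 0.01) {
  batch <- factor(batch)
  nb <- table(batch)
  if (length(nb) < 2) stop("need at least 2 batches")
  if (any(nb < 2)) stop("singleton batch(es): ", paste(names(nb)[nb < 2], collapse = ", "))
  levs <- levels(batch)
  idx <- lapply(levs, function(l) which(batch == l))
  w <- as.numeric(nb) / sum(nb)
  out <- lowlevel
  passthrough <- list()
  for (ch in c("green", "red")) {
    C <- round(lowlevel$mean_fi[[ch]])
    K <- length(levs)
    G <- nrow(C)
    mu <- matrix(NA_real_, G, K)
    phi <- matrix(NA_real_, G, K)
    for (k in seq_len(K)) {
      Ck <- C[, idx[[k]], drop = FALSE]
      m <- rowMeans(Ck)
      v <- rowSums((Ck - m)^2) / (ncol(Ck) - 1)
      mu[, k] <- m
      phi[, k] <- pmax((v - m) / pmax(m, 1e-8)^2, dispersion_floor)
    }
    ok <- rowSums(mu <= 0) == 0
    mu_t <- exp(rowMeans(log(mu[ok, , drop = FALSE])))
    phi_t <- as.vector(phi[ok, , drop = FALSE] %*% w)
    adj <- C
    for (k in seq_len(K)) {
      jj <- idx[[k]]
      adj[ok, jj] <- nb_quantile_map(
        C[ok, jj, drop = FALSE],
        mu_b = mu[ok, k], size_b = 1 / phi[ok, k],
        mu_t = mu_t, size_t = 1 / phi_t
      )
    }
    out$mean_fi[[ch]] <- adj
    passthrough[[ch]] <- rownames(C)[!ok]
  }
  attr(out, "passthrough") <- passthrough
  out
}

#' Summarise a batch correction
#'
#' Tabulates per-batch mean and SD of the matrix values before and after a
#' correction, and (optionally) the median positional F-statistics from
#' [variance_decomposition()] on both matrices.
#'
#' @param before,after features-by-samples matrices (same shape).
#' @param sheet a [sample_sheet] describing the columns.
#' @param batch_by `"chamber"` or `"slide"`.
#' @param f_stats also compute median F-statistics (slower).
#' @return A data.frame with one row per batch and arm (before/after), with
#'   attribute `"f_stats"` when requested.
#' @export
correction_report <- function(before, after, sheet, batch_by = c("chamber", "slide"),
                              f_stats = TRUE) {
  batch_by <- match.arg(batch_by)
  sheet <- validate_sample_sheet(sheet)
  stopifnot(identical(dim(before), dim(after)))
  b <- factor(sheet[[batch_by]][match(colnames(before), sheet$sample_id)])
  rows <- list()
  for (arm in c("before", "after")) {
    x <- if (arm == "before") before else after
    for (l in levels(b)) {
      v <- x[, b == l, drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        batch = l, arm = arm, mean = mean(v, na.rm = TRUE),
        sd = stats::sd(as.vector(v), na.rm = TRUE), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (f_stats) {
    fb <- variance_decomposition(before, sheet)
    fa <- variance_decomposition(after, sheet)
    col <- paste0("F_", batch_by)
    attr(out, "f_stats") <- c(before = stats::median(fb[[col]], na.rm = TRUE),
                              after = stats::median(fa[[col]], na.rm = TRUE))
  }
  out
}
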