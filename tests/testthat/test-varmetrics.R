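test_that("within-subject z-scores centre and scale per subject", {
  sheet <- tiny_sheet(2, 3)
  x <- matrix(c(1, 2, 3, 5, 5, 5), 1, 6,
              dimnames = list("p1", sheet$sample_id))
  z <- within_subject_zscores(x, sheet)
  expect_equal(unname(z[1, 1:3]), c(-1, 0, 1))
  expect_true(all(!is.finite(z[1, 4:6])))  # constant within subject
  set.seed(1)
  y <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("p", 1:10), sheet$sample_id))
  zy <- within_subject_zscores(y, sheet)
  expect_lt(max(abs(rowMeans(zy[, 1:3]))), 1e-12)
  one_rep <- tiny_sheet(2, 3)[c(1:3, 4), ]
  expect_error(within_subject_zscores(y[, 1:4], one_rep), "subject B")
})

test_that("sd_ratio matches plug-in arithmetic", {
  sheet <- tiny_sheet(2, 2)
  x0 <- matrix(0.42, 3, 4, dimnames = list(paste0("p", 1:3), sheet$sample_id))
  expect_equal(unname(sd_ratio(x0, sheet)), rep(0, 3))
  # constructed so mean within-SD = across-SD = 0.1 exactly
  d <- 0.1 / sqrt(2)
  x1 <- matrix(c(0.5 - d, 0.5 + d, 0.4 - d, 0.4 + d), 1, 4,
               dimnames = list("p", sheet$sample_id))
  w <- mean(c(sd(x1[1, 1:2]), sd(x1[1, 3:4])))
  a <- sd(x1[1, ])
  expect_equal(w, 0.1)
  expect_equal(a, 0.1)
  expect_equal(unname(sd_ratio(x1, sheet, offset = 1e-4)), 0.1 / 0.1001)
  # general case against the defining formula computed independently
  set.seed(2)
  x2 <- matrix(runif(40), 10, 4, dimnames = list(paste0("p", 1:10), sheet$sample_id))
  w2 <- (apply(x2[, 1:2], 1, sd) + apply(x2[, 3:4], 1, sd)) / 2
  expect_equal(unname(sd_ratio(x2, sheet)), unname(w2 / (apply(x2, 1, sd) + 1e-4)))
})

test_that("sd_ratio is scale-invariant up to the offset", {
  sheet <- tiny_sheet(2, 3)
  set.seed(3)
  x <- matrix(runif(30), 5, 6, dimnames = list(paste0("p", 1:5), sheet$sample_id))
  r0 <- sd_ratio(x, sheet, offset = 0)
  expect_equal(sd_ratio(3 * x, sheet, offset = 0), r0)
})

test_that("bead-level CV is sd/mean with zero-mean exclusion", {
  man <- mk_manifest(2)
  sheet <- tiny_sheet(1, 2)[, ]
  g <- matrix(c(200, 0, 200, 100), 2, 2, dimnames = list(man$probe_id, c("s01", "s02")))
  ll <- mk_lowlevel(g, g + 50, man)
  ll$sd_fi$green[1, 1] <- 20
  sheet2 <- sample_sheet(c("s01", "s02"), c("A", "A"), c("SL1", "SL1"), c(1, 2), TRUE)
  bc <- bead_cv(ll, sheet2)
  expect_equal(unname(bc$cv$green[1, 1]), 0.1)
  expect_equal(unname(bc$cv$green[1, 2]), 0)   # single-bead sd 0
  expect_true(is.na(bc$cv$green[2, 1]))        # zero mean excluded
  expect_equal(sum(bc$summary$n_zero_mean), 1)
})

test_that("inflated chamber-8 red noise tops the CV ranking", {
  infl <- matrix(1, 8, 2); infl[8, 2] <- 1.5
  dat <- simulate_dataset(sim_config(n_probes = 3000, chamber_cv_inflation = infl, seed = 14))
  bc <- bead_cv(dat$lowlevel, dat$sheet)
  red <- bc$summary[bc$summary$channel == "red", ]
  expect_equal(red$chamber[which.max(red$median)], "8")
  green <- bc$summary[bc$summary$channel == "green", ]
  expect_lt(diff(range(green$median)) / median(green$median), 0.05)
})

test_that("intensity bins centre at zero without bias and recover a scalar gain", {
  dat0 <- simulate_dataset(sim_config(n_probes = 5000, seed = 15))
  ib0 <- intensity_bin_bias(dat0$lowlevel, dat0$sheet, "green", "fi_deviation")
  frac_ok <- mean(abs(ib0$mean_dev) < 3 * ib0$se)
  expect_gte(frac_ok, 0.95)  # per-cell ratios are t7, not normal
  # multiplicative chamber gain: deviations grow in proportion to bin FI
  g <- matrix(1, 8, 2); g[1, ] <- 0.8
  dat1 <- simulate_dataset(sim_config(n_probes = 5000, chamber_gain = g,
                                      subject_effect_sd = 0, prep_noise_sd = 0,
                                      seed = 16))
  ib1 <- intensity_bin_bias(dat1$lowlevel, dat1$sheet, "green", "fi_deviation")
  ch1 <- ib1[ib1$chamber == "1", ]
  slope <- coef(lm(mean_dev ~ mean_bin_fi, data = ch1))[["mean_bin_fi"]]
  # each chamber-1 sample sits 0.2 below the median of 16 replicates of
  # which 2 are dimmed, so the deviation slope is close to the gain deficit
  # (diluted slightly by the shared background offset)
  expect_equal(slope, -0.2, tolerance = 0.1)
})

test_that("beta deviations concentrate in dim green bins under green noise", {
  infl <- matrix(1, 8, 2); infl[, 1] <- 2.5
  dat <- simulate_dataset(sim_config(n_probes = 5000, chamber_cv_inflation = infl,
                                     seed = 17))
  b <- beta_matrix(dat$lowlevel)
  ib <- intensity_bin_bias(dat$lowlevel, dat$sheet, "green", "beta_absdev", values = b)
  agg <- tapply(ib$mean_dev, ib$bin, mean)
  expect_gt(mean(agg[1:10]), mean(agg[91:100]))
})

test_that("variance decomposition matches one-way ANOVA on a balanced design", {
  sheet <- sample_sheet(paste0("s", 1:16), rep(c("A", "B"), each = 8),
                        rep(c("SL1", "SL2"), each = 8), rep(1:8, 2), TRUE)
  set.seed(18)
  m <- matrix(rnorm(48), 3, 16) + rep(rep(rnorm(8, 0, 0.5), 2), each = 3)
  # remove subject-mean differences so the REML ratio sits at the boundary
  for (i in 1:3) for (s in c("A", "B")) {
    j <- sheet$subject == s
    m[i, j] <- m[i, j] - mean(m[i, j])
  }
  dimnames(m) <- list(paste0("p", 1:3), sheet$sample_id)
  vd <- variance_decomposition(m, sheet, fixed = "chamber")
  f_aov <- apply(m, 1, function(v) {
    summary(stats::aov(v ~ factor(sheet$chamber)))[[1]][["F value"]][1]
  })
  expect_equal(unname(vd$F_chamber), unname(f_aov), tolerance = 1e-6)
  expect_equal(vd$sigma2_subject, rep(0, 3))
})

test_that("REML variance components agree with lme4", {
  dat <- simulate_dataset(sim_config(n_probes = 300, seed = 5))
  b <- beta_matrix(dat$lowlevel)[1:25, ]
  vd <- variance_decomposition(b, dat$sheet)
  sh <- dat$sheet[match(colnames(b), dat$sheet$sample_id), ]
  ref <- vapply(1:25, function(i) {
    d <- data.frame(y = b[i, ], ch = factor(sh$chamber), sl = factor(sh$slide),
                    subj = sh$subject)
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ ch + sl + (1 | subj), data = d, REML = TRUE)
    ))
    vc <- as.data.frame(lme4::VarCorr(fit))
    c(vc$vcov[1], vc$vcov[2])
  }, numeric(2))
  expect_equal(vd$sigma2_subject, ref[1, ], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(vd$sigma2_resid, ref[2, ], tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("a subject-free simulation pushes the subject component to zero", {
  dat <- simulate_dataset(sim_config(n_probes = 500, subject_effect_sd = 0,
                                     prep_noise_sd = 0, seed = 19))
  b <- beta_matrix(dat$lowlevel)
  vd <- variance_decomposition(b, dat$sheet)
  expect_lt(median(vd$sigma2_subject / vd$sigma2_resid), 0.1)
})

test_that("PCA clustering: duplicates merge first, purity ignores sample order", {
  dat <- simulate_dataset(sim_config(n_probes = 800, seed = 20))
  b <- beta_matrix(dat$lowlevel)
  b[, 2] <- b[, 1]  # duplicate sample
  expect_warning(pc <- pca_cluster(b, dat$sheet, n_components = 70), "reduced")
  expect_equal(sort(pc$hclust$merge[1, ]), c(-2, -1))
  expect_equal(pc$hclust$height[1], 0)
  perm <- sample(ncol(b))
  pc2 <- pca_cluster(b[, perm], dat$sheet, n_components = 50)
  pc1 <- pca_cluster(b, dat$sheet, n_components = 50)
  expect_equal(pc2$purity, pc1$purity)
})

test_that("Grubbs statistic and p-value match closed-form evaluation", {
  g1 <- grubbs_test(c(1, 2, 3, 10))
  expect_equal(g1$statistic, 6 / sqrt(50 / 3))
  # closed form for df = 2: P(T > t) = (1 - t / sqrt(2 + t^2)) / 2, t = sqrt(48)
  p_manual <- 8 * (1 - sqrt(48) / sqrt(2 + 48)) / 2
  expect_equal(g1$p.value, p_manual)
  expect_equal(g1$outlier, 4L)

  g2 <- grubbs_test(c(-1, 0, 1))
  expect_equal(g2$statistic, 1)
  # df = 1 (Cauchy): p = 2 * 3 * (0.5 - atan(sqrt(3)) / pi) = 1
  expect_equal(g2$p.value, 1)
  expect_gt(g2$p.value, 0.5)

  expect_error(grubbs_test(c(2, 2, 2)), "all values equal")
  expect_error(grubbs_test(c(1, 2)), "at least 3")
  # maximal attainable G for n = 3 gives p = 0 via the bound's boundary
  expect_lt(grubbs_test(c(0, 0, 1))$statistic, (3 - 1) / sqrt(3) + 1e-9)
})

test_that("low-level correlations recover the bead-count effect and pass the null", {
  dat <- simulate_dataset(sim_config(n_probes = 4000, prep_noise_sd = 0, seed = 21))
  b <- beta_matrix(dat$lowlevel)
  sh <- dat$sheet[match(colnames(b), dat$sheet$sample_id), ]
  per_subj <- vapply(unique(sh$subject), function(s) {
    apply(b[, sh$subject == s, drop = FALSE], 1, sd)
  }, numeric(nrow(b)))
  beta_sd <- rowMeans(per_subj)
  cors <- lowlevel_correlations(dat$lowlevel, beta_sd)
  expect_lt(cors$spearman[cors$feature == "n_beads"], 0)
  # shuffled response kills all correlations
  set.seed(1)
  shuf <- sample(beta_sd)
  names(shuf) <- names(beta_sd)
  cors0 <- lowlevel_correlations(dat$lowlevel, shuf)
  expect_true(all(abs(cors0$spearman) < 3 / sqrt(length(beta_sd))))
  # Spearman is invariant to monotone transforms of the response
  cors_m <- lowlevel_correlations(dat$lowlevel, beta_sd^3)
  expect_equal(cors_m$spearman, cors$spearman)
})
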