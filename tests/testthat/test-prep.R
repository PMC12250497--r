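test_that("detection p-values hit the ECDF extremes", {
  man <- mk_manifest(2, 4)
  # two Type II probes: one far above every OOB value, one below all of them
  g <- matrix(c(5000, 1, 300, 310, 295, 305), 6, 1,
              dimnames = list(man$probe_id, "s1"))
  r <- matrix(c(5000, 1, 320, 290, 300, 315), 6, 1, dimnames = dimnames(g))
  ll <- mk_lowlevel(g, r, man)
  dm <- detect_poobah(ll, alpha = 0.05)
  expect_equal(unname(dm$p["cg000001", 1]), 0)
  expect_equal(unname(dm$p["cg000002", 1]), 1)
  expect_false(dm$masked["cg000001", 1])
  expect_true(dm$masked["cg000002", 1])
  ll_no_oob <- mk_lowlevel(g[1:2, , drop = FALSE], r[1:2, , drop = FALSE], mk_manifest(2))
  expect_error(detect_poobah(ll_no_oob), "no out-of-band")
})

test_that("detection p-values are uniform for background-only probes", {
  # signal-free probes: in-band totals share the out-of-band distribution
  cfg <- sim_config(n_probes = 10000, frac_type1 = 0.3,
                    brightness_meanlog = log(1e-6), subject_effect_sd = 0,
                    prep_noise_sd = 0, seed = 6)
  dat <- simulate_dataset(cfg)
  dm <- detect_poobah(dat$lowlevel)
  t2 <- type2_probes <- dat$truth$manifest$probe_id[dat$truth$manifest$probe_type == "II"]
  p <- dm$p[t2, 1]
  # mid-rank ECDF p-values are mildly discrete; ties are expected
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("normexp correction matches the numerically integrated posterior mean", {
  mu <- 300; sig <- 60; al <- 2000
  post_mean_num <- function(x) {
    lo <- max(0, x - mu - 15 * sig)
    hi <- max(x - mu + 15 * sig, 12 * al)
    f <- function(s) s * stats::dnorm(x - s, mu, sig) * stats::dexp(s, 1 / al)
    g <- function(s) stats::dnorm(x - s, mu, sig) * stats::dexp(s, 1 / al)
    stats::integrate(f, lo, hi, rel.tol = 1e-10)$value /
      stats::integrate(g, lo, hi, rel.tol = 1e-10)$value
  }
  xs <- c(100, 300, 500, 2000, 10000)
  got <- limma::normexp.signal(c(mu, log(sig), log(al)), xs)
  expect_equal(got, vapply(xs, post_mean_num, numeric(1)), tolerance = 1e-3)
})

test_that("normexp recovers the true signal mean and stays positive", {
  set.seed(2)
  n2 <- 16000; k1 <- 4000
  man <- mk_manifest(n2, k1)
  n <- n2 + k1
  mu <- 300; sig <- 60; sbar <- 3000
  t1g <- man$probe_type == "I" & man$design_channel == "green"
  t1r <- man$probe_type == "I" & man$design_channel == "red"
  mk_channel <- function(inband_type1) {
    m <- matrix(0, n, 2, dimnames = list(man$probe_id, c("s1", "s2")))
    for (j in 1:2) {
      m[1:n2, j] <- rexp(n2, 1 / sbar) + rnorm(n2, mu, sig)
      m[which(inband_type1), j] <- rexp(sum(inband_type1), 1 / sbar) +
        rnorm(sum(inband_type1), 2 * mu, sqrt(2) * sig)
      oob <- man$probe_type == "I" & !inband_type1
      m[which(oob), j] <- rnorm(sum(oob), 2 * mu, sqrt(2) * sig)
    }
    pmax(m, 0)
  }
  ll <- mk_lowlevel(mk_channel(t1g), mk_channel(t1r), man)
  out <- background_correct_normexp(ll)
  expect_true(all(out$mean_fi$green > 0))
  expect_true(all(out$mean_fi$red > 0))
  expect_equal(mean(out$mean_fi$green[1:n2, ]), sbar, tolerance = 0.05)
  expect_equal(mean(out$mean_fi$red[1:n2, ]), sbar, tolerance = 0.05)
})

test_that("normexp is near the identity in the noise-free limit", {
  set.seed(4)
  man <- mk_manifest(200, 40)
  n <- 240
  g <- matrix(runif(n * 2, 2000, 8000), n, 2, dimnames = list(man$probe_id, c("a", "b")))
  r <- matrix(runif(n * 2, 2000, 8000), n, 2, dimnames = dimnames(g))
  oobch <- oob_channel(man)
  # out-of-band reads concentrated near zero: background mean and SD ~ 0
  g[which(oobch == "green"), ] <- abs(rnorm(sum(oobch == "green", na.rm = TRUE) * 2, 0, 1e-3))
  r[which(oobch == "red"), ] <- abs(rnorm(sum(oobch == "red", na.rm = TRUE) * 2, 0, 1e-3))
  ll <- mk_lowlevel(g, r, man)
  out <- background_correct_normexp(ll)
  t2 <- man$probe_type == "II"
  expect_equal(out$mean_fi$green[t2, ], g[t2, ], tolerance = 1e-4)
})

test_that("dye-bias scaling equalises Type II channel medians", {
  set.seed(5)
  man <- mk_manifest(500)
  g <- matrix(abs(rnorm(1000, 4000, 800)), 500, 2,
              dimnames = list(man$probe_id, c("a", "b")))
  ll <- mk_lowlevel(g, 2 * g, man)
  out <- dye_bias_scale(ll)
  expect_equal(unname(attr(out, "dye_scale")), c(0.5, 0.5))
  expect_equal(out$mean_fi$red, g)
  # random imbalance: post-correction median ratio is 1 to floating precision
  r2 <- matrix(abs(rnorm(1000, 2500, 900)), 500, 2, dimnames = dimnames(g))
  out2 <- dye_bias_scale(mk_lowlevel(g, r2, man))
  rat <- apply(out2$mean_fi$red, 2, median) / apply(out2$mean_fi$green, 2, median)
  expect_equal(unname(rat), c(1, 1), tolerance = 1e-9)
})

test_that("run_prep composes deterministically and is probe-order equivariant", {
  cfg <- sim_config(n_probes = 600, seed = 8)
  dat <- simulate_dataset(cfg)
  p1 <- run_prep(dat$lowlevel)
  p2 <- run_prep(dat$lowlevel)
  expect_identical(p1$beta, p2$beta)

  perm <- sample(nrow(dat$truth$manifest))
  ll <- dat$lowlevel
  ll$manifest <- validate_manifest(ll$manifest[perm, ])
  for (part in c("mean_fi", "sd_fi", "n_beads")) {
    for (ch in c("green", "red")) ll[[part]][[ch]] <- ll[[part]][[ch]][perm, ]
  }
  p3 <- run_prep(ll)
  common <- rownames(p1$beta)
  expect_equal(p3$beta[common, ], p1$beta[common, ])
})

test_that("a sample with an abnormally low detection rate is Grubbs-flagged", {
  cfg <- sim_config(n_probes = 2000, frac_type1 = 0.2, seed = 13)
  dat <- simulate_dataset(cfg)
  ll <- dat$lowlevel
  # degrade one sample: most of its probes drop to background level
  kill <- seq_len(1200)
  ll$mean_fi$green[kill, 3] <- ll$mean_fi$green[kill, 3] * 0.01
  ll$mean_fi$red[kill, 3] <- ll$mean_fi$red[kill, 3] * 0.01
  pr <- run_prep(ll)
  expect_true(pr$sample_qc$flagged[3])
  expect_equal(sum(pr$sample_qc$flagged), 1)
})
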