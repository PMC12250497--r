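test_that("EB adjustment is near the identity when batches share a distribution", {
  set.seed(1)
  x <- matrix(rnorm(1000 * 100, 0.5, 0.02), 1000, 100)
  rownames(x) <- paste0("p", 1:1000)
  batch <- rep(c("a", "b"), each = 50)
  out <- combat_adjust(x, batch, clip = NULL)
  expect_lt(mean(abs(out - x)), 0.01)
})

test_that("a location-only batch shift is removed", {
  set.seed(2)
  G <- 500
  delta <- 0.08
  x <- cbind(matrix(rnorm(G * 20, 0.5, 0.02), G, 20),
             matrix(rnorm(G * 20, 0.5, 0.02), G, 20) + delta)
  rownames(x) <- paste0("p", 1:G)
  batch <- rep(c("a", "b"), each = 20)
  out <- combat_adjust(x, batch, clip = NULL)
  diff_after <- rowMeans(out[, 21:40]) - rowMeans(out[, 1:20])
  expect_lt(median(abs(diff_after)), 0.05 * delta)
})

test_that("with a single feature the location estimate is unshrunken", {
  set.seed(3)
  x <- matrix(rnorm(24, 10, 1), 1, 24)
  rownames(x) <- "p1"
  batch <- rep(c("a", "b"), each = 12)
  expect_equal(combat_adjust(x, batch, shrink = TRUE, clip = NULL),
               combat_adjust(x, batch, shrink = FALSE, clip = NULL))
})

test_that("the zero-prior-precision limit equals direct per-batch standardisation", {
  set.seed(4)
  x <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("f", 1:5), paste0("s", 1:12)))
  batch <- rep(c("a", "b"), each = 6)
  got <- combat_adjust(x, batch, shrink = FALSE, clip = NULL)
  # independent location-scale oracle
  nb <- table(batch)
  bm <- vapply(names(nb), function(l) rowMeans(x[, batch == l]), numeric(5))
  alpha <- as.vector(bm %*% (as.numeric(nb) / 12))
  vp <- rowSums((x - bm[, match(batch, names(nb))])^2) / 12
  Z <- (x - alpha) / sqrt(vp)
  for (l in names(nb)) {
    zz <- Z[, batch == l]
    Z[, batch == l] <- (zz - rowMeans(zz)) / sqrt(apply(zz, 1, var))
  }
  oracle <- Z * sqrt(vp) + alpha
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("the EB adjustment agrees with an independent ComBat implementation", {
  set.seed(5)
  x <- matrix(rnorm(50 * 20, 5, 1), 50, 20, dimnames = list(paste0("f", 1:50), NULL))
  batch <- rep(c("a", "b"), each = 10)
  x[, batch == "b"] <- x[, batch == "b"] + rnorm(50, 0.5, 0.3)
  mine <- combat_adjust(x, batch, clip = NULL)
  theirs <- suppressMessages(sva::ComBat(x, batch = batch))
  expect_equal(mine, theirs, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("adjustment refuses singleton batches and commutes with reordering", {
  x <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  expect_error(combat_adjust(x, c(rep("a", 9), "b")), "singleton")
  batch <- rep(c("a", "b"), 5)
  out <- combat_adjust(x, batch, clip = NULL)
  pf <- sample(4); ps <- sample(10)
  out_perm <- combat_adjust(x[pf, ps], batch[ps], clip = NULL)
  expect_equal(out_perm, out[pf, ps])
})

test_that("beta-space adjustment clips to [0, 1]", {
  set.seed(6)
  x <- matrix(rbeta(200 * 16, 0.3, 0.3), 200, 16)
  rownames(x) <- paste0("p", 1:200)
  out <- combat_adjust(x, rep(c("a", "b"), each = 8))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("count adjustment is the identity (within rounding) on duplicated batches", {
  set.seed(7)
  man <- mk_manifest(1000)
  half <- matrix(rpois(1000 * 10, 3000), 1000, 10)
  g <- cbind(half, half)
  colnames(g) <- paste0("s", 1:20)
  rownames(g) <- man$probe_id
  r <- g[, c(11:20, 1:10)]
  dimnames(r) <- dimnames(g)
  ll <- mk_lowlevel(g, r, man)
  out <- combat_counts_fi(ll, rep(c("a", "b"), each = 10))
  d <- abs(out$mean_fi$green - round(g))
  expect_gte(mean(d <= 1), 0.99)
  expect_true(all(out$mean_fi$green >= 0))
  expect_true(all(out$mean_fi$green == round(out$mean_fi$green)))
})

test_that("count adjustment removes a known multiplicative batch gain", {
  set.seed(8)
  man <- mk_manifest(1000)
  mu <- runif(1000, 500, 8000)
  mk <- function(gain, k) matrix(rnbinom(1000 * k, mu = gain * mu, size = 50), 1000, k)
  g <- cbind(mk(1, 20), mk(2, 20))
  dimnames(g) <- list(man$probe_id, paste0("s", 1:40))
  r <- cbind(mk(1, 20), mk(2, 20))
  dimnames(r) <- dimnames(g)
  ll <- mk_lowlevel(g, r, man)
  batch <- rep(c("a", "b"), each = 20)
  out <- combat_counts_fi(ll, batch)
  ma <- rowMeans(out$mean_fi$green[, 1:20])
  mb <- rowMeans(out$mean_fi$green[, 21:40])
  expect_lt(median(abs(mb / ma - 1)), 0.05)
  # per-sample totals are not grossly distorted
  tot_before <- colSums(g)
  tot_after <- colSums(out$mean_fi$green)
  expect_lt(median(abs(tot_after / tot_before - c(sqrt(2), 1 / sqrt(2))[rep(1:2, each = 20)])),
            0.05)
})

test_that("zero counts map into the NB support", {
  man <- mk_manifest(50)
  set.seed(9)
  g <- matrix(rpois(50 * 8, 5), 50, 8, dimnames = list(man$probe_id, paste0("s", 1:8)))
  g[1, 1] <- 0
  ll <- mk_lowlevel(g, g + 1, man)
  out <- combat_counts_fi(ll, rep(c("a", "b"), each = 4))
  v <- out$mean_fi$green
  expect_true(all(v >= 0 & v == round(v)))
})

test_that("correction_report tabulates both arms and the F-statistic drop", {
  dat <- simulate_dataset(paper_scenario(seed = 30, n_probes = 1500))
  b <- beta_matrix(dat$lowlevel)
  ch <- dat$sheet$chamber[match(colnames(b), dat$sheet$sample_id)]
  after <- combat_adjust(b, ch)
  rep_ <- correction_report(b, after, dat$sheet, "chamber")
  expect_equal(nrow(rep_), 8 * 2)
  fs <- attr(rep_, "f_stats")
  expect_lt(fs["after"], fs["before"])
})
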