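test_that("wasserstein_1d: identity, shifts, sorted-sample oracle, metric", {
  set.seed(1)
  a <- rlnorm(40, 5, 0.6)
  expect_equal(wasserstein_1d(a, a), 0)
  expect_equal(wasserstein_1d(a, a + 3.7), 3.7, tolerance = 1e-12)

  # equal-n oracle: mean |sorted(a) - sorted(b)|
  for (rep in 1:10) {
    b <- rlnorm(40, 5, 0.8)
    expect_equal(wasserstein_1d(a, b), mean(abs(sort(a) - sort(b))),
                 tolerance = 1e-10)
  }

  # unequal sizes against a fine-grid quantile oracle
  b2 <- rlnorm(25, 5.2, 0.5)
  qgrid <- seq(0.0005, 0.9995, by = 0.001)
  oracle <- mean(abs(quantile(a, qgrid, type = 1) - quantile(b2, qgrid, type = 1)))
  expect_equal(wasserstein_1d(a, b2), oracle, tolerance = 0.02 * oracle)

  # triangle inequality, fuzzed
  for (rep in 1:20) {
    x <- rnorm(15); y <- rnorm(12, 1); z <- rnorm(18, -1)
    expect_lte(wasserstein_1d(x, z),
               wasserstein_1d(x, y) + wasserstein_1d(y, z) + 1e-12)
  }
  expect_error(wasserstein_1d(numeric(0), a), "empty")
})

test_that("wasserstein permutation test behaves at the extremes", {
  set.seed(2)
  x <- rnorm(30)
  same <- wasserstein_test(x, sample(x), n_perm = 199, seed = 3)
  expect_gt(same$p_value, 0.2)

  far <- wasserstein_test(x, x + 100, n_perm = 199, seed = 3)
  expect_equal(far$p_value, 1 / 200)

  degen <- wasserstein_test(rep(2, 10), rep(2, 12), n_perm = 99, seed = 1)
  expect_equal(degen$p_value, 1)
  expect_error(wasserstein_test(x, x, n_perm = 50), "99")
})

test_that("permutation p matches an independent re-implementation", {
  set.seed(4)
  a <- rlnorm(20); b <- rlnorm(24, 0.4)
  got <- wasserstein_test(a, b, n_perm = 299, seed = 11)
  # independent oracle re-drawing the same permutation stream
  pool <- c(a, b); na <- length(a)
  set.seed(11)
  perm <- vapply(1:299, function(i) {
    idx <- sample.int(length(pool), na)
    x <- sort(pool[idx]); y <- sort(pool[-idx])
    # direct quantile-integral on the merged support
    m <- sort(pool); n <- length(m)
    Fa <- findInterval(m[-n], x) / length(x)
    Fb <- findInterval(m[-n], y) / length(y)
    sum(abs(Fa - Fb) * diff(m))
  }, 0)
  expect_equal(got$p_value, (1 + sum(perm >= got$statistic)) / 300)
})

test_that("pcoa reproduces planar configurations and the cmdscale oracle", {
  set.seed(5)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(pts))
  emb <- pcoa_embed(D, dims = 2)
  expect_equal(as.matrix(dist(emb$coords)), D, tolerance = 1e-8,
               ignore_attr = TRUE)

  D0 <- matrix(0, 4, 4)
  emb0 <- pcoa_embed(D0)
  expect_true(all(abs(emb0$coords) < 1e-10))

  # random metric matrix: embedded-vs-input correlation equals cmdscale's
  x <- matrix(rnorm(40), 10, 4)
  Dr <- as.matrix(dist(x))
  embr <- pcoa_embed(Dr, dims = 2)
  ref <- stats::cmdscale(Dr, k = 2)
  got_cor <- cor(embr$shepard$input, embr$shepard$embedded)
  ut <- upper.tri(Dr)
  ref_cor <- cor(Dr[ut], as.matrix(dist(ref))[ut])
  expect_equal(got_cor, ref_cor, tolerance = 1e-10)
  # shepard pairs expose the linearity check inputs
  expect_equal(nrow(embr$shepard), sum(ut))
})

test_that("normalization by replicate mean and its invariances", {
  out <- normalize_by_mean(list(a = c(2, 4)))
  expect_equal(out$a, c(2, 4) / 3)
  expect_equal(mean(out$a), 1)

  already <- c(0.5, 1.5)
  expect_equal(normalize_by_mean(list(x = already))$x, already)

  set.seed(6)
  reps <- list(r1 = rlnorm(50, 4), r2 = rlnorm(60, 6), r3 = rlnorm(40, 5))
  n1 <- normalize_by_mean(reps)
  reps2 <- reps; reps2$r2 <- reps2$r2 * 37.5
  n2 <- normalize_by_mean(reps2)
  for (i in 1:3) for (j in 1:3)
    expect_equal(wasserstein_1d(n1[[i]], n1[[j]]),
                 wasserstein_1d(n2[[i]], n2[[j]]), tolerance = 1e-12)
  expect_true(all(vapply(n1, function(x) abs(mean(x) - 1) < 1e-12, NA)))
  expect_error(normalize_by_mean(list(z = numeric(0))), "empty")
})

test_that("giant density, area fraction and pooled-variance t-tests", {
  mk <- function(gareas, pareas) {
    n <- length(gareas) + length(pareas)
    data.frame(id = seq_len(n), area_um2 = c(gareas, pareas),
               cell_type = c(rep("giant", length(gareas)),
                             rep("pavement", length(pareas))))
  }
  tabs <- list(g1 = list(mk(100, 100), mk(c(100, 50), 150), mk(150, 50)),
               g2 = list(mk(300, 100), mk(350, 150), mk(400, 100)))
  segs <- list(g1 = c(1e6, 1e6, 1e6), g2 = c(1e6, 1e6, 1e6))
  res <- giant_density_and_area(tabs, segs)
  expect_equal(res$summary$density_per_mm2[1:3], c(1, 2, 1))
  expect_equal(res$summary$area_fraction[res$summary$group == "g2"],
               c(300, 350, 400) / 1e6)

  # oracle: equal-variance t.test on densities
  ref <- t.test(c(1, 2, 1), c(1, 1, 1), var.equal = TRUE)
  expect_equal(res$tests$t, unname(ref$statistic))
  expect_equal(res$tests$p, ref$p.value)

  # identical groups -> t = 0, p = 1
  res0 <- giant_density_and_area(list(a = tabs$g1, b = tabs$g1),
                                 list(a = segs$g1, b = segs$g1))
  expect_equal(res0$tests$t, 0)
  expect_equal(res0$tests$p, 1)

  # giants covering half the segmented area -> fraction 0.5
  half <- mk(500, 500)
  resh <- giant_density_and_area(list(h = list(half)), list(h = 1000))
  expect_equal(resh$summary$area_fraction, 0.5)
  expect_message(giant_density_and_area(list(a = tabs$g1, b = list(mk(1, 1))),
                                        list(a = segs$g1, b = 1e6)),
                 "skipped")
})
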