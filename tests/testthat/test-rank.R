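# Independent brute-force implementations used as oracles in this file.

brute_bandwidth <- function(psd, fraction = 0.99) {
  n <- length(psd)
  dc <- floor(n / 2) + 1L
  even <- n %% 2L == 0L
  n_pos <- if (even) n %/% 2L - 1L else (n - 1L) %/% 2L
  build <- function(dir) {
    e <- psd[dc] / 2
    for (j in seq_len(n_pos)) e <- c(e, psd[dc + dir * j])
    if (even) e <- c(e, psd[1] / 2)
    e
  }
  side <- function(e) {
    target <- fraction * sum(e)
    acc <- 0
    for (b in seq_along(e)) {
      acc <- acc + e[b]
      if (acc >= target - 1e-15) return(b / length(e))
    }
    1
  }
  mean(c(side(build(1L)), side(build(-1L))))
}

brute_pearson_abs <- function(U) {
  A <- abs(U)
  n <- ncol(A)
  C <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    a <- A[, i]; b <- A[, j]
    C[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  C
}

# Temporal vectors with r slowly varying (narrowband) columns followed by
# white noise.
make_V <- function(r, n_t = 100L, n_noise = 29L, seed = 1L) {
  set.seed(seed)
  slow <- sapply(seq_len(r), function(k)
    cos(2 * pi * k * seq_len(n_t) / n_t + runif(1, 0, 2 * pi)))
  noise <- matrix(rnorm(n_t * n_noise), n_t)
  qr.Q(qr(cbind(slow, noise)))[, seq_len(r + n_noise)]
}

test_that("temporal PSD satisfies Fourier-pair and Parseval identities", {
  n <- 64L
  # constant vector: all energy in the central (DC) bin
  psd <- temporal_psd(matrix(1, n, 1))
  expect_equal(psd[1, floor(n / 2) + 1L], sum(rep(1, n)^2))
  expect_equal(sum(psd[1, -(floor(n / 2) + 1L)]), 0, tolerance = 1e-20)

  # pure sinusoid at bin f: energy split between the +-f bins
  f <- 5L
  v <- cos(2 * pi * f * (0:(n - 1)) / n)
  psd <- temporal_psd(matrix(v, n, 1))[1, ]
  dc <- floor(n / 2) + 1L
  expect_equal(psd[dc + f] + psd[dc - f], sum(v^2), tolerance = 1e-10)
  expect_equal(psd[dc + f], psd[dc - f], tolerance = 1e-10)

  # white noise: Parseval per realization
  set.seed(4)
  V <- matrix(rnorm(n * 6), n, 6)
  psd <- temporal_psd(V)
  expect_equal(rowSums(psd), colSums(V^2), tolerance = 1e-10)

  expect_error(temporal_psd(matrix(1, 4, 2)), ">= 8")
})

test_that("bandwidth99 matches a brute-force cumulative-sum oracle", {
  set.seed(9)
  for (n in c(16L, 32L, 33L, 64L)) {
    for (trial in 1:20) {
      psd <- abs(rnorm(n))^2
      expect_equal(bandwidth99(psd), brute_bandwidth(psd),
                   tolerance = 1e-12)
    }
  }
})

test_that("bandwidth99 behaves correctly for canonical spectra", {
  n <- 32L
  dc <- floor(n / 2) + 1L
  # all energy at DC: a single bin per side
  psd <- numeric(n); psd[dc] <- 1
  expect_lt(bandwidth99(psd), 1.2 / (n / 2))
  # flat PSD: ~99% of the band
  expect_equal(bandwidth99(rep(1, n)), 0.99, tolerance = 0.02)
  # >=99.5% concentrated within +-3 bins: narrow band, matches the oracle
  psd <- rep(0.0005 / (n - 7), n)
  psd[(dc - 3):(dc + 3)] <- 0.9995 / 7
  expect_equal(bandwidth99(psd), brute_bandwidth(psd), tolerance = 1e-12)
  expect_lt(bandwidth99(psd), 4.5 / 16)
  expect_gt(bandwidth99(psd), 2.5 / 16)
  expect_error(bandwidth99(numeric(8)), "zero-energy")
})

test_that("temporal estimator recovers the slow-subspace dimension", {
  hits <- 0L
  for (s in 1:20) {
    est <- estimate_rank_temporal(make_V(3, seed = s))
    hits <- hits + (est$k == 3L)
  }
  expect_gte(hits, 19L)

  # all-noise input clamps to 1
  set.seed(5)
  V <- qr.Q(qr(matrix(rnorm(100 * 20), 100)))[, 1:20]
  expect_equal(estimate_rank_temporal(V)$k, 1L)
})

test_that("shuffling noise-only orders leaves the temporal estimate fixed", {
  V <- make_V(3, seed = 11)
  k0 <- estimate_rank_temporal(V)$k
  set.seed(2)
  Vp <- V
  Vp[, 4:32] <- Vp[, sample(4:32)]
  expect_equal(estimate_rank_temporal(Vp)$k, k0)
  expect_equal(k0, 3L)
})

test_that("spatial similarity matrix equals Pearson correlation of |u|", {
  set.seed(13)
  U <- matrix(rnorm(1000 * 10), 1000, 10)
  C <- spatial_similarity_matrix(U)
  expect_equal(C, brute_pearson_abs(U), tolerance = 1e-12)
  expect_equal(diag(C), rep(1, 10))
  expect_equal(C, t(C))
  expect_true(all(abs(C) <= 1 + 1e-12))

  # identical columns correlate perfectly
  U2 <- cbind(U[, 1], U[, 1], U[, 2])
  expect_equal(spatial_similarity_matrix(U2)[1, 2], 1)

  expect_error(spatial_similarity_matrix(cbind(U[, 1], 1)), "order 2")
})

test_that("spatial estimator finds the leading correlated block", {
  # constructed boundary: 4x4 block of 0.8, near-zero elsewhere
  set.seed(17)
  C <- diag(12)
  C[1:4, 1:4] <- 0.8; diag(C) <- 1
  C[5:12, 5:12][upper.tri(C[5:12, 5:12])] <- runif(28, -0.02, 0.02)
  C[5:12, 5:12][lower.tri(C[5:12, 5:12])] <-
    t(C[5:12, 5:12])[lower.tri(C[5:12, 5:12])]
  expect_equal(estimate_rank_spatial(C), 4L)
  expect_equal(estimate_rank_spatial(C, threshold = 0.2), 4L)

  # identity matrix: no correlated block beyond the minimum
  expect_equal(estimate_rank_spatial(diag(10)), 1L)
  expect_equal(estimate_rank_spatial(diag(10), threshold = 0.2), 1L)
})

test_that("both estimators agree on coherent low-rank + noise matrices", {
  for (r in c(2L, 4L)) {
    x <- synthetic_lowrank_casorati(r, m = 3000L, seed = 500L + r)
    est <- estimate_rank(x$S, orders = 20L)
    expect_equal(est$k_temporal, r)
    expect_equal(est$k_spatial, r)
    expect_lte(abs(est$k_temporal - est$k_spatial), 1L)
    expect_equal(est$k, min(est$k_temporal, est$k_spatial))
  }
})

test_that("rank diagnostics are written as image files", {
  x <- synthetic_lowrank_casorati(3L, m = 2000L, seed = 77L)
  est <- estimate_rank(x$S, orders = 16L)
  V <- full_svd(x$S)$v
  d <- withr::local_tempdir()
  p1 <- file.path(d, "psd.png"); p2 <- file.path(d, "sim.png")
  plot_rank_diagnostics(est, V, p1, p2)
  expect_true(file.exists(p1) && file.size(p1) > 0)
  expect_true(file.exists(p2) && file.size(p2) > 0)
})
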