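test_that("PSNR follows its closed forms and logarithm laws", {
  X <- matrix(runif(100), 10, 10)
  expect_identical(pa_psnr(X, X), Inf)

  # max(X) = 1 and uniform |X - Y| = 0.1 gives 10 log10(1 / 0.01) = 20 dB
  X <- matrix(0.5, 8, 8); X[1, 1] <- 1
  Y <- X + 0.1
  expect_equal(pa_psnr(X, Y), 20, tolerance = 1e-12)

  # shrinking the error field by 10 raises PSNR by 20 dB
  Y10 <- X + 0.01
  expect_equal(pa_psnr(X, Y10) - pa_psnr(X, Y), 20, tolerance = 1e-10)

  # the standard convention squares the peak: differs by 10 log10(max)
  Z <- 2 * X
  expect_equal(pa_psnr(Z, Z + 0.1, convention = "standard") -
                 pa_psnr(Z, Z + 0.1), 10 * log10(2), tolerance = 1e-10)

  expect_error(pa_psnr(X, matrix(0, 2, 2)), "shape")
})

test_that("SSIM matches closed forms and an independent implementation", {
  set.seed(3)
  X <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(pa_ssim(X, X), 1, tolerance = 1e-15)

  # constant images, raw evaluation: sigma terms vanish
  a <- 30; b <- 70; C1 <- (0.01 * 255)^2
  expect_equal(pa_ssim(matrix(a, 5, 5), matrix(b, 5, 5), rescale = FALSE),
               (2 * a * b + C1) / (a^2 + b^2 + C1), tolerance = 1e-12)

  # independent textbook implementation (global window)
  ssim_oracle <- function(X, Y, L = 255) {
    C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
    mx <- mean(X); my <- mean(Y)
    vx <- stats::var(as.vector(X)); vy <- stats::var(as.vector(Y))
    cxy <- stats::cov(as.vector(X), as.vector(Y))
    (2 * mx * my + C1) * (2 * cxy + C2) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  Y <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(pa_ssim(X, Y, rescale = FALSE), ssim_oracle(X, Y),
               tolerance = 1e-12)
  expect_equal(pa_ssim(X, Y), pa_ssim(Y, X), tolerance = 1e-12)
})

test_that("EPI is 1 for identical or offset images and drops with blur", {
  set.seed(5)
  Y <- matrix(rnorm(900), 30, 30)
  expect_equal(pa_epi(Y, Y), 1, tolerance = 1e-12)
  expect_equal(pa_epi(Y + 5, Y), 1, tolerance = 1e-10)

  # separable binomial [1 2 1]/4 smoothing (non-negative transfer function)
  blur <- function(img, times) {
    n <- nrow(img); m <- ncol(img)
    for (i in seq_len(times)) {
      img <- (img[c(1, 1:(n - 1)), ] + 2 * img + img[c(2:n, n), ]) / 4
      img <- (img[, c(1, 1:(m - 1))] + 2 * img + img[, c(2:m, m)]) / 4
    }
    img
  }
  epis <- sapply(c(1, 3, 6), function(t) pa_epi(blur(Y, t), Y))
  expect_true(all(epis < 1))
  expect_true(all(diff(epis) < 0))

  expect_error(pa_epi(matrix(1, 5, 5), Y[1:5, 1:5]), "zero variance")
})

test_that("ROI SNR follows the amplitude-ratio definition", {
  set.seed(11)
  img <- matrix(rnorm(40 * 40), 40, 40)          # noise sd 1
  img[5:12, 5:12] <- 10                          # constant signal block
  rois <- roi_set(list(c(5, 12, 5, 12)), list(c(25, 32, 25, 32)),
                  dim = dim(img))
  expect_equal(image_snr(img, rois), 10, tolerance = 0.6)

  img2 <- img; img2[5:12, 5:12] <- 20            # doubled signal amplitude
  expect_equal(image_snr(img2, rois) - image_snr(img, rois),
               10 * log10(2), tolerance = 1e-10)

  # hand-computed 3x3 example
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3)
  m[4:6, 4:6] <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  r <- roi_set(list(c(1, 3, 1, 3)), list(c(4, 6, 4, 6)), dim = c(6, 6))
  expect_equal(image_snr(m, r),
               10 * log10(5 / stats::sd(c(0, 1, 0, 1, 0, 1, 0, 1, 0))),
               tolerance = 1e-12)
})

test_that("ROI CNR follows its arithmetic definition", {
  img <- matrix(0, 20, 20)
  img[1:5, 1:5] <- 5
  set.seed(2)
  noise_vals <- 1 + 2 * scale(rnorm(25))          # mean 1, sd 2 exactly
  img[10:14, 10:14] <- noise_vals
  rois <- roi_set(list(c(1, 5, 1, 5)), list(c(10, 14, 10, 14)),
                  dim = dim(img))
  expect_equal(image_cnr(img, rois), (5 - 1) / 2, tolerance = 1e-12)

  # identical statistics give ~0
  img2 <- img; img2[1:5, 1:5] <- noise_vals
  expect_lt(image_cnr(img2, rois), 1e-12)

  # multiple ROIs against brute-force arithmetic (amplitude-like image)
  set.seed(8)
  big <- matrix(abs(rnorm(900)), 30, 30)
  sig <- list(c(1, 4, 1, 4), c(10, 13, 1, 4))
  noi <- list(c(20, 23, 20, 23), c(25, 28, 10, 13))
  rr <- roi_set(sig, noi, dim = dim(big))
  mu_s <- mean(sapply(sig, function(r) mean(big[r[1]:r[2], r[3]:r[4]])))
  mu_n <- mean(sapply(noi, function(r) mean(big[r[1]:r[2], r[3]:r[4]])))
  sd_n <- mean(sapply(noi, function(r) sd(big[r[1]:r[2], r[3]:r[4]])))
  expect_equal(image_cnr(big, rr), abs(mu_s - mu_n) / sd_n,
               tolerance = 1e-12)
  expect_equal(image_snr(big, rr), 10 * log10(mu_s / sd_n),
               tolerance = 1e-12)
})

test_that("roi_set validates geometry", {
  expect_error(roi_set(list(c(1, 3, 1, 3)), list(c(2, 4, 2, 4)),
                       dim = c(10, 10)), "overlap")
  expect_error(roi_set(list(c(1, 3, 1, 3)), list(c(5, 6, 5, 6)),
                       dim = c(10, 10)), "same number of pixels")
  expect_error(roi_set(list(c(1, 3, 1, 3)), list(c(9, 11, 1, 3)),
                       dim = c(10, 10)), "outside")
})

test_that("axial FWHM matches closed forms", {
  spacing <- 0.01
  z <- seq(0, 4, by = spacing)
  # Gaussian: FWHM = 2 sqrt(2 ln 2) sigma = 2.3548 sigma
  g <- exp(-(z - 2)^2 / (2 * 0.1^2))
  expect_equal(axial_fwhm(g, spacing), 2 * sqrt(2 * log(2)) * 0.1,
               tolerance = 0.01)
  # triangle of half-width w: FWHM = w
  w <- 0.5
  tri <- pmax(0, 1 - abs(z - 2) / w)
  expect_equal(axial_fwhm(tri, spacing), w, tolerance = 1e-6)
  # coarsely sampled modulated envelope vs a dense-grid oracle
  f <- function(z) abs(cos(2 * pi * 7 * (z - 2))) *
    exp(-(z - 2)^2 / (2 * 0.2^2))
  coarse_z <- seq(1, 3, by = 0.05)
  env <- exp(-(coarse_z - 2)^2 / (2 * 0.2^2))
  dense_z <- seq(1, 3, by = 0.0005)
  dense <- exp(-(dense_z - 2)^2 / (2 * 0.2^2))
  expect_equal(axial_fwhm(env, 0.05), axial_fwhm(dense, 0.0005),
               tolerance = 0.0055)
  # error cases: boundary peak and missing crossing
  expect_error(axial_fwhm(seq(0, 1, by = 0.1), 0.1), "boundary")
  expect_error(axial_fwhm(c(1, 1.2, 1.1, 1, 0.9), 0.1), "crossing")
})

test_that("reference metrics are invariant under a common shift", {
  set.seed(21)
  X <- matrix(runif(400), 20, 20)
  Y <- X + matrix(rnorm(400, sd = 0.05), 20, 20)
  shift <- function(m) m[c(3:20, 1:2), c(5:20, 1:4)]
  expect_equal(pa_psnr(shift(X), shift(Y)), pa_psnr(X, Y),
               tolerance = 1e-12)
  expect_equal(pa_ssim(shift(X), shift(Y)), pa_ssim(X, Y),
               tolerance = 1e-12)
  # EPI uses reflective borders, so compare on interior-identical shifts
  expect_equal(pa_epi(shift(X), shift(Y)), pa_epi(X, Y), tolerance = 0.02)
})
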