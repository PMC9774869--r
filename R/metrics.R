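#' Rectangular region-of-interest set
#'
#' Signal and background-noise regions for the non-reference metrics
#' ([image_snr()], [image_cnr()]). Rectangles are given in pixel indices
#' (inclusive) as `c(row_min, row_max, col_min, col_max)`. All regions must
#' contain the same number of pixels, lie inside the image, and the signal
#' and noise sets must not overlap.
#'
#' @param signal_regions List of length-4 integer vectors.
#' @param noise_regions List of length-4 integer vectors.
#' @param dim Image dimensions `c(n_rows, n_cols)` used for bounds checks.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(signal_regions, noise_regions, dim) {
  check_rect <- function(r, what) {
    if (length(r) != 4L) stop(what, " rectangle must have 4 entries")
    r <- as.integer(r)
    if (r[1] > r[2] || r[3] > r[4]) stop(what, " rectangle is empty")
    if (r[1] < 1L || r[3] < 1L || r[2] > dim[1] || r[4] > dim[2]) {
      stop(what, " rectangle lies outside the image bounds")
    }
    r
  }
  if (!length(signal_regions) || !length(noise_regions)) {
    stop("need at least one signal and one noise region")
  }
  signal_regions <- lapply(signal_regions, check_rect, what = "signal")
  noise_regions <- lapply(noise_regions, check_rect, what = "noise")
  npix <- function(r) (r[2] - r[1] + 1L) * (r[4] - r[3] + 1L)
  counts <- vapply(c(signal_regions, noise_regions), npix, integer(1))
  if (length(unique(counts)) != 1L) {
    stop("all regions must contain the same number of pixels")
  }
  cells <- function(r) {
    as.vector(outer(r[1]:r[2], (r[3]:r[4] - 1L) * dim[1], "+"))
  }
  sig_cells <- unlist(lapply(signal_regions, cells))
  noi_cells <- unlist(lapply(noise_regions, cells))
  if (length(intersect(sig_cells, noi_cells))) {
    stop("signal and noise regions overlap")
  }
  structure(list(signal_regions = signal_regions,
                 noise_regions = noise_regions, dim = as.integer(dim)),
            class = "roi_set")
}

roi_pixels <- function(img, rect) {
  img[rect[1]:rect[2], rect[3]:rect[4]]
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak / MSE)` between a denoised image X and its noise-free
#' reference Y. The default convention uses the peak amplitude `max(X)` in
#' the numerator, as is common in the photoacoustic denoising literature;
#' `convention = "standard"` uses the conventional squared peak `max(X)^2`.
#' Identical images give `Inf`.
#'
#' @param X Denoised image (matrix).
#' @param Y Reference image, same shape.
#' @param convention `"amplitude"` (peak amplitude numerator, default) or
#'   `"standard"` (squared peak).
#' @return PSNR in dB (`Inf` when X equals Y).
#' @export
pa_psnr <- function(X, Y, convention = c("amplitude", "standard")) {
  convention <- match.arg(convention)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("images must have the same shape")
  mse <- mean((X - Y)^2)
  if (mse == 0) return(Inf)
  peak <- max(X)
  num <- if (convention == "amplitude") peak else peak^2
  10 * log10(num / mse)
}

#' Global structural similarity index
#'
#' Single-window ("simplified") SSIM computed over the whole image:
#' `(2 mux muy + C1)(2 sxy + C2) / ((mux^2 + muy^2 + C1)(sx^2 + sy^2 + C2))`
#' with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `L = 255`. With
#' `rescale = TRUE` (default) both images are mapped to the 8-bit range
#' [0, L] by their joint extrema and rounded to integers, matching uint8
#' input; set `rescale = FALSE` to evaluate the formula on the raw values.
#'
#' @param X,Y Images of identical shape.
#' @param L Dynamic range (default 255).
#' @param rescale Map both images jointly onto `[0, L]` and round, before
#'   evaluating.
#' @return SSIM in [-1, 1]; symmetric in X and Y.
#' @export
pa_ssim <- function(X, Y, L = 255, rescale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("images must have the same shape")
  if (rescale) {
    lo <- min(X, Y); hi <- max(X, Y)
    span <- if (hi > lo) hi - lo else 1
    X <- round((X - lo) / span * L)
    Y <- round((Y - lo) / span * L)
  }
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mux <- mean(X); muy <- mean(Y)
  n <- length(X)
  sx2 <- sum((X - mux)^2) / (n - 1)
  sy2 <- sum((Y - muy)^2) / (n - 1)
  sxy <- sum((X - mux) * (Y - muy)) / (n - 1)
  ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (sx2 + sy2 + C2))
}

# 3x3 Laplacian (center -4, cross neighbors 1) with reflective borders.
laplacian_filter <- function(img) {
  n <- nrow(img); m <- ncol(img)
  if (n < 3L || m < 3L) stop("image must be at least 3 x 3")
  up    <- img[c(1L, seq_len(n - 1L)), , drop = FALSE]
  down  <- img[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  left  <- img[, c(1L, seq_len(m - 1L)), drop = FALSE]
  right <- img[, c(seq_len(m - 1L) + 1L, m), drop = FALSE]
  up + down + left + right - 4 * img
}

#' Edge preservation index
#'
#' Normalized correlation of the mean-subtracted, high-pass Laplacian
#' filtered denoised and reference images, evaluated over the whole image.
#' 1 means edges are perfectly preserved (up to a constant offset, which
#' the Laplacian removes).
#'
#' @param X,Y Images of identical shape, at least 3 x 3.
#' @return EPI in [-1, 1].
#' @export
pa_epi <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("images must have the same shape")
  dX <- laplacian_filter(X); dY <- laplacian_filter(Y)
  a <- dX - mean(dX); b <- dY - mean(dY)
  na <- sum(a * a); nb <- sum(b * b)
  if (na == 0 || nb == 0) {
    stop("Laplacian-filtered image has zero variance; EPI undefined")
  }
  sum(a * b) / sqrt(na * nb)
}

#' Image signal-to-noise ratio from ROIs
#'
#' `10 log10( mean_i mu_i / mean_j sigma_j )`: the mean of the signal-region
#' mean amplitudes over the mean of the noise-region standard deviations,
#' in decibels. Note the factor 10 on an amplitude ratio, which follows the
#' definition used for low-fluence photoacoustic image evaluation.
#'
#' @param img Image matrix.
#' @param rois An [roi_set()].
#' @return SNR in dB.
#' @export
image_snr <- function(img, rois) {
  stopifnot(inherits(rois, "roi_set"))
  img <- as.matrix(img)
  mu_s <- mean(vapply(rois$signal_regions,
                      function(r) mean(roi_pixels(img, r)), numeric(1)))
  sd_n <- mean(vapply(rois$noise_regions,
                      function(r) stats::sd(roi_pixels(img, r)), numeric(1)))
  if (sd_n == 0) stop("noise regions have zero standard deviation")
  if (mu_s <= 0) {
    stop("mean signal amplitude is not positive; SNR is defined on ",
         "amplitude (envelope-detected) images")
  }
  10 * log10(mu_s / sd_n)
}

#' Image contrast-to-noise ratio from ROIs
#'
#' `|mean_i mu_i - mean_j mu_j| / mean_j sigma_j`: absolute difference of
#' the mean signal and mean noise amplitudes over the mean noise standard
#' deviation.
#'
#' @inheritParams image_snr
#' @return Unitless CNR.
#' @export
image_cnr <- function(img, rois) {
  stopifnot(inherits(rois, "roi_set"))
  img <- as.matrix(img)
  mu_s <- mean(vapply(rois$signal_regions,
                      function(r) mean(roi_pixels(img, r)), numeric(1)))
  mu_n <- mean(vapply(rois$noise_regions,
                      function(r) mean(roi_pixels(img, r)), numeric(1)))
  sd_n <- mean(vapply(rois$noise_regions,
                      function(r) stats::sd(roi_pixels(img, r)), numeric(1)))
  if (sd_n == 0) stop("noise regions have zero standard deviation")
  abs(mu_s - mu_n) / sd_n
}

#' Full width at half maximum of an axial profile
#'
#' Measures the width between the two half-maximum crossings bracketing the
#' global peak of a depth profile, used as the axial resolution. The
#' profile is linearly upsampled by a factor of 10 and the crossings are
#' located by linear interpolation on the fine grid.
#'
#' @param profile Numeric amplitude-vs-depth vector with a unique global
#'   maximum away from either boundary.
#' @param spacing Sample spacing in mm.
#' @param upsample Linear upsampling factor (default 10).
#' @return FWHM in mm.
#' @export
axial_fwhm <- function(profile, spacing, upsample = 10L) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 3L) stop("profile too short")
  x <- seq_len(n)
  fine <- seq(1, n, by = 1 / upsample)
  p <- stats::approx(x, profile, xout = fine)$y
  imax <- which.max(p)
  if (imax == 1L || imax == length(p)) {
    stop("global maximum lies on the profile boundary")
  }
  half <- p[imax] / 2
  cross <- function(idx_range, from_peak) {
    below <- which(p[idx_range] <= half)
    if (!length(below)) {
      stop("no half-maximum crossing on one side of the peak")
    }
    i <- if (from_peak == "left") max(below) else min(below)
    idx_range[i]
  }
  li <- cross(seq_len(imax - 1L), "left")
  ri <- cross(seq(imax + 1L, length(p)), "right")
  # refine each crossing by linear interpolation between fine-grid samples
  interp_cross <- function(i0, i1) {
    if (p[i1] == p[i0]) return(fine[i1])
    fine[i0] + (half - p[i0]) / (p[i1] - p[i0]) * (fine[i1] - fine[i0])
  }
  xl <- interp_cross(li, li + 1L)
  xr <- interp_cross(ri, ri - 1L)
  (xr - xl) * spacing
}
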