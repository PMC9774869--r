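#' Reconstructed photoacoustic image
#'
#' @param pixels Numeric matrix (depth rows x lateral columns).
#' @param pixel_spacing `c(dx, dz)` in mm.
#' @param origin `c(x0, z0)` in mm of the first pixel center.
#' @return An object of class `pa_image`.
#' @export
pa_image <- function(pixels, pixel_spacing, origin = c(0, 0)) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  stopifnot(all(pixel_spacing > 0))
  structure(list(pixels = pixels,
                 pixel_spacing = as.numeric(pixel_spacing),
                 origin = as.numeric(origin)),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("PA image: %d x %d px, spacing (%.3g, %.3g) mm\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

#' Image grid specification for reconstruction
#'
#' Default lateral span is the array aperture at the element pitch; default
#' depth window 5-25 mm echoes the display region of a 38.4 mm x ~10-20 mm
#' superficial vascular field of view.
#'
#' @param geom An [array_geometry()].
#' @param z_range_mm Depth range `c(z_min, z_max)` in mm.
#' @param dz_mm Axial pixel size in mm.
#' @param dx_mm Lateral pixel size in mm (default: the element pitch).
#' @return List with pixel center coordinates `x_mm`, `z_mm`.
#' @export
image_grid <- function(geom, z_range_mm = c(5, 25), dz_mm = 0.1,
                       dx_mm = geom$pitch) {
  stopifnot(z_range_mm[1] > 0, z_range_mm[2] > z_range_mm[1])
  x_half <- aperture_mm(geom) / 2
  list(x_mm = seq(-x_half + dx_mm / 2, x_half - dx_mm / 2, by = dx_mm),
       z_mm = seq(z_range_mm[1], z_range_mm[2], by = dz_mm),
       dx_mm = dx_mm, dz_mm = dz_mm)
}

#' Precompute delay-and-sum interpolation tables
#'
#' For a fixed geometry, grid and depth-sample count, precomputes the
#' per-pixel, per-element one-way delays as fractional sample indices plus
#' linear interpolation weights. Reconstructing many frames then reduces
#' to two gathers and a row sum per frame.
#'
#' @param geom An [array_geometry()].
#' @param grid An [image_grid()].
#' @param n_z Depth samples per element in the RF frames to be
#'   reconstructed.
#' @return An opaque list consumed by [das_reconstruct()].
#' @export
das_prepare <- function(geom, grid, n_z) {
  ex <- element_positions_mm(geom)
  if (min(grid$x_mm) < min(ex) - geom$pitch ||
      max(grid$x_mm) > max(ex) + geom$pitch) {
    stop("image grid extends beyond the array's lateral span")
  }
  n_z <- as.integer(n_z)
  fs <- geom$sampling_rate * 1e6
  c_mm <- geom$sound_speed * 1e3
  npx <- length(grid$x_mm) * length(grid$z_mm)
  nel <- geom$n_elements
  # pixel coordinates, depth-major (rows of the image are depths)
  pz <- rep(grid$z_mm, times = length(grid$x_mm))
  px <- rep(grid$x_mm, each = length(grid$z_mm))
  i0 <- matrix(0L, npx, nel)
  w1 <- matrix(0, npx, nel)
  valid <- matrix(FALSE, npx, nel)
  for (e in seq_len(nel)) {
    d <- sqrt((px - ex[e])^2 + pz^2)
    tau <- d / c_mm * fs               # fractional 0-based sample
    lo <- floor(tau)
    ok <- lo >= 0 & lo < (n_z - 1L)
    i0[, e] <- as.integer(ifelse(ok, lo, 0L)) + (e - 1L) * n_z + 1L
    w1[, e] <- ifelse(ok, tau - lo, 0)
    valid[, e] <- ok
  }
  list(i0 = i0, w1 = w1, valid = valid, n_z = n_z,
       n_rows = length(grid$z_mm), n_cols = length(grid$x_mm),
       grid = grid, geom = geom)
}

#' Delay-and-sum reconstruction of one RF frame
#'
#' Each pixel sums, over all elements, the RF sample at the element's
#' one-way time-of-flight delay (linear interpolation between samples); no
#' apodization. The same beamformer is applied to every denoising method
#' under comparison, so image-domain metrics are internally consistent.
#'
#' @param frame `n_x x n_z` RF frame matrix.
#' @param geom An [array_geometry()]; ignored when `prep` is given.
#' @param grid An [image_grid()]; ignored when `prep` is given.
#' @param prep Optional precomputed tables from [das_prepare()].
#' @return A [pa_image()] (depth rows x lateral columns).
#' @export
das_reconstruct <- function(frame, geom = NULL, grid = NULL, prep = NULL) {
  frame <- as.matrix(frame)
  if (is.null(prep)) {
    stopifnot(!is.null(geom), !is.null(grid))
    prep <- das_prepare(geom, grid, ncol(frame))
  }
  if (ncol(frame) != prep$n_z) {
    stop("frame has ", ncol(frame), " depth samples, expected ", prep$n_z)
  }
  rf <- as.vector(t(frame))   # element-major: sample s of element e at (e-1)*n_z + s
  vals <- (rf[prep$i0] * (1 - prep$w1) + rf[prep$i0 + 1L] * prep$w1) *
    prep$valid
  img <- matrix(rowSums(vals), prep$n_rows, prep$n_cols)
  pa_image(img, c(prep$grid$dx_mm, prep$grid$dz_mm),
           origin = c(prep$grid$x_mm[1], prep$grid$z_mm[1]))
}

#' Analytic-signal envelope along depth
#'
#' Magnitude of the analytic signal of each depth line (column of a
#' depth-by-lateral image, or each row of an `n_x x n_z` RF frame when
#' `along = "row"`). Nonnegative; preserves peak locations of narrowband
#' pulses to within one sample.
#'
#' @param x Matrix (or vector) of RF or beamformed samples.
#' @param along `"col"` if depth runs down the columns (images), `"row"`
#'   for RF frames stored elements x depth.
#' @return Envelope of the same shape.
#' @export
envelope <- function(x, along = c("col", "row")) {
  along <- match.arg(along)
  vec_in <- is.null(dim(x))
  m <- if (vec_in) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  if (along == "row") m <- t(m)
  n <- nrow(m)
  if (n < 8L) stop("need at least 8 samples along depth")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  analytic <- stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / n
  env <- Mod(analytic)
  if (along == "row") env <- t(env)
  if (vec_in) as.vector(env) else env
}

#' Reconstruct and envelope-detect every frame of a stack
#'
#' @param stack An [rf_stack()].
#' @param prep Precomputed [das_prepare()] tables matching the stack.
#' @param frames Which frames to reconstruct (default all).
#' @param envelope_detect Apply [envelope()] to each image (default TRUE).
#' @return 3-D array `(n_rows, n_cols, length(frames))` of image pixels.
#' @export
reconstruct_stack <- function(stack, prep, frames = NULL,
                              envelope_detect = TRUE) {
  stopifnot(is_rf_stack(stack))
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  out <- array(0, c(prep$n_rows, prep$n_cols, length(frames)))
  for (i in seq_along(frames)) {
    img <- das_reconstruct(stack$samples[, , frames[i]], prep = prep)$pixels
    if (envelope_detect) img <- envelope(img, along = "col")
    out[, , i] <- img
  }
  out
}
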