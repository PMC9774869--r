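#' Denoising configuration
#'
#' @param rank Either an explicit number of singular value components to
#'   retain, or one of `"auto-temporal"`, `"auto-spatial"`, `"auto-min"`
#'   (the conservative default combination rule, `min` of the two
#'   estimators).
#' @param window_frames Sliding-window length in frames.
#' @param stride Window step in frames (>= 1).
#' @param oversample,power_iterations Randomized sketch parameters (see
#'   [randomized_range_finder()]).
#' @param seed Master seed; per-window seeds are derived as
#'   `seed + window index` so results are reproducible and stable under
#'   stride changes.
#' @param orders Singular-vector orders analyzed by the automatic rank
#'   estimators (default `min(window_frames, 75)`).
#' @param backend `"gram"` (exact thin SVD through the n_t x n_t Gram
#'   matrix, the default for the short windows used here) or `"rsvd"`
#'   (randomized sketch).
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(rank = "auto-min", window_frames = 75L,
                           stride = 1L, oversample = 8L,
                           power_iterations = 2L, seed = 1L,
                           orders = NULL, backend = c("gram", "rsvd")) {
  backend <- match.arg(backend)
  if (is.numeric(rank)) {
    rank <- as.integer(rank)
    if (rank < 1L) stop("explicit rank must be >= 1")
  } else {
    rank <- match.arg(rank, c("auto-min", "auto-temporal", "auto-spatial"))
  }
  stopifnot(window_frames >= 1L, stride >= 1L, stride <= window_frames)
  structure(list(rank = rank, window_frames = as.integer(window_frames),
                 stride = as.integer(stride),
                 oversample = as.integer(oversample),
                 power_iterations = as.integer(power_iterations),
                 seed = as.integer(seed), orders = orders,
                 backend = backend),
            class = "denoise_config")
}

resolve_window_rank <- function(cfg, factors, orders) {
  if (is.numeric(cfg$rank)) return(list(k = cfg$rank, est = NULL))
  est <- estimate_rank(orders = orders, factors = factors)
  k <- switch(cfg$rank,
              "auto-temporal" = est$k_temporal,
              "auto-spatial" = est$k_spatial,
              "auto-min" = est$k)
  list(k = k, est = est)
}

#' Spatiotemporal SVD denoising with a sliding window
#'
#' The core pipeline: for each window position, the window's Casorati
#' matrix is formed, the tissue-subspace rank is resolved (explicit, or
#' automatically from the singular-vector estimators), and the matrix is
#' truncated to exactly the k leading singular value components. Each
#' window emits its newest frame (causal, real-time-compatible); frames
#' before the first full window are taken from the first window's
#' truncation. With a stride > 1, frames between window positions reuse
#' the most recent window's subspace.
#'
#' @param stack A noisy [rf_stack()].
#' @param cfg A [denoise_config()]; `window_frames` must not exceed the
#'   stack length, and automatic rank selection needs a window of at least
#'   8 frames.
#' @return List with `stack` (the denoised [rf_stack()]) and `ranks`
#'   (integer vector, the rank used for each emitted window position).
#' @export
stsvd_denoise <- function(stack, cfg = denoise_config()) {
  stopifnot(is_rf_stack(stack), inherits(cfg, "denoise_config"))
  n_t <- n_frames(stack)
  w <- cfg$window_frames
  if (w > n_t) stop("window (", w, " frames) exceeds the stack (", n_t, ")")
  if (!is.numeric(cfg$rank) && w < 8L) {
    stop("automatic rank selection needs a window of at least 8 frames")
  }
  orders <- if (is.null(cfg$orders)) min(w, 75L) else
    min(as.integer(cfg$orders), w)
  S_full <- to_casorati(stack)
  out <- matrix(0, nrow(S_full$values), n_t)
  positions <- seq(w, n_t, by = cfg$stride)
  if (positions[length(positions)] != n_t) positions <- c(positions, n_t)
  ranks <- integer(length(positions))
  need <- if (is.numeric(cfg$rank)) max(cfg$rank, 1L) else orders
  for (p in seq_along(positions)) {
    tpos <- positions[p]
    cols <- (tpos - w + 1L):tpos
    Sw <- S_full$values[, cols, drop = FALSE]
    factors <- if (cfg$backend == "gram") {
      gram_factors(Sw, need)
    } else {
      truncated_factors(Sw, need, cfg$oversample, cfg$power_iterations,
                        seed = cfg$seed + p)
    }
    k <- min(resolve_window_rank(cfg, factors, orders)$k, length(factors$d))
    ranks[p] <- k
    Vk <- factors$v[, seq_len(k), drop = FALSE]
    proj <- function(local_t) Sw %*% (Vk %*% Vk[local_t, ])
    if (p == 1L) {
      # frames up to the first window position use the first window
      for (t in seq_len(tpos)) out[, t] <- proj(t)
    } else {
      prev <- positions[p - 1L]
      for (t in (prev + 1L):tpos) out[, t] <- proj(t - tpos + w)
    }
  }
  denoised <- from_casorati(casorati_matrix(out, S_full$n_x, S_full$n_z),
                            stack)
  denoised$provenance <- paste0(stack$provenance, " | stsvd")
  list(stack = denoised, ranks = ranks)
}

#' Running-mean frame averaging
#'
#' Frame t of the output is the mean of input frames
#' `max(1, t - batch + 1) .. t` (trailing window), the standard
#' averaging baseline for high-repetition-rate acquisitions.
#'
#' @param stack An [rf_stack()].
#' @param batch Number of trailing frames to average (>= 1).
#' @return An [rf_stack()] of identical shape.
#' @export
frame_average <- function(stack, batch = 75L) {
  stopifnot(is_rf_stack(stack), batch >= 1L)
  batch <- as.integer(batch)
  S <- to_casorati(stack)
  n_t <- ncol(S$values)
  cs <- matrix(0, nrow(S$values), n_t + 1L)
  for (t in seq_len(n_t)) cs[, t + 1L] <- cs[, t] + S$values[, t]
  out <- matrix(0, nrow(S$values), n_t)
  for (t in seq_len(n_t)) {
    lo <- max(0L, t - batch)
    out[, t] <- (cs[, t + 1L] - cs[, lo + 1L]) / (t - lo)
  }
  avg <- from_casorati(casorati_matrix(out, S$n_x, S$n_z), stack)
  avg$provenance <- paste0(stack$provenance, " | average")
  avg
}

## ---- db4 discrete wavelet transform (periodized) -----------------------

# Daubechies-4 (8-tap) decomposition low-pass filter.
db4_dec_lo <- c(-0.010597401784997278, 0.032883011666982945,
                0.030841381835986965, -0.187034811718881140,
                -0.027983769416983850, 0.630880767929590400,
                0.714846570552541500, 0.230377813308855230)

db4_filters <- function() {
  lo <- db4_dec_lo
  rec_lo <- rev(lo)
  k <- seq_along(lo) - 1L
  dec_hi <- (-1)^(k + 1L) * rec_lo   # quadrature mirror of rec_lo
  list(dec_lo = lo, dec_hi = dec_hi, rec_lo = rec_lo,
       rec_hi = rev(dec_hi))
}

# One periodized analysis step: returns approximation and detail halves.
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  xp <- c(x, x[seq_len(L - 1L)])           # periodic extension
  conv_lo <- stats::filter(xp, lo, sides = 1)
  conv_hi <- stats::filter(xp, hi, sides = 1)
  take <- seq(L, n + L - 1L, by = 2L)
  list(a = as.numeric(conv_lo[take]), d = as.numeric(conv_hi[take]))
}

idwt_step <- function(a, d, lo, hi) {
  L <- length(lo)
  n2 <- 2L * length(a)
  up <- function(c) { u <- numeric(n2); u[seq(1L, n2, by = 2L)] <- c; u }
  ua <- up(a); ud <- up(d)
  ext <- function(u) c(u[(n2 - (L - 2L)):n2], u)   # periodic head extension
  ra <- stats::filter(ext(ua), rev(lo), sides = 1)
  rd <- stats::filter(ext(ud), rev(hi), sides = 1)
  take <- seq(L, n2 + L - 1L)
  out <- as.numeric(ra[take]) + as.numeric(rd[take])
  out[seq_len(n2)]
}

#' Multilevel periodized db4 DWT of a vector
#'
#' @param x Numeric vector; length must be divisible by `2^level`.
#' @param level Decomposition depth.
#' @return List with `approx` (coarsest approximation) and `details`
#'   (list of detail coefficient vectors, finest level first).
#' @keywords internal
dwt_db4 <- function(x, level) {
  f <- db4_filters()
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    if (length(a) %% 2L != 0L) stop("signal length not divisible by 2^level")
    st <- dwt_step(a, f$dec_lo, f$dec_hi)
    details[[j]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details)
}

#' @keywords internal
idwt_db4 <- function(decomp) {
  f <- db4_filters()
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[j]], f$dec_lo, f$dec_hi)
  }
  a
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' Wavelet denoising of a single RF frame
#'
#' The single-frame baseline: each A-line (one element's depth series) is
#' decomposed with a multilevel Daubechies-4 wavelet transform
#' (periodized), the noise level is estimated from the finest detail
#' coefficients as `MAD / 0.6745`, and all detail coefficients are soft
#' thresholded at the universal threshold `sigma * sqrt(2 log n_z)`;
#' approximation coefficients are left untouched.
#'
#' @param frame `n_x x n_z` RF frame matrix with `n_z >= 16`.
#' @param level Decomposition depth (capped by the dyadic divisibility of
#'   `n_z`; default `min(4, ...)`).
#' @param mode `"per-line"` (1-D along depth, default) or `"2d"`
#'   (separable 2-D transform of the whole frame).
#' @return Denoised frame of the same shape.
#' @export
dwt_denoise <- function(frame, level = 4L, mode = c("per-line", "2d")) {
  mode <- match.arg(mode)
  frame <- as.matrix(frame)
  n_z <- ncol(frame)
  if (n_z < 16L) stop("need at least 16 depth samples, got ", n_z)
  max_level <- 0L
  n <- n_z
  while (n %% 2L == 0L) { max_level <- max_level + 1L; n <- n %/% 2L }
  level <- min(as.integer(level), max_level)
  if (level < 1L) stop("depth-sample count must be even for the DWT")
  denoise_line <- function(x) {
    dec <- dwt_db4(x, level)
    sigma <- stats::mad(dec$details[[1]], constant = 1) / 0.6745
    lambda <- sigma * sqrt(2 * log(length(x)))
    dec$details <- lapply(dec$details, soft_threshold, lambda = lambda)
    idwt_db4(dec)
  }
  if (mode == "per-line") {
    t(apply(frame, 1L, denoise_line))
  } else {
    tmp <- t(apply(frame, 1L, denoise_line))
    n_x <- nrow(frame)
    if (n_x >= 16L) apply(tmp, 2L, denoise_line) else tmp
  }
}

#' Wavelet-denoise every frame of a stack
#'
#' @param stack An [rf_stack()].
#' @param ... Passed to [dwt_denoise()].
#' @return An [rf_stack()] of identical shape.
#' @export
dwt_denoise_stack <- function(stack, ...) {
  stopifnot(is_rf_stack(stack))
  out <- stack$samples
  for (t in seq_len(n_frames(stack))) {
    out[, , t] <- dwt_denoise(stack$samples[, , t], ...)
  }
  res <- rf_stack(out, stack$geometry, stack$frame_interval,
                  paste0(stack$provenance, " | dwt"))
  res
}
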