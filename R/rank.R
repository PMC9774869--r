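#' Double-sided power spectral density of temporal singular vectors
#'
#' For each column of V, computes the squared magnitude of its discrete
#' Fourier transform, frequency-shifted so that DC sits at the center bin.
#' The PSD is scaled so each row sums to the column's energy (Parseval).
#' Tissue components produce narrowband (low-frequency) rows; noise
#' components are broadband.
#'
#' @param V Matrix of temporal singular vectors, one per column, each of
#'   length `n_t >= 8`.
#' @return Matrix with one row per singular-vector order and `n_t` columns
#'   (frequency bins, DC centered).
#' @export
temporal_psd <- function(V) {
  V <- as.matrix(V)
  n_t <- nrow(V)
  if (n_t < 8L) stop("temporal vectors must have length >= 8, got ", n_t)
  spec <- Mod(stats::mvfft(V))^2 / n_t      # rows sum to column energy
  shift <- c(seq(floor(n_t / 2) + 1L, n_t), seq_len(floor(n_t / 2)))
  t(spec[shift, , drop = FALSE])
}

# Index of the DC bin in a DC-centered spectrum of length n.
dc_bin <- function(n) floor(n / 2) + 1L

#' 99%-energy bandwidth of one PSD row
#'
#' Splits a DC-centered PSD into a negative- and a positive-frequency side
#' (each side receives half of the DC bin, and for even lengths half of the
#' Nyquist bin) and finds, per side, the smallest band growing symmetrically
#' from DC that contains at least `fraction` of that side's energy. The
#' result is the band size as a fraction of the side's full band; the two
#' sides are combined by `reducer` (mean by default).
#'
#' @param psd_row Nonnegative numeric vector (one DC-centered PSD).
#' @param fraction Energy fraction defining the band (default 0.99).
#' @param reducer How to combine the two sides: "mean" or "max".
#' @return One-sided bandwidth fraction in (0, 1].
#' @export
bandwidth99 <- function(psd_row, fraction = 0.99,
                        reducer = c("mean", "max")) {
  reducer <- match.arg(reducer)
  psd_row <- as.numeric(psd_row)
  if (any(psd_row < 0)) stop("PSD must be nonnegative")
  total <- sum(psd_row)
  if (total <= 0) stop("zero-energy PSD: bandwidth undefined")
  n <- length(psd_row)
  dc <- dc_bin(n)
  even <- n %% 2L == 0L
  # side energy ladders, from DC outward; DC (and Nyquist, even n) split in half
  n_pos <- if (even) n %/% 2L - 1L else (n - 1L) %/% 2L
  pos <- c(psd_row[dc] / 2,
           if (n_pos > 0L) psd_row[(dc + 1L):(dc + n_pos)],
           if (even) psd_row[1L] / 2)
  neg <- c(psd_row[dc] / 2,
           if (n_pos > 0L) rev(psd_row[(dc - n_pos):(dc - 1L)]),
           if (even) psd_row[1L] / 2)
  side_bw <- function(e) {
    cum <- cumsum(e)
    if (cum[length(e)] <= 0) return(1)
    b <- which(cum >= fraction * cum[length(e)])[1]
    b / length(e)
  }
  vals <- c(side_bw(neg), side_bw(pos))
  if (reducer == "mean") mean(vals) else max(vals)
}

#' Temporal rank estimator (99%-bandwidth expansion)
#'
#' Computes the per-order 99% bandwidth of the temporal singular vectors
#' and returns the last order before the curve expands towards the full
#' frequency band. The expansion point is detected as the first order whose
#' bandwidth fraction exceeds `expansion_threshold`; the estimate is that
#' order minus one, clamped to at least 1. If no order exceeds the
#' threshold, all analyzed orders are attributed to the tissue subspace.
#'
#' The default threshold of 0.8 reflects that broadband noise vectors sit
#' at a 99% bandwidth of essentially the full band (>= 0.95), whereas
#' tissue vectors — even ones with sharp temporal edges from stepwise
#' motion, whose spectra have slowly decaying 1/f^2 tails — stay below
#' about 0.7 of the band. The threshold therefore sits inside the gap
#' between the two regimes rather than below it.
#'
#' @param V Matrix of temporal singular vectors (columns ordered by
#'   singular value). At least 4 columns are required.
#' @param fraction Energy fraction for the bandwidth (default 0.99).
#' @param expansion_threshold Bandwidth fraction regarded as "expanded to
#'   the entire band" (default 0.8).
#' @param reducer Side reducer passed to [bandwidth99()].
#' @return List with `k` (the estimate) and `bandwidth` (the diagnostic
#'   per-order curve).
#' @export
estimate_rank_temporal <- function(V, fraction = 0.99,
                                   expansion_threshold = 0.8,
                                   reducer = "mean") {
  V <- as.matrix(V)
  if (ncol(V) < 4L) stop("need at least 4 singular-vector orders, got ",
                         ncol(V))
  psd <- temporal_psd(V)
  bw <- apply(psd, 1L, bandwidth99, fraction = fraction, reducer = reducer)
  over <- which(bw > expansion_threshold)
  k <- if (length(over)) max(1L, over[1] - 1L) else length(bw)
  list(k = as.integer(k), bandwidth = bw)
}

#' Spatial similarity matrix of singular-vector magnitudes
#'
#' Pearson correlation between the elementwise magnitude images |u_n| and
#' |u_m| of the leading spatial singular vectors, computed over all
#' n_x * n_z 'pixels'. Within the tissue subspace the magnitudes share the
#' vascular structure and correlate strongly; noise vectors are spatially
#' random and correlate weakly.
#'
#' @param U Matrix of spatial singular vectors (columns ordered by singular
#'   value).
#' @param orders Number of leading orders to analyze (default: all columns).
#' @return Symmetric `orders x orders` correlation matrix with unit
#'   diagonal.
#' @export
spatial_similarity_matrix <- function(U, orders = ncol(U)) {
  U <- as.matrix(U)
  orders <- as.integer(orders)
  if (orders > ncol(U)) stop("orders (", orders, ") exceeds available ",
                             "columns (", ncol(U), ")")
  A <- abs(U[, seq_len(orders), drop = FALSE])
  sds <- apply(A, 2L, stats::sd)
  bad <- which(sds == 0)
  if (length(bad)) {
    stop("spatial vector magnitude has zero variance at order ", bad[1])
  }
  C <- stats::cor(A)
  (C + t(C)) / 2
}

#' Spatial rank estimator (leading correlation block)
#'
#' Finds the largest leading block of the spatial similarity matrix that is
#' coherently correlated: the largest k such that every order j <= k has
#' mean off-diagonal correlation (within the block) of at least
#' `threshold`. Returns 1 when no block of size >= 2 qualifies.
#'
#' By default the threshold adapts to the matrix at hand: the noise-floor
#' correlation level is measured as a high quantile of the absolute
#' off-diagonal entries among the trailing half of the analyzed orders
#' (which, by construction, are dominated by noise), and the boundary
#' threshold is `noise_multiplier` times that floor (with a small absolute
#' floor). This keys the detector to the tissue-vs-noise correlation
#' *gap* rather than to an absolute correlation level, which varies with
#' the noise leakage into the spatial vectors.
#'
#' @param C Similarity matrix from [spatial_similarity_matrix()].
#' @param threshold Fixed minimum mean within-block correlation; `NULL`
#'   (default) for the adaptive rule.
#' @param noise_multiplier Multiplier on the measured noise-floor
#'   correlation (default 3).
#' @param floor Lower clamp on the adaptive threshold (default 0.005).
#' @return Integer rank estimate.
#' @export
estimate_rank_spatial <- function(C, threshold = NULL,
                                  noise_multiplier = 3, floor = 0.005) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (is.null(threshold)) {
    tail_idx <- seq(max(2L, n %/% 2L + 1L), n)
    tail_block <- abs(C[tail_idx, tail_idx, drop = FALSE])
    off <- tail_block[upper.tri(tail_block)]
    noise_level <- if (length(off)) stats::quantile(off, 0.9, names = FALSE)
                   else 0
    threshold <- min(max(noise_multiplier * noise_level, floor), 0.5)
  }
  best <- 1L
  for (k in seq_len(n)[-1]) {
    block <- C[seq_len(k), seq_len(k), drop = FALSE]
    mean_off <- (colSums(block) - diag(block)) / (k - 1)
    if (all(mean_off >= threshold)) best <- k
  }
  best
}

#' Estimate the tissue-subspace rank of an RF sequence
#'
#' Runs both singular-vector rank estimators on the leading singular
#' components of a Casorati matrix and returns the estimates plus their
#' diagnostic curves. The combined default follows a conservative rule:
#' `min(k_temporal, k_spatial)`.
#'
#' @param S A `casorati_matrix`, or an [rf_stack()] (converted internally).
#'   May be `NULL` when `factors` is supplied.
#' @param orders Number of leading singular-vector orders to analyze
#'   (default `min(n_t, 75)`).
#' @param factors Optionally, precomputed [svd_factors()] with at least
#'   `orders` components; if `NULL` they are computed exactly through the
#'   Gram matrix.
#' @param fraction,expansion_threshold,reducer Passed to the temporal
#'   estimator.
#' @param threshold Passed to the spatial estimator.
#' @return An object of class `rank_estimate`: list with `k` (combined),
#'   `k_temporal`, `k_spatial`, `bandwidth` curve, `similarity` matrix,
#'   `orders`.
#' @export
estimate_rank <- function(S = NULL, orders = NULL, factors = NULL,
                          fraction = 0.99, expansion_threshold = 0.8,
                          reducer = "mean", threshold = NULL) {
  if (is.null(factors)) {
    if (is.null(S)) stop("supply either S or precomputed factors")
    if (is_rf_stack(S)) S <- to_casorati(S)
    values <- casorati_values(S)
    n_t <- ncol(values)
  } else {
    n_t <- nrow(factors$v)
  }
  if (is.null(orders)) orders <- min(n_t, 75L)
  orders <- as.integer(orders)
  if (orders < 4L) stop("need at least 4 orders to estimate a rank")
  if (is.null(factors)) factors <- gram_factors(values, orders)
  if (length(factors$d) < orders) {
    stop("factors carry ", length(factors$d), " components, need ", orders)
  }
  tmp <- estimate_rank_temporal(factors$v[, seq_len(orders), drop = FALSE],
                                fraction, expansion_threshold, reducer)
  C <- spatial_similarity_matrix(factors$u, orders)
  ks <- estimate_rank_spatial(C, threshold)
  structure(list(k = min(tmp$k, ks),
                 k_temporal = tmp$k,
                 k_spatial = ks,
                 bandwidth = tmp$bandwidth,
                 similarity = C,
                 orders = orders),
            class = "rank_estimate")
}

#' @export
print.rank_estimate <- function(x, ...) {
  cat(sprintf(paste0("Tissue-subspace rank estimate: %d ",
                     "(temporal %d, spatial %d; %d orders analyzed)\n"),
              x$k, x$k_temporal, x$k_spatial, x$orders))
  invisible(x)
}

#' Write rank-selection diagnostic plots
#'
#' Produces the two standard diagnostics as PNG files: the per-order PSD
#' heatmap with the 99%-bandwidth curve overlaid, and the spatial
#' similarity matrix heatmap.
#'
#' @param est A `rank_estimate` from [estimate_rank()].
#' @param V Temporal singular vectors used for the estimate (for the PSD
#'   panel).
#' @param path_psd,path_similarity Output PNG paths.
#' @return Invisibly, `est`.
#' @export
plot_rank_diagnostics <- function(est, V, path_psd, path_similarity) {
  stopifnot(inherits(est, "rank_estimate"))
  psd <- temporal_psd(as.matrix(V)[, seq_len(est$orders), drop = FALSE])
  grDevices::png(path_psd, width = 900, height = 500)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(x = seq_len(nrow(psd)), y = seq_len(ncol(psd)),
                  z = log10(psd + max(psd) * 1e-8),
                  xlab = "singular vector order",
                  ylab = "frequency bin (DC centered)",
                  main = "Temporal PSD and 99% bandwidth",
                  col = grDevices::hcl.colors(64, "inferno"))
  n <- ncol(psd)
  graphics::lines(seq_along(est$bandwidth),
                  dc_bin(n) + est$bandwidth * (n - dc_bin(n)),
                  col = "white", lwd = 2)
  graphics::abline(v = est$k_temporal + 0.5, col = "cyan", lty = 2)
  grDevices::dev.off()
  grDevices::png(path_similarity, width = 550, height = 500)
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(x = seq_len(est$orders), y = seq_len(est$orders),
                  z = est$similarity, zlim = c(-1, 1),
                  xlab = "order", ylab = "order",
                  main = "Spatial similarity matrix",
                  col = grDevices::hcl.colors(64, "viridis"))
  graphics::rect(0.5, 0.5, est$k_spatial + 0.5, est$k_spatial + 0.5,
                 border = "red", lwd = 2, lty = 2)
  invisible(est)
}
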