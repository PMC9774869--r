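#' Full singular value decomposition of a Casorati matrix
#'
#' Decomposes `S = U diag(sigma) V'` where the columns of U are spatial
#' singular vectors (flattened-frame space) and the columns of V are
#' temporal singular vectors. RF data are real, so the conjugate transpose
#' reduces to the transpose. Singular vectors carry a fixed sign convention
#' (the largest-magnitude entry of each spatial vector is positive) so
#' repeated decompositions are reproducible.
#'
#' @param S A `casorati_matrix` (or plain numeric matrix).
#' @return An object of class `svd_factors`: list with `u` (spatial
#'   vectors), `d` (singular values, descending), `v` (temporal vectors).
#' @export
full_svd <- function(S) {
  values <- casorati_values(S)
  if (!all(is.finite(values))) stop("input contains non-finite values")
  sv <- svd(values)
  svd_factors(sv$u, sv$d, sv$v)
}

casorati_values <- function(S) {
  if (inherits(S, "casorati_matrix")) S$values else as.matrix(S)
}

#' Construct (and sign-normalize) an SVD factor object
#'
#' @param u Matrix of spatial singular vectors (orthonormal columns).
#' @param d Singular values, nonnegative and descending.
#' @param v Matrix of temporal singular vectors (orthonormal columns).
#' @return An `svd_factors` object.
#' @export
svd_factors <- function(u, d, v) {
  u <- as.matrix(u); v <- as.matrix(v); d <- as.numeric(d)
  stopifnot(ncol(u) == length(d), ncol(v) == length(d))
  if (length(d) && is.unsorted(rev(d))) stop("singular values must descend")
  for (k in seq_along(d)) {
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  structure(list(u = u, d = d, v = v), class = "svd_factors")
}

#' @export
print.svd_factors <- function(x, ...) {
  cat(sprintf("SVD factors: %d components, spatial dim %d, temporal dim %d\n",
              length(x$d), nrow(x$u), nrow(x$v)))
  cat("  leading singular values:",
      paste(signif(utils::head(x$d, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Filter a Casorati matrix by singular components
#'
#' Reconstructs `sum_{k in keep} sigma_k u_k v_k'`, i.e. applies the
#' diagonal filtering matrix that zeroes the discarded singular value
#' components. With `keep = first k`, this is the best rank-k approximation
#' (Eckart-Young).
#'
#' @param factors An [svd_factors()] of `S`.
#' @param keep Logical vector over components, or a single integer k
#'   meaning keep components `1..k`. An all-`FALSE` mask yields the zero
#'   matrix.
#' @param S The Casorati matrix the factors came from (used only for shape
#'   bookkeeping of the returned object).
#' @return A `casorati_matrix` of the same shape as `S`.
#' @export
svd_filter <- function(factors, keep, S) {
  stopifnot(inherits(factors, "svd_factors"))
  r <- length(factors$d)
  if (is.numeric(keep) && length(keep) == 1L) {
    k <- as.integer(keep)
    if (k < 0L || k > r) stop("rank k must be between 0 and ", r)
    keep <- seq_len(r) <= k
  }
  if (!is.logical(keep) || length(keep) != r) {
    stop("keep mask length (", length(keep),
         ") does not match component count (", r, ")")
  }
  shape <- casorati_shape(S)
  if (!any(keep)) {
    out <- matrix(0, nrow(factors$u), nrow(factors$v))
  } else {
    idx <- which(keep)
    out <- factors$u[, idx, drop = FALSE] %*%
      (factors$d[idx] * t(factors$v[, idx, drop = FALSE]))
  }
  casorati_matrix(out, shape$n_x, shape$n_z)
}

casorati_shape <- function(S) {
  if (inherits(S, "casorati_matrix")) {
    list(n_x = S$n_x, n_z = S$n_z)
  } else {
    list(n_x = 1L, n_z = nrow(as.matrix(S)))
  }
}

#' Randomized range finder with power iteration
#'
#' Sketches the range of `S` by multiplying with a Gaussian random matrix
#' (entries i.i.d. N(0, 1)), orthonormalizing with a pivoted QR
#' decomposition, and sharpening the subspace with `power_iterations`
#' rounds of `S (S' Q)`. Each half-step is re-orthonormalized by QR to
#' prevent floating-point collapse of the basis onto the dominant singular
#' direction.
#'
#' @param S Casorati matrix or plain matrix.
#' @param k Target rank (1 <= k, k + oversample <= n_t).
#' @param oversample Extra sketch columns beyond `k` (default 8).
#' @param power_iterations Number of power-iteration rounds (default 2).
#' @param seed Integer seed making the Gaussian draw reproducible.
#' @return Matrix Q with `k + oversample` orthonormal columns.
#' @references Halko, Martinsson & Tropp (2011), SIAM Review 53(2), 217-288.
#' @export
randomized_range_finder <- function(S, k, oversample = 8L,
                                    power_iterations = 2L, seed = 1L) {
  values <- casorati_values(S)
  n_t <- ncol(values)
  k <- as.integer(k)
  l <- k + as.integer(oversample)
  if (k < 1L) stop("rank k must be >= 1")
  if (l > n_t) {
    stop("k + oversample (", l, ") exceeds the number of frames (", n_t, ")")
  }
  R <- with_seed(seed, matrix(stats::rnorm(n_t * l), n_t, l))
  Q <- qr.Q(qr(values %*% R, LAPACK = TRUE))
  q <- as.integer(power_iterations)
  for (i in seq_len(q)) {
    Z <- qr.Q(qr(crossprod(values, Q), LAPACK = TRUE))
    Q <- qr.Q(qr(values %*% Z, LAPACK = TRUE))
  }
  Q
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Randomized low-rank denoising of a Casorati matrix
#'
#' Projects `S` onto the sketched range: `P = Q Q' S` with Q from
#' [randomized_range_finder()]. For spectra with a gap after the k-th
#' singular value this matches the exact rank-k truncation closely while
#' costing only O(n_x n_z n_t (k + oversample)).
#'
#' @inheritParams randomized_range_finder
#' @return A `casorati_matrix` with `rank(P) <= k + oversample`.
#' @export
rsvd_denoise <- function(S, k, oversample = 8L, power_iterations = 2L,
                         seed = 1L) {
  values <- casorati_values(S)
  Q <- randomized_range_finder(values, k, oversample, power_iterations, seed)
  shape <- casorati_shape(S)
  casorati_matrix(Q %*% crossprod(Q, values), shape$n_x, shape$n_z)
}

#' Top-k singular factors via the randomized sketch
#'
#' Computes the SVD of the small projected matrix `Q' S` and lifts the left
#' factors by Q, giving the leading k singular components without a full
#' decomposition. For gapped spectra the result matches [full_svd()]'s
#' top-k factors to high accuracy.
#'
#' @inheritParams randomized_range_finder
#' @return An [svd_factors()] with exactly `k` components.
#' @export
truncated_factors <- function(S, k, oversample = 8L, power_iterations = 2L,
                              seed = 1L) {
  values <- casorati_values(S)
  n_t <- ncol(values)
  l <- min(as.integer(k) + as.integer(oversample), n_t)
  Q <- randomized_range_finder(values, k, l - as.integer(k),
                               power_iterations, seed)
  B <- crossprod(Q, values)          # l x n_t
  sv <- svd(B, nu = k, nv = k)
  svd_factors(Q %*% sv$u, sv$d[seq_len(k)], sv$v)
}

# Exact thin factors through the n_t x n_t Gram matrix: cheap when the
# number of frames is small (<= a few hundred), which is the regime of the
# sliding-window pipeline. Returns the leading `k` components.
gram_factors <- function(values, k = ncol(values)) {
  n_t <- ncol(values)
  k <- min(as.integer(k), n_t)
  eg <- eigen(crossprod(values), symmetric = TRUE)
  d2 <- pmax(eg$values, 0)
  d <- sqrt(d2)
  pos <- d > max(d[1], .Machine$double.eps) * 1e-12
  keep <- seq_len(k)
  v <- eg$vectors[, keep, drop = FALSE]
  # U = S V / sigma; columns with (numerically) zero sigma are left zero
  u <- values %*% v
  for (j in seq_len(k)) {
    if (pos[j]) u[, j] <- u[, j] / d[j] else u[, j] <- 0
  }
  svd_factors(u, d[keep], v)
}
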