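#' RF frame stack
#'
#' The central data container: a 3-D array of radiofrequency samples indexed
#' (element x, depth-sample z, frame t) together with the acquisition
#' geometry and the inter-frame interval. All computation is done in double
#' precision; the on-disk container stores samples in single precision.
#'
#' @param samples 3-D numeric array with dimensions
#'   `(n_x, n_z, n_t)`; `n_x` must equal `geometry$n_elements` and every
#'   value must be finite.
#' @param geometry An [array_geometry()].
#' @param frame_interval Time between consecutive frames in seconds (> 0).
#' @param provenance Free-text label recording where the data came from.
#'
#' @return An object of class `rf_stack` with fields `samples`, `geometry`,
#'   `frame_interval`, `provenance`.
#' @examples
#' geom <- array_geometry(n_elements = 4)
#' s <- rf_stack(array(0, c(4, 16, 2)), geom)
#' dim(s$samples)
#' @export
rf_stack <- function(samples, geometry, frame_interval = 1e-3,
                     provenance = "unspecified") {
  stopifnot(inherits(geometry, "array_geometry"))
  if (!is.array(samples) || length(dim(samples)) != 3L) {
    stop("samples must be a 3-D array (n_x, n_z, n_t)")
  }
  storage.mode(samples) <- "double"
  d <- dim(samples)
  if (d[1] != geometry$n_elements) {
    stop("first dimension of samples (", d[1], ") must equal ",
         "geometry$n_elements (", geometry$n_elements, ")")
  }
  if (d[3] < 1L) stop("stack must contain at least one frame")
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  stopifnot(is.numeric(frame_interval), frame_interval > 0)
  structure(
    list(samples = samples,
         geometry = geometry,
         frame_interval = as.numeric(frame_interval),
         provenance = as.character(provenance)[1]),
    class = "rf_stack"
  )
}

#' @export
print.rf_stack <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("RF stack: %d elements x %d depth samples x %d frames\n",
              d[1], d[2], d[3]))
  cat(sprintf("  frame interval %.3g s, provenance: %s\n",
              x$frame_interval, x$provenance))
  invisible(x)
}

#' @rdname rf_stack
#' @param x Object to test.
#' @export
is_rf_stack <- function(x) inherits(x, "rf_stack")

n_frames <- function(stack) dim(stack$samples)[3]

#' Reshape an RF stack into its Casorati matrix
#'
#' Column `t` of the Casorati matrix is frame `t` flattened in element-major
#' order: row index `= (x - 1) * n_z + z` for element `x` and depth sample
#' `z`. This fixed flattening convention is shared by every routine that
#' reshapes spatial singular vectors back into images, so diagnostics and
#' filtering always agree on pixel order. The singular values themselves are
#' invariant to the choice.
#'
#' @param stack An [rf_stack()].
#' @return An object of class `casorati_matrix`: a list with `values`
#'   (matrix of shape `(n_x * n_z, n_t)`), `n_x` and `n_z`.
#' @seealso [from_casorati()]
#' @export
to_casorati <- function(stack) {
  stopifnot(is_rf_stack(stack))
  d <- dim(stack$samples)
  # aperm puts z fastest within each column so row = (x-1)*n_z + z
  values <- matrix(aperm(stack$samples, c(2, 1, 3)), nrow = d[1] * d[2])
  casorati_matrix(values, n_x = d[1], n_z = d[2])
}

#' Construct a Casorati matrix from raw values
#'
#' @param values Numeric matrix of shape `(n_x * n_z, n_t)`.
#' @param n_x,n_z Spatial dimensions of each flattened frame.
#' @return A `casorati_matrix` object.
#' @export
casorati_matrix <- function(values, n_x, n_z) {
  values <- as.matrix(values)
  n_x <- as.integer(n_x); n_z <- as.integer(n_z)
  if (nrow(values) != n_x * n_z) {
    stop("row count (", nrow(values), ") must equal n_x * n_z (",
         n_x * n_z, ")")
  }
  structure(list(values = values, n_x = n_x, n_z = n_z),
            class = "casorati_matrix")
}

#' @export
print.casorati_matrix <- function(x, ...) {
  cat(sprintf("Casorati matrix: (%d x %d) x %d frames  [n_x = %d, n_z = %d]\n",
              x$n_x, x$n_z, ncol(x$values), x$n_x, x$n_z))
  invisible(x)
}

#' Unroll a Casorati matrix back into an RF stack
#'
#' Exact inverse of [to_casorati()]; acquisition metadata is copied from
#' `template`.
#'
#' @param mat A `casorati_matrix` (or plain matrix with `n_x * n_z` rows).
#' @param template An [rf_stack()] providing the spatial dimensions and
#'   metadata.
#' @return An [rf_stack()] with `ncol(mat)` frames.
#' @export
from_casorati <- function(mat, template) {
  stopifnot(is_rf_stack(template))
  d <- dim(template$samples)
  values <- if (inherits(mat, "casorati_matrix")) mat$values else as.matrix(mat)
  if (nrow(values) != d[1] * d[2]) {
    stop("Casorati row count (", nrow(values), ") does not match template ",
         "n_x * n_z (", d[1] * d[2], ")")
  }
  samples <- aperm(array(values, c(d[2], d[1], ncol(values))), c(2, 1, 3))
  rf_stack(samples, template$geometry, template$frame_interval,
           template$provenance)
}

#' Reshape one spatial singular vector into an image
#'
#' Inverts the element-major flattening used by [to_casorati()] so that a
#' column of the spatial singular-vector matrix U can be viewed as an
#' `n_z x n_x` image (depth down, elements across).
#'
#' @param u Numeric vector of length `n_x * n_z`.
#' @param n_x,n_z Spatial dimensions.
#' @return An `n_z x n_x` matrix.
#' @export
spatial_vector_image <- function(u, n_x, n_z) {
  stopifnot(length(u) == n_x * n_z)
  matrix(u, nrow = n_z, ncol = n_x)
}
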