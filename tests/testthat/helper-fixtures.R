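# Shared fixtures, generated once per test run and cached across files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small acquisition for fast unit tests: 32-element array over 9.6 mm,
# shallow phantom, 320 depth samples (~12 mm).
small_geom <- function() array_geometry(n_elements = 32L)

small_phantom <- function(seed = 3L, n_vessels = 4L) {
  make_vessel_phantom(seed = seed, n_vessels = n_vessels,
                      extent_mm = c(12, 14), depth_extent_mm = c(5, 9),
                      tortuosity = 0.6)
}

small_motion_schedule <- function(n_t = 40L) {
  motion_schedule(rep(n_t %/% 4L, 4L), c(0, 1, 2, -1))
}

fixture_small_static <- function() {
  fixture("small_static", function() {
    make_sequence(small_phantom(), small_geom(), static_schedule(40L),
                  n_z = 320L)
  })
}

fixture_small_motion <- function() {
  fixture("small_motion", function() {
    make_sequence(small_phantom(), small_geom(), small_motion_schedule(),
                  n_z = 320L)
  })
}

# Full-scale study conditions (128 elements, 640 depth samples, 100 frames).
fixture_motion_sim <- function() {
  fixture("motion_sim", function() simulate_sequence("motion", snr_db = -10,
                                                     seed = 1L))
}

fixture_static_clean <- function() {
  fixture("static_clean", function() simulate_sequence("static",
                                                       snr_db = NULL,
                                                       seed = 1L)$clean)
}

fixture_full_prep <- function() {
  fixture("full_prep", function() {
    geom <- array_geometry()
    das_prepare(geom, image_grid(geom, z_range_mm = c(8, 23), dz_mm = 0.15),
                n_z = 640L)
  })
}

# Random orthonormal matrix (haar-ish via QR of a Gaussian).
random_orthonormal <- function(n, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * n), n)))
}

# Matrix with prescribed singular values, fixed seed.
matrix_with_spectrum <- function(m, n, d, seed) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(m * n), m, n)))
  V <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  U %*% (d * t(V))
}
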