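test_that("phantom generation is seeded and geometrically sane", {
  p1 <- make_vessel_phantom(seed = 5)
  p2 <- make_vessel_phantom(seed = 5)
  expect_identical(p1$pressure_map, p2$pressure_map)
  expect_false(identical(p1$pressure_map,
                         make_vessel_phantom(seed = 6)$pressure_map))

  # empty phantom
  p0 <- make_vessel_phantom(seed = 1, n_vessels = 0)
  expect_false(any(p0$vessel_mask))
  expect_equal(sum(p0$pressure_map), 0)

  # vessel pixels confined to the depth band, amplitudes decay with depth
  rows <- which(rowSums(p1$vessel_mask) > 0)
  expect_gte(min(p1$z_mm[rows]), 10)
  expect_lte(max(p1$z_mm[rows]), 20)
  expect_true(all(p1$pressure_map >= 0))
  expect_true(all(p1$vessel_mask == (p1$pressure_map > 0)))

  expect_error(make_vessel_phantom(radius_range = c(1, 6)), "impossible")
})

test_that("default phantoms occupy a plausible fraction of the grid", {
  fracs <- sapply(1:20, function(s)
    mean(make_vessel_phantom(seed = s)$vessel_mask))
  expect_true(all(fracs >= 0.005 & fracs <= 0.10))
})

test_that("forward projection respects symmetry, delay and linearity", {
  geom <- small_geom()
  blank <- make_vessel_phantom(seed = 1, n_vessels = 0,
                               extent_mm = c(12, 14),
                               depth_extent_mm = c(5, 9))
  point_at <- function(ph, z_mm, x_mm = 0) {
    iz <- which.min(abs(ph$z_mm - z_mm))
    ix <- which.min(abs(ph$x_mm - x_mm))
    ph$pressure_map[iz, ix] <- 1
    ph$vessel_mask[iz, ix] <- TRUE
    ph
  }

  # a source equidistant from two elements produces identical traces;
  # x = 0.15 mm lies on the phantom grid and is the midpoint of
  # elements 16 (x = -0.15) and 18 (x = 0.45)
  ex <- element_positions_mm(geom)
  fr <- forward_project(point_at(blank, 7.05, 0.15), geom, n_z = 320L)
  expect_equal((ex[16] + ex[18]) / 2, 0.15)
  expect_equal(fr[16, ], fr[18, ], tolerance = 1e-10)

  # on-axis time of flight: envelope peak at round(d / c * fs) +- 1
  # (z = 7.05 mm and x = -0.15 mm are exact grid points)
  d_mm <- 7.05
  fr2 <- forward_project(point_at(blank, d_mm, ex[16]), geom, n_z = 320L)
  peak <- which.max(envelope(fr2[16, ]))
  expected <- round(d_mm / (geom$sound_speed * 1e3) *
                      geom$sampling_rate * 1e6) + 1
  expect_lte(abs(peak - expected), 1)

  # superposition: two-point frame equals the sum of single-point frames
  pa <- point_at(blank, 6, -2); pb <- point_at(blank, 8, 2)
  pab <- point_at(point_at(blank, 6, -2), 8, 2)
  expect_equal(forward_project(pab, geom, 320L),
               forward_project(pa, geom, 320L) +
                 forward_project(pb, geom, 320L),
               tolerance = 1e-10)

  # array wider than the phantom grid is rejected
  expect_error(forward_project(blank, array_geometry(), 320L), "span")
})

test_that("clean Casorati rank equals the number of distinct motion states", {
  geom <- small_geom()
  ph <- small_phantom()
  shifts_pool <- c(0, 1, 2, -1, 0.5)
  for (n_states in 1:5) {
    sched <- motion_schedule(rep(4L, n_states),
                             shifts_pool[seq_len(n_states)])
    st <- make_sequence(ph, geom, sched, n_z = 320L)
    d <- full_svd(to_casorati(st))$d
    expect_lt(d[n_states + 1], 1e-8 * d[1])
    expect_gt(d[n_states], 1e-6 * d[1])
  }
})

test_that("static sequences are constant and schedule order is immaterial", {
  s <- fixture_small_static()
  expect_equal(s$samples[, , 1], s$samples[, , 40])
  d_static <- full_svd(to_casorati(s))$d
  expect_lt(d_static[2], 1e-10 * d_static[1])

  geom <- small_geom(); ph <- small_phantom()
  fwd <- make_sequence(ph, geom, motion_schedule(c(5L, 5L), c(0, 1)),
                       n_z = 320L)
  rev <- make_sequence(ph, geom, motion_schedule(c(5L, 5L), c(1, 0)),
                       n_z = 320L)
  expect_equal(full_svd(to_casorati(fwd))$d, full_svd(to_casorati(rev))$d,
               tolerance = 1e-10)
  # reversing permutes frames
  expect_equal(rev$samples[, , 1], fwd$samples[, , 10])

  expect_error(make_sequence(ph, geom, motion_schedule(10L, 30),
                             n_z = 320L), "off the grid")
})

test_that("noise injection is calibrated, seeded, and vanishes at high SNR", {
  s <- fixture_small_static()   # 32 * 320 * 40 = 4.1e5 entries
  for (snr in c(-5, -10, -15)) {
    noisy <- add_noise_db(s, snr, seed = 31)
    realized <- 10 * log10(mean(s$samples^2) /
                             mean((noisy$samples - s$samples)^2))
    expect_lt(abs(realized - snr), 0.1)
  }
  n1 <- add_noise_db(s, -10, seed = 8)
  n2 <- add_noise_db(s, -10, seed = 8)
  expect_identical(n1$samples, n2$samples)
  expect_false(identical(n1$samples, add_noise_db(s, -10, seed = 9)$samples))

  hi <- add_noise_db(s, 60, seed = 8)
  expect_lt(sqrt(sum((hi$samples - s$samples)^2) / sum(s$samples^2)),
            0.002)

  empty <- rf_stack(array(0, c(4, 16, 2)), array_geometry(n_elements = 4L))
  expect_error(add_noise_db(empty, -10), "zero energy")
})

test_that("a noisy static sequence has a near-constant first temporal vector", {
  s <- fixture_small_static()
  noisy <- add_noise_db(s, -5, seed = 13)
  v1 <- full_svd(to_casorati(noisy))$v[, 1]
  ones <- rep(1, length(v1)) / sqrt(length(v1))
  expect_gt(abs(sum(v1 * ones)), 0.99)
})

test_that("simulate_sequence presets encode the study conditions", {
  sim <- fixture_motion_sim()
  expect_equal(sim$schedule$z_shifts_mm, c(0, 1, 2, -1))
  expect_equal(sim$schedule$frame_counts, rep(25L, 4))
  expect_equal(dim(sim$noisy$samples), c(128L, 640L, 100L))
  expect_equal(aperture_mm(sim$clean$geometry), 38.4)
  realized <- 10 * log10(mean(sim$clean$samples^2) /
                           mean((sim$noisy$samples -
                                   sim$clean$samples)^2))
  expect_lt(abs(realized - (-10)), 0.1)
})
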