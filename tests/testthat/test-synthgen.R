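# Synthetic generators: Markov HB kinetics, end-to-end mapping, Brownian
# tracers, ideal helix geometry.

test_that("spec validation names the offending field", {
  expect_error(kinetics_spec(n_bonds = 0, k_form = 1, k_break = 1,
                             n_frames = 10), "n_bonds")
  expect_error(kinetics_spec(n_bonds = 1, k_form = -1, k_break = 1,
                             n_frames = 10), "k_form")
  expect_error(kinetics_spec(n_bonds = 1, k_form = 1, k_break = 1,
                             n_frames = 1), "n_frames")
  expect_error(kinetics_spec(n_bonds = 1, k_form = 1, k_break = 1,
                             cooperativity = 0, n_frames = 10),
               "cooperativity")
  expect_error(brownian_spec(n_particles = 1, d_true = 0, n_frames = 10),
               "d_true")
  expect_error(geometry_spec(coil_length_sd = -1), "coil_length_sd")
})

test_that("generators are bit-reproducible under a fixed seed", {
  spec <- kinetics_spec(n_bonds = 3, k_form = 100, k_break = 300,
                        dt = 2, n_frames = 5000, seed = 42)
  s1 <- simulate_hb_states(spec)
  s2 <- simulate_hb_states(spec)
  expect_identical(s1$states, s2$states)

  g <- geometry_spec(seed = 7)
  expect_identical(hb_to_end_to_end(s1, g), hb_to_end_to_end(s2, g))

  bs <- brownian_spec(n_particles = 5, d_true = 1e-5, n_frames = 100,
                      seed = 9)
  expect_identical(simulate_brownian(bs)$coords,
                   simulate_brownian(bs)$coords)
})

test_that("stationary occupancy matches k_form/(k_form+k_break) within 3 SE", {
  # tau_c = 1/(k_f+k_u) = 5 ns = 2500 frames at dt = 2 ps
  spec <- kinetics_spec(n_bonds = 4, k_form = 50, k_break = 150,
                        dt = 2, n_frames = 1e6, seed = 1)
  st <- simulate_hb_states(spec)
  p <- 50 / 200
  se <- occupancy_se(p, tau_frames = 2500, n_frames = 1e6, n_indep = 4)
  expect_lt(abs(mean(st$states) - p), 3 * se)
})

test_that("k_break = 0 makes the formed state absorbing", {
  spec <- kinetics_spec(n_bonds = 2, k_form = 1e4, k_break = 0,
                        dt = 2, n_frames = 5000, seed = 3, init = "broken")
  st <- simulate_hb_states(spec)
  for (b in 1:2) expect_true(all(diff(st$states[, b]) >= 0))
  expect_equal(st$states[5000, ], c(1L, 1L))
})

test_that("formed dwell times are exponential with mean 1/k_break (KS)", {
  # tau = 100 ps at dt = 0.5 ps keeps the discretization error well below
  # the KS critical distance at n = 1e4
  spec <- kinetics_spec(n_bonds = 1, k_form = 5e3, k_break = 1e4,
                        dt = 0.5, n_frames = 6.2e6, seed = 11)
  st <- simulate_hb_states(spec)
  dw <- extract_dwells(st, "per_bond_formed")
  expect_gt(length(dw$durations), 1e4)
  ks <- suppressWarnings(stats::ks.test(dw$durations, stats::pexp,
                                        rate = 1 / 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-bond ACF decays at rate k_form + k_break", {
  # tau_c = 250 ps = 125 frames; 2e6 frames give ~1% ACF noise
  spec <- kinetics_spec(n_bonds = 1, k_form = 2000, k_break = 2000,
                        dt = 2, n_frames = 2e6, seed = 5)
  st <- simulate_hb_states(spec)
  ac <- autocorrelation(as.numeric(st$states[, 1]), 2000)
  fit <- fit_relaxation(ac, st$dt)
  expect_lt(abs(fit$tau / 250 - 1), 0.05)
})

test_that("cooperativity boosts occupancy of interior bonds", {
  base <- kinetics_spec(n_bonds = 5, k_form = 50, k_break = 500,
                        dt = 2, n_frames = 5e5, seed = 13)
  coop <- kinetics_spec(n_bonds = 5, k_form = 50, k_break = 500,
                        cooperativity = 10, dt = 2, n_frames = 5e5,
                        seed = 13)
  occ_base <- mean(simulate_hb_states(base)$states)
  occ_coop <- mean(simulate_hb_states(coop)$states)
  expect_gt(occ_coop, occ_base * 1.2)
})

test_that("hb_to_end_to_end arithmetic and conditional structure", {
  st <- hb_state_matrix(matrix(c(1, 1, 1, 1,
                                 1, 1, 0, 0,
                                 0, 0, 0, 0), nrow = 3, byrow = TRUE),
                        dt = 2)
  g0 <- geometry_spec(coil_length_mean = 1.0, coil_length_sd = 0,
                      rise_per_residue = 0.15)
  d <- hb_to_end_to_end(st, g0)
  expect_equal(d, c(1.60, 1.30, 1.00), tolerance = 1e-12,
               ignore_attr = TRUE)

  # conditional means for h and h+1 differ by exactly the rise when sd = 0
  expect_equal(d[1] - d[2], 2 * 0.15, tolerance = 1e-12)

  # with noise: conditional mean increasing in h, spread ~ coil sd
  spec <- kinetics_spec(n_bonds = 4, k_form = 200, k_break = 200,
                        dt = 2, n_frames = 2e5, seed = 21)
  stn <- simulate_hb_states(spec)
  gn <- geometry_spec(coil_length_sd = 0.1, seed = 2)
  dn <- hb_to_end_to_end(stn, gn)
  mu <- tapply(dn, stn$h_series, mean)
  expect_true(all(diff(mu) > 0))
  sds <- tapply(dn, stn$h_series, sd)
  expect_true(all(abs(sds - 0.1) < 0.01))
  expect_true(all(dn >= 0))
})

test_that("Brownian increments have per-axis variance 2 D dt", {
  d_true <- 5.6635e-5                       # cm^2/s
  bs <- brownian_spec(n_particles = 100, d_true = d_true, dt = 2,
                      n_frames = 2000, seed = 17)
  paths <- simulate_brownian(bs)
  v_expect <- 2 * d_true * 100 * 2          # nm^2 per step
  for (ax in 1:3) {
    incr <- diff(paths$coords[, , ax])
    expect_lt(abs(var(as.numeric(incr)) / v_expect - 1), 0.02)
  }
})

test_that("ideal helix geometry: chord distances and HB detection", {
  g <- geometry_spec(rise_per_residue = 0.15, twist_per_residue = 100,
                     helix_radius = 0.23)
  fr <- ideal_helix_coordinates(8, g)
  ca <- fr$coords[1, fr$atoms$role == "CA", ]
  chords <- sqrt(rowSums(diff(ca)^2))
  chord_expect <- sqrt(0.15^2 + (2 * 0.23 * sin(50 * pi / 180))^2)
  expect_equal(unname(chords), rep(chord_expect, 7), tolerance = 1e-10)
  expect_equal(chord_expect, 0.383, tolerance = 1e-3)

  two <- ideal_helix_coordinates(2, g)
  ca2 <- two$coords[1, two$atoms$role == "CA", ]
  expect_equal(sqrt(sum((ca2[1, ] - ca2[2, ])^2)), chord_expect,
               tolerance = 1e-10)

  hb <- detect_hbonds(fr)
  expect_equal(hb$h_series, hb$h_max)
  expect_equal(hb$h_max, 4L)

  expect_error(ideal_helix_coordinates(1), "n_residues")
})
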