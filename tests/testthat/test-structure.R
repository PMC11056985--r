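# Structural observables: HB detection, helix fraction, end-to-end
# distance, RMSDH superposition.

make_pair_frame <- function(n_dist) {
  # one O(1)...N(5) pair at distance n_dist along z
  atoms <- data.frame(residue = c(1L, 5L), role = c("O", "N"))
  coords <- rbind(c(0, 0, 0), c(0, 0, n_dist))
  frame_series(0, atoms, coords)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}

transform_frames <- function(fr, rot, shift) {
  out <- fr
  for (i in seq_along(fr$times)) {
    m <- matrix(fr$coords[i, , ], ncol = 3)
    out$coords[i, , ] <- m %*% t(rot) + matrix(shift, nrow(m), 3,
                                               byrow = TRUE)
  }
  out
}

test_that("HB criterion is strictly below the cutoff", {
  expect_equal(detect_hbonds(make_pair_frame(0.35))$states[1, 1], 1L)
  expect_equal(detect_hbonds(make_pair_frame(0.36))$states[1, 1], 0L)
  expect_equal(detect_hbonds(make_pair_frame(0.3599999))$states[1, 1], 1L)
})

test_that("detect_hbonds errors name the missing residue and role", {
  atoms <- data.frame(residue = c(1L, 5L), role = c("O", "CA"))
  fr <- frame_series(0, atoms, rbind(c(0, 0, 0), c(0, 0, 0.3)))
  expect_error(detect_hbonds(fr), "residue 5.*'N'")
})

test_that("detect_hbonds is invariant under rigid motion", {
  fr <- ideal_helix_coordinates(9)
  ref <- detect_hbonds(fr)$states
  for (s in 1:5) {
    moved <- transform_frames(fr, random_rotation(s), rnorm(3, sd = 5))
    expect_identical(detect_hbonds(moved)$states, ref)
  }
})

test_that("helix_fraction definition and concatenation linearity", {
  mk <- function(h_rows) hb_state_matrix(h_rows, dt = 2, h_max = 4)
  full <- mk(matrix(1L, nrow = 3, ncol = 4))
  expect_equal(helix_fraction(full), 1)

  m <- rbind(rep(0L, 4), rep(1L, 4), rep(1L, 4), rep(0L, 4))
  expect_equal(helix_fraction(mk(m)), 0.5)

  a <- mk(m[1:2, , drop = FALSE]); b <- mk(m)
  combined <- mk(rbind(m[1:2, , drop = FALSE], m))
  expect_equal(helix_fraction(combined),
               (2 * helix_fraction(a) + 4 * helix_fraction(b)) / 6)

  degenerate <- hb_state_matrix(matrix(0L, 2, 1), dt = 2)
  degenerate$h_max <- 0L
  expect_error(helix_fraction(degenerate), "h_max")
})

test_that("end_to_end distance and invariances", {
  atoms <- data.frame(residue = c(1L, 2L), role = c("terminal", "terminal"))
  fr <- frame_series(0, atoms, rbind(c(0, 0, 0), c(0, 0, 2.5)))
  expect_equal(end_to_end(fr), 2.5)

  shifted <- transform_frames(fr, diag(3), c(1, -2, 3))
  expect_equal(end_to_end(shifted), 2.5, tolerance = 1e-12)

  # default termini: first and last CA by residue
  helix <- ideal_helix_coordinates(8)
  ca <- helix$coords[1, helix$atoms$role == "CA", ]
  expect_equal(end_to_end(helix),
               sqrt(sum((ca[1, ] - ca[8, ])^2)), tolerance = 1e-12)

  bad <- frame_series(0, data.frame(residue = 1L, role = "O"),
                      rbind(c(0, 0, 0)))
  expect_error(end_to_end(bad), "terminal")
})

test_that("rmsdh is zero under rigid motion and bounded for displacements", {
  helix <- ideal_helix_coordinates(10)
  expect_lt(rmsdh(helix, helix), 1e-12)
  for (s in 1:5) {
    moved <- transform_frames(helix, random_rotation(s + 10), rnorm(3))
    expect_lt(rmsdh(moved, helix), 1e-9)
  }

  # one of 10 CA atoms displaced by 0.03 nm: RMSDH <= 0.03/sqrt(10)
  perturbed <- helix
  ca_idx <- which(helix$atoms$role == "CA")[4]
  perturbed$coords[1, ca_idx, 3] <- perturbed$coords[1, ca_idx, 3] + 0.03
  expect_lte(rmsdh(perturbed, helix), 0.03 / sqrt(10) + 1e-12)
  expect_gt(rmsdh(perturbed, helix), 0)

  short <- ideal_helix_coordinates(6)
  expect_error(rmsdh(short, helix), "mismatch")
})

test_that("rmsdh agrees with an optimizer oracle on small toys", {
  set.seed(31)
  for (case in 1:4) {
    n <- sample(3:5, 1)
    x <- matrix(rnorm(3 * n), ncol = 3)
    y <- matrix(rnorm(3 * n), ncol = 3)
    atoms <- data.frame(residue = seq_len(n), role = rep("CA", n))
    fx <- frame_series(0, atoms, x)
    fy <- frame_series(0, atoms, y)
    expect_equal(rmsdh(fx, fy), oracle_rmsd(x, y), tolerance = 1e-6)
  }
})

test_that("rmsdh_histogram conserves frame counts", {
  expect_error(rmsdh_histogram(numeric(0), 0.1), "empty")
  expect_error(rmsdh_histogram(1, -0.1), "bin_width")

  h1 <- rmsdh_histogram(rep(0.2, 50), 0.05)
  expect_equal(sum(h1$count), 50)
  expect_equal(sum(h1$count > 0), 1)

  set.seed(8)
  vals <- c(rnorm(500, 0.1, 0.01), rnorm(500, 0.8, 0.01))
  h2 <- rmsdh_histogram(vals, 0.05)
  expect_equal(sum(h2$count), 1000)
  # bimodal mixture: two occupied regions, modes near the generator means
  occupied <- h2[h2$count > 50, ]
  expect_true(any(occupied$bin_left <= 0.1 & 0.1 <= occupied$bin_right))
  expect_true(any(occupied$bin_left <= 0.8 & 0.8 <= occupied$bin_right))
})
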