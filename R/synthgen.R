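# Synthetic trajectory generators. These emulate the statistical structure
# the downstream analysis assumes -- two-state multi-bond helix-coil
# kinetics, helix-geometry end-to-end distances with coil noise, and 3-D
# Brownian tracer motion -- and are stand-ins for MD output, not models of
# MD ensembles.

#' Simulate hydrogen-bond formation states
#'
#' Each bond is a two-state continuous-time Markov chain sampled every `dt`
#' picoseconds using the exact per-step transition probabilities
#' `1 - exp(-k dt)` (not an Euler step), so dwell statistics are unbiased at
#' coarse frame intervals. With `cooperativity != 1`, the formation rate of
#' a broken bond is multiplied by the cooperativity factor whenever at least
#' one neighbouring bond was formed at the previous frame.
#'
#' The stationary occupancy of an independent bond is
#' `k_form / (k_form + k_break)` and the state autocorrelation decays at
#' rate `k_form + k_break`.
#'
#' @param spec a [kinetics_spec()].
#' @return an [hb_state_matrix()] with generator metadata (seed, rates).
#' @export
simulate_hb_states <- function(spec) {
  if (!inherits(spec, "KineticsSpec"))
    stop("simulate_hb_states: 'spec' must be a KineticsSpec")
  init_code <- switch(spec$init, broken = 0L, formed = 1L, stationary = 2L)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  states <- simulate_hb_chain_cpp(spec$n_frames, spec$n_bonds,
                                  spec$k_form, spec$k_break,
                                  spec$cooperativity, spec$dt * 1e-6,
                                  init_code)
  hb_state_matrix(states, dt = spec$dt,
                  meta = list(generator = "simulate_hb_states",
                              seed = spec$seed, k_form = spec$k_form,
                              k_break = spec$k_break,
                              cooperativity = spec$cooperativity,
                              init = spec$init))
}

#' Map HB counts to synthetic end-to-end distances
#'
#' Per-frame distance is a coil baseline sample (Gaussian with mean
#' `coil_length_mean` and sd `coil_length_sd`, truncated at zero) plus the
#' number of formed bonds times `rise_per_residue`. The conditional mean
#' given `h` formed bonds is therefore strictly increasing in `h`, with
#' conditional spread equal to the coil sd.
#'
#' @param states an [hb_state_matrix()].
#' @param geom a [geometry_spec()].
#' @return numeric vector of end-to-end distances (nm), one per frame, with
#'   the generator seed attached as attribute `seed`.
#' @export
hb_to_end_to_end <- function(states, geom) {
  if (!inherits(states, "HBStateMatrix"))
    stop("hb_to_end_to_end: 'states' must be an HBStateMatrix")
  if (!inherits(geom, "GeometrySpec"))
    stop("hb_to_end_to_end: 'geom' must be a GeometrySpec")
  n <- length(states$h_series)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(geom$seed)
  base <- rnorm(n, geom$coil_length_mean, geom$coil_length_sd)
  bad <- which(base < 0)
  while (length(bad) > 0) {  # truncation at zero: distances are nonnegative
    base[bad] <- rnorm(length(bad), geom$coil_length_mean,
                       geom$coil_length_sd)
    bad <- bad[base[bad] < 0]
  }
  d <- base + states$h_series * geom$rise_per_residue
  attr(d, "seed") <- geom$seed
  d
}

#' Simulate Brownian tracer particles
#'
#' Independent 3-D Gaussian increments with per-axis variance
#' `2 * d_true * dt`, so the ensemble MSD slope divided by 6 recovers
#' `d_true`.
#'
#' @param spec a [brownian_spec()].
#' @return a `ParticlePaths` object: list with `coords` (array of dim
#'   `(n_frames, n_particles, 3)`, nm), `times` (ps), `dt` and metadata.
#' @export
simulate_brownian <- function(spec) {
  if (!inherits(spec, "BrownianSpec"))
    stop("simulate_brownian: 'spec' must be a BrownianSpec")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  d_nm2_ps <- spec$d_true * 100  # 1 cm^2/s = 100 nm^2/ps
  sigma <- sqrt(2 * d_nm2_ps * spec$dt)
  nf <- spec$n_frames; np <- spec$n_particles
  coords <- array(0, dim = c(nf, np, 3L))
  for (ax in 1:3) {
    incr <- matrix(rnorm((nf - 1L) * np, sd = sigma), nrow = nf - 1L)
    coords[, , ax] <- rbind(0, apply(incr, 2L, cumsum))
  }
  structure(list(coords = coords, times = (seq_len(nf) - 1) * spec$dt,
                 dt = spec$dt,
                 meta = list(generator = "simulate_brownian",
                             seed = spec$seed, d_true = spec$d_true)),
            class = "ParticlePaths")
}

#' @export
print.ParticlePaths <- function(x, ...) {
  cat(sprintf("ParticlePaths: %d particles, %d frames (dt = %g ps)\n",
              dim(x$coords)[2], dim(x$coords)[1], x$dt))
  invisible(x)
}

#' Ideal alpha-helix coordinates
#'
#' Places C-alpha atoms on a regular helix with the stated rise, twist and
#' radius, and backbone O and N atoms phase-shifted along the same helix so
#' that every i -> i+4 O...N distance equals `on_distance` (0.29 nm by
#' default, below the 0.36 nm HB cutoff) for the ideal geometry.
#'
#' @param n_residues number of residues (>= 2).
#' @param geom a [geometry_spec()].
#' @param on_distance target O(i)...N(i+4) distance (nm).
#' @return a single-frame [frame_series()] with roles `CA`, `O`, `N`.
#' @export
ideal_helix_coordinates <- function(n_residues, geom = geometry_spec(),
                                    on_distance = 0.29) {
  if (!is.numeric(n_residues) || n_residues < 2)
    stop("ideal_helix_coordinates: 'n_residues' must be >= 2")
  n_residues <- as.integer(n_residues)
  rise <- geom$rise_per_residue
  twist <- geom$twist_per_residue * pi / 180
  r <- geom$helix_radius

  idx <- seq_len(n_residues)
  theta <- (idx - 1) * twist
  ca <- cbind(r * cos(theta), r * sin(theta), (idx - 1) * rise)

  # O(i) sits at phase +phi_o and +z_o from CA(i); N(i) at phase
  # phi_o - 4*twist and z_o - 4*rise + on_distance, which puts O(i) and
  # N(i+4) at the same helix angle, separated axially by exactly
  # on_distance.
  phi_o <- 20 * pi / 180
  z_o <- on_distance / 2
  phi_n <- phi_o - 4 * twist
  z_n <- z_o - 4 * rise + on_distance
  o_xyz <- cbind(r * cos(theta + phi_o), r * sin(theta + phi_o),
                 (idx - 1) * rise + z_o)
  n_xyz <- cbind(r * cos(theta + phi_n), r * sin(theta + phi_n),
                 (idx - 1) * rise + z_n)

  atoms <- data.frame(residue = rep(idx, times = 3L),
                      role = rep(c("CA", "O", "N"), each = n_residues))
  coords <- rbind(ca, o_xyz, n_xyz)
  frame_series(times = 0, atoms = atoms, coords = coords)
}

# Save/restore the global RNG state so generators own their streams without
# disturbing the caller's.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
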