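# Validated parameter bundles for the synthetic generators. Each generator
# owns one RNG stream (its seed), recorded in the output metadata.

.check_field <- function(ok, spec, field, msg) {
  if (!ok) stop(sprintf("%s: invalid field '%s' (%s)", spec, field, msg),
                call. = FALSE)
}

#' Kinetics specification for the synthetic HB simulator
#'
#' Describes a set of helical hydrogen-bond sites evolving as independent (or
#' nearest-neighbour-coupled) two-state continuous-time Markov chains sampled
#' at a fixed frame interval.
#'
#' @param n_bonds number of helical HB sites.
#' @param k_form per-bond formation rate (1/us).
#' @param k_break per-bond rupture rate (1/us); 0 makes the formed state
#'   absorbing.
#' @param cooperativity multiplier applied to `k_form` when at least one
#'   neighbouring bond is formed (1 = independent bonds).
#' @param dt frame interval (ps).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed for the generator's RNG stream.
#' @param init initial state: `"stationary"` (independent-bond stationary
#'   draw), `"broken"` or `"formed"`.
#' @return a `KineticsSpec` object.
#' @export
kinetics_spec <- function(n_bonds, k_form, k_break, cooperativity = 1,
                          dt = 2, n_frames, seed = 1L,
                          init = c("stationary", "broken", "formed")) {
  init <- match.arg(init)
  .check_field(is.numeric(n_bonds) && n_bonds >= 1, "KineticsSpec",
               "n_bonds", "must be >= 1")
  .check_field(is.numeric(k_form) && k_form > 0, "KineticsSpec",
               "k_form", "must be > 0")
  .check_field(is.numeric(k_break) && k_break >= 0, "KineticsSpec",
               "k_break", "must be >= 0")
  .check_field(is.numeric(cooperativity) && cooperativity > 0, "KineticsSpec",
               "cooperativity", "must be > 0")
  .check_field(is.numeric(dt) && dt > 0, "KineticsSpec", "dt", "must be > 0")
  .check_field(is.numeric(n_frames) && n_frames >= 2, "KineticsSpec",
               "n_frames", "must be >= 2")
  .check_field(is.numeric(seed) && is.finite(seed), "KineticsSpec",
               "seed", "must be a finite integer")
  structure(list(n_bonds = as.integer(n_bonds), k_form = k_form,
                 k_break = k_break, cooperativity = cooperativity,
                 dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), init = init),
            class = "KineticsSpec")
}

#' Helix geometry specification
#'
#' Geometry used both to place atoms of an ideal alpha-helix and to map HB
#' counts to synthetic end-to-end distances: each formed bond extends the
#' chain by one helix rise, on top of a Gaussian coil baseline truncated at
#' zero (distances are nonnegative).
#'
#' @param rise_per_residue helix rise per residue (nm), default 0.15.
#' @param twist_per_residue helix twist per residue (degrees), default 100.
#' @param helix_radius C-alpha helix radius (nm), default 0.23.
#' @param coil_length_mean,coil_length_sd end-to-end statistics of the fully
#'   broken (coil) state (nm).
#' @param seed integer seed.
#' @return a `GeometrySpec` object.
#' @export
geometry_spec <- function(rise_per_residue = 0.15, twist_per_residue = 100,
                          helix_radius = 0.23, coil_length_mean = 1.0,
                          coil_length_sd = 0.1, seed = 1L) {
  .check_field(is.numeric(rise_per_residue) && rise_per_residue > 0,
               "GeometrySpec", "rise_per_residue", "must be > 0")
  .check_field(is.numeric(helix_radius) && helix_radius > 0,
               "GeometrySpec", "helix_radius", "must be > 0")
  .check_field(is.numeric(coil_length_sd) && coil_length_sd >= 0,
               "GeometrySpec", "coil_length_sd", "must be >= 0")
  .check_field(is.numeric(coil_length_mean) && coil_length_mean >= 0,
               "GeometrySpec", "coil_length_mean", "must be >= 0")
  structure(list(rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 helix_radius = helix_radius,
                 coil_length_mean = coil_length_mean,
                 coil_length_sd = coil_length_sd, seed = as.integer(seed)),
            class = "GeometrySpec")
}

#' Brownian tracer specification
#'
#' Independent 3-D Brownian particles with a prescribed diffusion constant,
#' standing in for water center-of-mass trajectories in the MSD analysis.
#'
#' @param n_particles number of particles (>= 1).
#' @param d_true diffusion constant (cm^2/s), must be > 0.
#' @param dt frame interval (ps).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @return a `BrownianSpec` object.
#' @export
brownian_spec <- function(n_particles, d_true, dt = 1, n_frames, seed = 1L) {
  .check_field(is.numeric(n_particles) && n_particles >= 1, "BrownianSpec",
               "n_particles", "must be >= 1")
  .check_field(is.numeric(d_true) && d_true > 0, "BrownianSpec",
               "d_true", "must be > 0")
  .check_field(is.numeric(dt) && dt > 0, "BrownianSpec", "dt", "must be > 0")
  .check_field(is.numeric(n_frames) && n_frames >= 2, "BrownianSpec",
               "n_frames", "must be >= 2")
  structure(list(n_particles = as.integer(n_particles), d_true = d_true,
                 dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "BrownianSpec")
}
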