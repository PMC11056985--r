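# Core containers shared across modules: HB state matrices and coordinate
# frame series. Both are plain lists with a class tag and validated fields,
# in the style of base-R time-series containers.

#' Construct an HB state matrix
#'
#' Per-frame, per-bond boolean formation states plus the derived total-HB
#' series `h_series` and the topology maximum `h_max`.
#'
#' @param states integer/logical matrix, frames x bonds (0/1).
#' @param dt frame interval (ps).
#' @param bond_labels optional character vector naming the (i, i+4) pairs.
#' @param h_max maximum HB count for the topology (default `ncol(states)`).
#' @param meta optional list of provenance metadata (seed, generator
#'   settings).
#' @return an `HBStateMatrix` object with fields `states`, `dt`,
#'   `bond_labels`, `h_series`, `h_max`, `meta`.
#' @export
hb_state_matrix <- function(states, dt, bond_labels = NULL, h_max = NULL,
                            meta = list()) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (any(states != 0L & states != 1L))
    stop("hb_state_matrix: 'states' must be 0/1")
  if (!is.numeric(dt) || dt <= 0)
    stop("hb_state_matrix: 'dt' must be > 0")
  if (is.null(bond_labels))
    bond_labels <- sprintf("b%d_%d", seq_len(ncol(states)),
                           seq_len(ncol(states)) + 4L)
  if (is.null(h_max)) h_max <- ncol(states)
  h_series <- as.integer(rowSums(states))
  if (any(h_series > h_max))
    stop("hb_state_matrix: h_series exceeds h_max")
  structure(list(states = states, dt = dt, bond_labels = bond_labels,
                 h_series = h_series, h_max = as.integer(h_max), meta = meta),
            class = "HBStateMatrix")
}

#' @export
print.HBStateMatrix <- function(x, ...) {
  cat(sprintf("HBStateMatrix: %d frames x %d bonds (dt = %g ps, h_max = %d)\n",
              nrow(x$states), ncol(x$states), x$dt, x$h_max))
  cat(sprintf("  mean h = %.3f, helix fraction = %.3f\n",
              mean(x$h_series), mean(x$h_series) / x$h_max))
  invisible(x)
}

#' Construct a coordinate frame series
#'
#' Time-stamped coordinate snapshots of labelled atoms. Every frame shares
#' the same atom ordering; roles are `CA`, `O`, `N` and optionally
#' `terminal`.
#'
#' @param times frame timestamps (ps), strictly increasing.
#' @param atoms data.frame with columns `residue` (integer) and `role`
#'   (character); one row per atom, in coordinate order.
#' @param coords numeric array of dim `(n_frames, n_atoms, 3)` in nm, or an
#'   `n_atoms x 3` matrix for a single frame.
#' @return a `FrameSeries` object.
#' @export
frame_series <- function(times, atoms, coords) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("frame_series: 'coords' must have dim (n_frames, n_atoms, 3)")
  if (length(times) != dim(coords)[1])
    stop("frame_series: length(times) must equal the number of frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame_series: 'times' must be strictly increasing")
  if (!all(c("residue", "role") %in% names(atoms)))
    stop("frame_series: 'atoms' needs columns 'residue' and 'role'")
  if (nrow(atoms) != dim(coords)[2])
    stop("frame_series: nrow(atoms) must equal the number of atom columns")
  structure(list(times = as.numeric(times),
                 atoms = data.frame(residue = as.integer(atoms$residue),
                                    role = as.character(atoms$role),
                                    stringsAsFactors = FALSE),
                 coords = coords),
            class = "FrameSeries")
}

#' @export
print.FrameSeries <- function(x, ...) {
  cat(sprintf("FrameSeries: %d frames, %d atoms (roles: %s)\n",
              length(x$times), nrow(x$atoms),
              paste(sort(unique(x$atoms$role)), collapse = ", ")))
  invisible(x)
}

# Extract the coordinates of one frame as an n_atoms x 3 matrix.
frame_coords <- function(frames, i) {
  matrix(frames$coords[i, , ], ncol = 3L)
}

# Frame interval of a FrameSeries (1 ps placeholder for single frames, which
# carry no interval information).
frame_dt <- function(frames) {
  if (length(frames$times) >= 2) frames$times[2] - frames$times[1] else 1
}
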