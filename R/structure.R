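# Structural observables: HB detection, helix fraction, end-to-end
# distance, and RMSD from the ideal helix (RMSDH) with optimal rigid-body
# superposition.

#' Detect helical (i, i+4) hydrogen bonds
#'
#' A bond between the carbonyl oxygen of residue i and the amide nitrogen of
#' residue i+4 is formed at a frame iff their distance is strictly below the
#' cutoff ("below 0.36 nm" convention). Detection is purely distance based
#' and invariant under rigid motion of the coordinates.
#'
#' @param frames a [frame_series()] containing `O` and `N` roles for every
#'   (i, i+4) residue pair of the topology.
#' @param cutoff distance cutoff in nm (default 0.36).
#' @param h_max maximum HB count; defaults to the number of (i, i+4) pairs
#'   present (n_residues - 4 for a plain topology). Capping-group
#'   donors/acceptors can be included by supplying extra residues.
#' @return an [hb_state_matrix()]; `dt` is taken from the frame timestamps.
#' @export
detect_hbonds <- function(frames, cutoff = 0.36, h_max = NULL) {
  if (!inherits(frames, "FrameSeries"))
    stop("detect_hbonds: 'frames' must be a FrameSeries")
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("detect_hbonds: 'cutoff' must be > 0")
  residues <- sort(unique(frames$atoms$residue))
  donors <- residues[(residues + 4L) %in% residues]
  if (length(donors) == 0)
    stop("detect_hbonds: topology has no (i, i+4) residue pairs")
  o_idx <- integer(length(donors)); n_idx <- integer(length(donors))
  for (j in seq_along(donors)) {
    i <- donors[j]
    oi <- which(frames$atoms$residue == i & frames$atoms$role == "O")
    ni <- which(frames$atoms$residue == i + 4L & frames$atoms$role == "N")
    if (length(oi) != 1)
      stop(sprintf("detect_hbonds: residue %d: missing atom role 'O'", i))
    if (length(ni) != 1)
      stop(sprintf("detect_hbonds: residue %d: missing atom role 'N'",
                   i + 4L))
    o_idx[j] <- oi; n_idx[j] <- ni
  }
  nf <- length(frames$times)
  states <- matrix(0L, nrow = nf, ncol = length(donors))
  for (j in seq_along(donors)) {
    dx <- frames$coords[, o_idx[j], 1] - frames$coords[, n_idx[j], 1]
    dy <- frames$coords[, o_idx[j], 2] - frames$coords[, n_idx[j], 2]
    dz <- frames$coords[, o_idx[j], 3] - frames$coords[, n_idx[j], 3]
    states[, j] <- as.integer(sqrt(dx^2 + dy^2 + dz^2) < cutoff)
  }
  hb_state_matrix(states, dt = frame_dt(frames),
                  bond_labels = sprintf("b%d_%d", donors, donors + 4L),
                  h_max = h_max,
                  meta = list(cutoff = cutoff, source = "detect_hbonds"))
}

#' Helix fraction from HB states
#'
#' The folded fraction `f = mean(h_i) / h_max`: the trajectory-averaged
#' number of formed helical HBs relative to the topology maximum.
#'
#' @param states an [hb_state_matrix()].
#' @return f in `[0, 1]`.
#' @export
helix_fraction <- function(states) {
  if (!inherits(states, "HBStateMatrix"))
    stop("helix_fraction: 'states' must be an HBStateMatrix")
  if (states$h_max <= 0)
    stop("helix_fraction: h_max must be > 0")
  mean(states$h_series) / states$h_max
}

#' End-to-end distance series
#'
#' Per-frame Euclidean distance between the two terminus atoms. Atoms with
#' role `terminal` are used when present; otherwise the first and last
#' `CA` atoms (by residue index) serve as the default termini.
#'
#' @param frames a [frame_series()].
#' @return numeric vector (nm), one entry per frame.
#' @export
end_to_end <- function(frames) {
  if (!inherits(frames, "FrameSeries"))
    stop("end_to_end: 'frames' must be a FrameSeries")
  term <- which(frames$atoms$role == "terminal")
  if (length(term) == 0) {
    ca <- which(frames$atoms$role == "CA")
    if (length(ca) < 2)
      stop("end_to_end: missing 'terminal' atoms and fewer than two CA atoms")
    ord <- ca[order(frames$atoms$residue[ca])]
    term <- c(ord[1], ord[length(ord)])
  }
  if (length(term) != 2)
    stop("end_to_end: expected exactly two 'terminal' atoms, found ",
         length(term))
  dx <- frames$coords[, term[1], 1] - frames$coords[, term[2], 1]
  dy <- frames$coords[, term[1], 2] - frames$coords[, term[2], 2]
  dz <- frames$coords[, term[1], 3] - frames$coords[, term[2], 3]
  sqrt(dx^2 + dy^2 + dz^2)
}

# Kabsch superposition: optimal proper rotation (reflections disallowed)
# and translation of x onto y, both n x 3. Returns the minimum RMSD.
.kabsch_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffs <- yc - xc %*% t(rot)
  sqrt(mean(rowSums(diffs^2)))
}

#' RMSD from an ideal-helix reference (RMSDH)
#'
#' Per-frame minimum RMSD of the selected atoms after optimal rigid-body
#' superposition (least-squares rotation + translation; reflections are
#' disallowed). Zero iff the frame is congruent with the reference.
#'
#' @param frames a [frame_series()].
#' @param reference a single-frame [frame_series()], typically from
#'   [ideal_helix_coordinates()].
#' @param selection atom roles entering the superposition (default `"CA"`).
#' @return numeric vector of RMSDH values (nm), one per frame.
#' @export
rmsdh <- function(frames, reference, selection = "CA") {
  if (!inherits(frames, "FrameSeries") || !inherits(reference, "FrameSeries"))
    stop("rmsdh: 'frames' and 'reference' must be FrameSeries")
  sel_f <- which(frames$atoms$role %in% selection)
  sel_r <- which(reference$atoms$role %in% selection)
  if (length(sel_f) != length(sel_r))
    stop(sprintf("rmsdh: atom-count mismatch (%d selected vs %d in reference)",
                 length(sel_f), length(sel_r)))
  if (length(sel_f) < 3)
    stop("rmsdh: need at least 3 selected atoms for superposition")
  ref <- matrix(reference$coords[1, sel_r, ], ncol = 3L)
  vapply(seq_along(frames$times), function(i) {
    .kabsch_rmsd(matrix(frames$coords[i, sel_f, ], ncol = 3L), ref)
  }, numeric(1))
}

#' Histogram of an RMSDH (or any nonnegative) series
#'
#' Equilibrium state densities: counts of frames per RMSDH bin.
#'
#' @param series numeric vector (nm).
#' @param bin_width bin width (nm), > 0.
#' @return data.frame with columns `bin_left`, `bin_right`, `count`; counts
#'   sum to `length(series)`.
#' @export
rmsdh_histogram <- function(series, bin_width) {
  if (length(series) == 0) stop("rmsdh_histogram: empty series")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("rmsdh_histogram: 'bin_width' must be > 0")
  lo <- floor(min(series) / bin_width) * bin_width
  hi <- max(series) + bin_width  # right-open bins: top value lands inside
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(series, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
             count = counts)
}
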