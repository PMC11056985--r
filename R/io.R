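# Plain-text readers and writers for the package's interchange formats:
# HB-state matrices and scalar series as delimited text with unit-bearing
# headers, particle paths and coordinate frames as XYZ-like blocks, a
# minimal fixed-column PDB coordinate subset, and flat key:value configs.

#' Write an HB state matrix as delimited text
#'
#' Header comment lines record `dt` (ps) and `h_max`; columns are
#' `time_ps` followed by one 0/1 column per bond.
#'
#' @param states an [hb_state_matrix()].
#' @param path output file.
#' @export
write_hb_states <- function(states, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_ps=%.10g", states$dt),
               sprintf("# h_max=%d", states$h_max),
               "# units=boolean"), con)
  df <- data.frame(time_ps = (seq_len(nrow(states$states)) - 1) * states$dt,
                   states$states)
  names(df) <- c("time_ps", states$bond_labels)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read an HB state matrix written by [write_hb_states()]
#'
#' @param path input file.
#' @return an [hb_state_matrix()].
#' @export
read_hb_states <- function(path) {
  header <- readLines(path, n = 10)
  hdr <- grep("^#", header, value = TRUE)
  dt <- as.numeric(sub("^# dt_ps=", "", grep("^# dt_ps=", hdr, value = TRUE)))
  h_max <- as.integer(sub("^# h_max=", "",
                          grep("^# h_max=", hdr, value = TRUE)))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  hb_state_matrix(m, dt = dt,
                  bond_labels = names(df)[-1],
                  h_max = if (length(h_max)) h_max else NULL,
                  meta = list(source = path))
}

#' Write a scalar time series (e.g. end-to-end distances) as delimited text
#'
#' @param values numeric vector.
#' @param dt frame interval (ps).
#' @param path output file.
#' @param name column name for the observable (default `"value"`).
#' @param unit unit string recorded in the header.
#' @export
write_series <- function(values, dt, path, name = "value", unit = "nm") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_ps=%.10g", dt), sprintf("# unit=%s", unit)), con)
  df <- data.frame(time_ps = (seq_along(values) - 1) * dt, v = values)
  names(df) <- c("time_ps", name)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a scalar time series written by [write_series()]
#'
#' @param path input file.
#' @return numeric vector with attributes `dt` (ps) and `unit`.
#' @export
read_series <- function(path) {
  hdr <- grep("^#", readLines(path, n = 5), value = TRUE)
  dt <- as.numeric(sub("^# dt_ps=", "", grep("^# dt_ps=", hdr, value = TRUE)))
  unit <- sub("^# unit=", "", grep("^# unit=", hdr, value = TRUE))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- df[[2]]
  attr(out, "dt") <- dt
  attr(out, "unit") <- if (length(unit)) unit else NA_character_
  out
}

#' Write coordinate frames as XYZ-like blocks
#'
#' Each frame is a block: an atom-count line, a comment line carrying the
#' timestamp (`t= <ps>`), then one `LABEL x y z` line per atom with
#' coordinates in nm. Labels are `ROLE_resid` (e.g. `CA_3`).
#'
#' @param frames a [frame_series()] or `ParticlePaths` (particles become
#'   atoms labelled `P_i`).
#' @param path output file.
#' @export
write_xyz_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(frames, "ParticlePaths")) {
    np <- dim(frames$coords)[2]
    labels <- sprintf("P_%d", seq_len(np))
    times <- frames$times
    coords <- frames$coords
  } else {
    labels <- sprintf("%s_%d", frames$atoms$role, frames$atoms$residue)
    times <- frames$times
    coords <- frames$coords
  }
  for (i in seq_along(times)) {
    writeLines(c(sprintf("%d", length(labels)),
                 sprintf("t= %.10g", times[i])), con)
    m <- matrix(coords[i, , ], ncol = 3L)
    writeLines(sprintf("%s %.8f %.8f %.8f", labels, m[, 1], m[, 2], m[, 3]),
               con)
  }
}

#' Read XYZ-like frame blocks (coordinates in nm)
#'
#' @param path input file written in the layout of [write_xyz_frames()].
#' @return a [frame_series()]; labels of the form `ROLE_resid` become atom
#'   roles/residues, anything else becomes role `P` with a running index.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  times <- numeric(0)
  frames <- list()
  atoms <- NULL
  while (pos <= length(lines)) {
    n <- as.integer(lines[pos])
    tline <- lines[pos + 1L]
    t <- as.numeric(sub("^t=\\s*", "", tline))
    body <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    lab <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(atoms)) {
      has_us <- grepl("_", lab)
      role <- ifelse(has_us, sub("_.*$", "", lab), lab)
      resid <- ifelse(has_us, suppressWarnings(as.integer(sub("^.*_", "", lab))),
                      seq_along(lab))
      atoms <- data.frame(residue = resid, role = role,
                          stringsAsFactors = FALSE)
    }
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t)
    pos <- pos + 2L + n
  }
  coords <- array(0, dim = c(length(frames), nrow(atoms), 3L))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  frame_series(times, atoms, coords)
}

#' Read a minimal fixed-column PDB coordinate subset
#'
#' Parses `ATOM` records (atom name, residue sequence number, x, y, z) using
#' the fixed PDB columns; coordinates are converted from Angstrom to nm.
#' `MODEL`/`ENDMDL` blocks become successive frames (1 ps apart by
#' convention, or supply `times`). Atom names `CA`, `O`, `N` map to the
#' corresponding roles; other names are kept verbatim.
#'
#' @param path input PDB file.
#' @param times optional frame timestamps (ps).
#' @return a [frame_series()] with coordinates in nm.
#' @export
read_pdb_frames <- function(path, times = NULL) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  blocks <- if (length(model_starts) == 0) list(lines) else {
    ends <- grep("^ENDMDL", lines)
    mapply(function(s, e) lines[s:e], model_starts, ends, SIMPLIFY = FALSE)
  }
  atoms <- NULL
  frames <- list()
  for (blk in blocks) {
    rec <- grep("^ATOM", blk, value = TRUE)
    if (length(rec) == 0) next
    name <- trimws(substr(rec, 13, 16))
    resseq <- as.integer(substr(rec, 23, 26))
    x <- as.numeric(substr(rec, 31, 38))
    y <- as.numeric(substr(rec, 39, 46))
    z <- as.numeric(substr(rec, 47, 54))
    if (is.null(atoms))
      atoms <- data.frame(residue = resseq, role = name,
                          stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- cbind(x, y, z) / 10  # Angstrom -> nm
  }
  if (length(frames) == 0) stop("read_pdb_frames: no ATOM records found")
  if (is.null(times)) times <- seq_along(frames) - 1
  coords <- array(0, dim = c(length(frames), nrow(atoms), 3L))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  frame_series(times, atoms, coords)
}

#' Write a flat key:value configuration file
#'
#' @param config named list of scalars.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, function(v) format(v, digits = 15),
                            character(1))),
             path)
}

#' Read a flat key:value configuration file
#'
#' Values that parse as numbers become numeric; everything else stays
#' character.
#'
#' @param path input file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) next
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a free-energy surface as delimited text
#'
#' Two matrices (occupancy and free energy) with HB-level row headers and
#' distance-bin-edge metadata; energies are blank where undefined.
#'
#' @param surface a `FreeEnergySurface`.
#' @param path output file.
#' @export
write_surface <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# temperature_K=%.10g", surface$temperature),
               sprintf("# bin_width_nm=%.10g", surface$bin_width),
               paste0("# distance_edges_nm=",
                      paste(format(surface$breaks, digits = 10),
                            collapse = ","))), con)
  writeLines("# occupancy", con)
  write.table(surface$counts, con, sep = "\t", col.names = FALSE,
              row.names = rownames(surface$counts), quote = FALSE)
  writeLines("# free_energy_kJ_per_mol", con)
  g <- surface$free_energy
  write.table(g, con, sep = "\t", col.names = FALSE,
              row.names = rownames(g), quote = FALSE, na = "")
}
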