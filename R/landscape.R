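# Free-energy surfaces over (HB count, end-to-end distance) and the
# per-level histogram centers x_i whose squared steps feed the global
# friction coefficient.

#' Build a free-energy surface over (HB count, end-to-end distance)
#'
#' Bins the joint occupancy Omega of the HB level and the end-to-end
#' distance and converts it to `G = -RT ln(Omega)` (kJ/mol). Empty bins have
#' undefined free energy and are represented as `NA`, never 0. The raw
#' per-frame series are retained so histogram centers can be computed from
#' raw samples rather than bin midpoints.
#'
#' @param h_series integer vector of per-frame HB counts.
#' @param e2e_series numeric vector of per-frame end-to-end distances (nm).
#' @param bin_width distance bin width (nm), default 0.05.
#' @param temperature temperature (K), default 300.
#' @param h_max maximum HB level (default `max(h_series)`).
#' @param shift_min if TRUE (default), shift G so its minimum over occupied
#'   bins is zero.
#' @param store_raw keep the raw series in the object (default TRUE).
#' @return a `FreeEnergySurface`: list with `hb_levels`, `breaks` (nm),
#'   `counts` (levels x bins), `free_energy` (kJ/mol, NA where empty),
#'   `temperature`, and optionally `h_series`, `e2e_series`.
#' @export
build_surface <- function(h_series, e2e_series, bin_width = 0.05,
                          temperature = 300, h_max = NULL,
                          shift_min = TRUE, store_raw = TRUE) {
  if (length(h_series) == 0 || length(e2e_series) == 0)
    stop("build_surface: empty series")
  if (length(h_series) != length(e2e_series))
    stop("build_surface: series lengths differ")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("build_surface: 'bin_width' must be > 0")
  if (is.null(h_max)) h_max <- max(h_series)
  levels <- 0:h_max
  lo <- floor(min(e2e_series) / bin_width) * bin_width
  hi <- max(e2e_series) + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin_idx <- findInterval(e2e_series, breaks, rightmost.closed = FALSE)
  counts <- matrix(0, nrow = length(levels), ncol = length(breaks) - 1L,
                   dimnames = list(paste0("h", levels), NULL))
  tab <- table(factor(h_series, levels = levels),
               factor(bin_idx, levels = seq_len(length(breaks) - 1L)))
  counts[] <- as.numeric(tab)
  rt <- .GAS_CONSTANT_KJ_PER_MOL_K * temperature
  g <- -rt * log(counts)
  g[!is.finite(g)] <- NA_real_
  if (shift_min && any(!is.na(g))) g <- g - min(g, na.rm = TRUE)
  out <- list(hb_levels = levels, breaks = breaks, counts = counts,
              free_energy = g, temperature = temperature,
              bin_width = bin_width)
  if (store_raw) {
    out$h_series <- as.integer(h_series)
    out$e2e_series <- as.numeric(e2e_series)
  }
  structure(out, class = "FreeEnergySurface")
}

#' @export
print.FreeEnergySurface <- function(x, ...) {
  cat(sprintf(
    "FreeEnergySurface: %d HB levels x %d distance bins (%g nm, T = %g K)\n",
    length(x$hb_levels), ncol(x$counts), x$bin_width, x$temperature))
  cat(sprintf("  %d frames, occupied bins: %d\n",
              sum(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Per-level histogram centers and end-to-end step aggregate
#'
#' For each HB level i, computes the center of mass `x_i` of the end-to-end
#' distance distribution at that level (from the raw per-frame samples when
#' stored, removing any bin-width dependence; from count-weighted bin
#' midpoints otherwise). Steps `Dx_i = x_{i+1} - x_i` between consecutive
#' retained levels are accumulated as `sum(Dx_i^2)`, whose square root is
#' the reported aggregate Dx. Levels occupied by fewer than `min_count`
#' frames are excluded (their centers are unstable) and reported.
#'
#' @param surface a `FreeEnergySurface` from [build_surface()].
#' @param min_count occupancy floor per level (default 50 frames).
#' @return a `DeltaXResult`: list with `levels`, `x_centers` (nm),
#'   `delta_x_steps` (nm), `delta_x_sq_total` (nm^2), `delta_x_reported`
#'   (nm), `excluded_levels`.
#' @export
histogram_centers <- function(surface, min_count = 50) {
  if (!inherits(surface, "FreeEnergySurface"))
    stop("histogram_centers: 'surface' must be a FreeEnergySurface")
  levels <- surface$hb_levels
  n_per_level <- rowSums(surface$counts)
  usable <- which(n_per_level >= min_count)
  if (length(usable) < 2)
    stop("histogram_centers: no folding path (fewer than 2 usable levels)")
  if (!is.null(surface$e2e_series)) {
    x_centers <- vapply(levels[usable], function(lv) {
      mean(surface$e2e_series[surface$h_series == lv])
    }, numeric(1))
  } else {
    mids <- (surface$breaks[-length(surface$breaks)] + surface$breaks[-1]) / 2
    x_centers <- as.numeric(surface$counts[usable, , drop = FALSE] %*% mids) /
      n_per_level[usable]
  }
  steps <- diff(x_centers)
  structure(list(levels = levels[usable], x_centers = x_centers,
                 delta_x_steps = steps,
                 delta_x_sq_total = sum(steps^2),
                 delta_x_reported = sqrt(sum(steps^2)),
                 excluded_levels = levels[setdiff(seq_along(levels), usable)],
                 min_count = min_count),
            class = "DeltaXResult")
}

#' @export
print.DeltaXResult <- function(x, ...) {
  cat(sprintf(
    "DeltaXResult: %d levels, sum(Dx^2) = %.4g nm^2, Dx = %.4g nm\n",
    length(x$levels), x$delta_x_sq_total, x$delta_x_reported))
  if (length(x$excluded_levels))
    cat("  excluded levels (below occupancy floor):",
        paste(x$excluded_levels, collapse = ", "), "\n")
  invisible(x)
}
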