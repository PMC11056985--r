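# Tracer diffusion from mean square displacement, relative viscosity via
# the Stokes ratio of diffusion constants, and linear / power-law
# extrapolation of friction-vs-viscosity series to zero viscosity.

#' Ensemble- and time-origin-averaged mean square displacement
#'
#' `MSD(L) = < |r(t+L) - r(t)|^2 >` averaged over all particles and all
#' time origins t.
#'
#' @param paths a `ParticlePaths` from [simulate_brownian()] (or any list
#'   with `coords` of dim `(n_frames, n_particles, 3)` and `dt`).
#' @param lags integer vector of frame lags (default: every lag for short
#'   series, ~200 evenly spaced lags otherwise).
#' @return data.frame with columns `lag`, `time` (ps), `msd` (nm^2).
#' @export
msd_curve <- function(paths, lags = NULL) {
  coords <- paths$coords
  nf <- dim(coords)[1]
  if (is.null(lags)) {
    lags <- if (nf <= 256) seq_len(nf - 1L)
            else unique(round(seq(1, nf - 1L, length.out = 100)))
  }
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1 | lags >= nf))
    stop("msd_curve: lags must lie in [1, n_frames - 1]")
  np <- dim(coords)[2]
  axes <- lapply(1:3, function(ax) {
    m <- coords[, , ax, drop = FALSE]
    dim(m) <- c(nf, np)
    m
  })
  msd <- vapply(lags, function(L) {
    tot <- 0
    for (m in axes) {
      dmat <- m[(1L + L):nf, , drop = FALSE] - m[1:(nf - L), , drop = FALSE]
      tot <- tot + sum(dmat * dmat)
    }
    tot / ((nf - L) * np)
  }, numeric(1))
  data.frame(lag = lags, time = lags * paths$dt, msd = msd)
}

#' Diffusion constant from the MSD slope
#'
#' Fits `MSD = 6 D t + b` over a time window excluding the short-time
#' nonlinear domain (default window: 10% to 50% of the analysed span) and
#' returns `D = slope / 6`. Optional chunking splits the trajectory into
#' equal chunks whose MSD curves are averaged before fitting, mirroring the
#' usual practice for long trajectories. Diagnostics flag a vanishing MSD
#' and curvature (relative quadratic contribution) indicating non-diffusive
#' motion.
#'
#' @param paths a `ParticlePaths`.
#' @param fit_window numeric length-2 time range (ps); default
#'   `c(0.1, 0.5) * span`.
#' @param lags optional frame lags passed to [msd_curve()].
#' @param chunk_frames optional chunk length in frames.
#' @return list with `d` (cm^2/s), `slope` (nm^2/ps), `intercept`,
#'   `diagnostics` (list: `r_squared`, `curvature`, `curvature_flag`,
#'   `zero_msd`), `fit_window`, `curve`.
#' @export
msd_diffusion <- function(paths, fit_window = NULL, lags = NULL,
                          chunk_frames = NULL) {
  coords <- paths$coords
  nf <- dim(coords)[1]
  if (!is.null(chunk_frames) && chunk_frames < nf) {
    n_chunks <- nf %/% chunk_frames
    if (is.null(lags) && chunk_frames > 256) {
      # default window tops out at 50% of the chunk span; don't waste
      # effort on longer lags
      lags <- unique(round(seq(1, floor(0.55 * chunk_frames),
                               length.out = 60)))
    }
    curves <- lapply(seq_len(n_chunks), function(ci) {
      sub <- paths
      rows <- ((ci - 1L) * chunk_frames + 1L):(ci * chunk_frames)
      sub$coords <- coords[rows, , , drop = FALSE]
      msd_curve(sub, lags = lags)
    })
    curve <- curves[[1]]
    curve$msd <- Reduce(`+`, lapply(curves, `[[`, "msd")) / n_chunks
  } else {
    curve <- msd_curve(paths, lags = lags)
  }
  span <- max(curve$time)
  if (is.null(fit_window)) fit_window <- c(0.1, 0.5) * span
  sel <- curve$time >= fit_window[1] & curve$time <= fit_window[2]
  if (sum(sel) < 3)
    stop("msd_diffusion: fit window too short (< 3 points)")
  tt <- curve$time[sel]; yy <- curve$msd[sel]
  if (all(yy == 0)) {
    return(list(d = 0, slope = 0, intercept = 0,
                diagnostics = list(r_squared = NA_real_,
                                   curvature = NA_real_,
                                   curvature_flag = FALSE, zero_msd = TRUE),
                fit_window = fit_window, curve = curve))
  }
  fit <- lm(yy ~ tt)
  slope <- coef(fit)[[2]]
  r2 <- summary(fit)$r.squared
  qfit <- lm(yy ~ tt + I(tt^2))
  quad <- coef(qfit)[[3]]
  # relative quadratic contribution across the window
  curvature <- abs(quad) * diff(range(tt))^2 / max(abs(slope) * diff(range(tt)),
                                                   .Machine$double.eps)
  list(d = max(slope, 0) / 6 * 1e-2,  # nm^2/ps -> cm^2/s
       slope = slope, intercept = coef(fit)[[1]],
       diagnostics = list(r_squared = r2, curvature = curvature,
                          curvature_flag = curvature > 0.1,
                          zero_msd = FALSE),
       fit_window = fit_window, curve = curve)
}

#' Relative viscosity from water diffusion constants
#'
#' Stokes-type inverse proportionality: `eta/eta0 = D_w0 / D_w`, with the
#' pure-water TIP3P reference `D_w0 = 5.6635e-5 cm^2/s` by default. Any
#' re-simulation should supply its own reference.
#'
#' @param d_w measured diffusion constant (cm^2/s), > 0.
#' @param d_w0_ref pure-water reference diffusion constant (cm^2/s).
#' @return relative viscosity eta/eta0.
#' @export
relative_viscosity <- function(d_w, d_w0_ref = 5.6635e-5) {
  if (!is.numeric(d_w) || any(d_w <= 0))
    stop("relative_viscosity: 'd_w' must be > 0")
  if (!is.numeric(d_w0_ref) || d_w0_ref <= 0)
    stop("relative_viscosity: 'd_w0_ref' must be > 0")
  d_w0_ref / d_w
}

#' Fit friction vs relative viscosity
#'
#' Linear model `gamma = a * (eta/eta0) + gamma0` (the intercept `gamma0`
#' is the internal friction, the value extrapolated to zero viscosity), or
#' power law `gamma = gamma_w * (eta/eta0)^beta` (`gamma_w` is the
#' friction at pure-water viscosity; `beta < 1` indicates sub-linear
#' viscosity coupling). The power fit is done in log-log space by linear
#' least squares, followed by a nonlinear refinement in linear space.
#'
#' @param points data.frame with columns `eta` (relative viscosity) and
#'   `gamma` (friction, any consistent unit).
#' @param model `"linear"` or `"power"`.
#' @param refine for the power model, refine the log-log estimate by
#'   nonlinear least squares (default TRUE).
#' @return a `ViscosityFit`: for linear, `a` and `gamma0`; for power,
#'   `gamma_w` and `beta`; both with `residuals` and `model`.
#' @export
fit_friction_vs_viscosity <- function(points, model = c("linear", "power"),
                                      refine = TRUE) {
  model <- match.arg(model)
  if (!all(c("eta", "gamma") %in% names(points)))
    stop("fit_friction_vs_viscosity: 'points' needs columns eta and gamma")
  pts <- points[order(points$eta), , drop = FALSE]
  if (nrow(pts) < 2)
    stop("fit_friction_vs_viscosity: need at least 2 points")
  if (model == "linear") {
    fit <- lm(gamma ~ eta, data = pts)
    out <- list(model = "linear", a = coef(fit)[[2]],
                gamma0 = coef(fit)[[1]], residuals = resid(fit))
  } else {
    if (any(pts$gamma <= 0) || any(pts$eta <= 0))
      stop("fit_friction_vs_viscosity: power model needs positive data")
    llfit <- lm(log(gamma) ~ log(eta), data = pts)
    gamma_w <- exp(coef(llfit)[[1]]); beta <- coef(llfit)[[2]]
    if (refine) {
      obj <- function(p) sum((pts$gamma - exp(p[1]) * pts$eta^p[2])^2)
      r <- tryCatch(optim(c(log(gamma_w), beta), obj, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-15)),
                    error = function(e) NULL)
      if (!is.null(r) && is.finite(r$value)) {
        gamma_w <- exp(r$par[1]); beta <- r$par[2]
      }
    }
    out <- list(model = "power", gamma_w = gamma_w, beta = beta,
                residuals = pts$gamma - gamma_w * pts$eta^beta)
  }
  structure(out, class = "ViscosityFit")
}

#' @export
print.ViscosityFit <- function(x, ...) {
  if (x$model == "linear")
    cat(sprintf("linear fit: gamma = %.4g * eta + %.4g (gamma0 = internal friction)\n",
                x$a, x$gamma0))
  else
    cat(sprintf("power fit: gamma = %.4g * eta^%.4g\n", x$gamma_w, x$beta))
  invisible(x)
}

#' Normalize a friction series by its value at relative viscosity one
#'
#' Divides all friction values by gamma(eta/eta0 = 1), taken from an exact
#' point when present (within `tol`) or linearly interpolated otherwise.
#' Normalization preserves the power-law exponent beta.
#'
#' @param points data.frame with columns `eta`, `gamma`.
#' @param tol tolerance for finding the eta = 1 point (default 1e-8).
#' @return the same data.frame with `gamma` normalized.
#' @export
normalize_series <- function(points, tol = 1e-8) {
  if (!all(c("eta", "gamma") %in% names(points)))
    stop("normalize_series: 'points' needs columns eta and gamma")
  hit <- which(abs(points$eta - 1) <= tol)
  ref <- if (length(hit) > 0) {
    mean(points$gamma[hit])
  } else {
    if (min(points$eta) > 1 || max(points$eta) < 1)
      stop("normalize_series: no reference point at eta = 1 ",
           "(and 1 is outside the data range)")
    approx(points$eta, points$gamma, xout = 1)$y
  }
  if (!is.finite(ref) || ref == 0)
    stop("normalize_series: reference friction at eta = 1 is degenerate")
  out <- points
  out$gamma <- points$gamma / ref
  out
}
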