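# Dwell-time analysis: maximal constant runs of a binary HB signal,
# censoring-aware, with log-binned histograms and exponential-mixture fits
# of the histogram generating function. The resulting ensemble dwell time
# tau feeds the local friction coefficient.

#' Extract dwell times from HB state data
#'
#' Segments the chosen binary signal into maximal constant runs. The first
#' and last runs of each signal are excluded as censored (their durations
#' are only lower bounds). Modes:
#' \describe{
#'   \item{`per_bond_formed`}{lifetimes of each bond's formed state, pooled
#'     over all bonds (default).}
#'   \item{`per_bond_broken`}{lifetimes of the broken state, pooled.}
#'   \item{`total_h_constant`}{runs over which the total HB count stays
#'     constant, i.e. waiting times between changes of h.}
#' }
#'
#' @param states an [hb_state_matrix()] (>= 2 frames).
#' @param mode extraction mode, see above.
#' @return a `DwellSet`: list with `durations` (ps, = run length x dt),
#'   `mode`, `censored_count`, `dt`.
#' @export
extract_dwells <- function(states,
                           mode = c("per_bond_formed", "per_bond_broken",
                                    "total_h_constant")) {
  mode <- match.arg(mode)
  if (!inherits(states, "HBStateMatrix"))
    stop("extract_dwells: 'states' must be an HBStateMatrix")
  if (nrow(states$states) < 2)
    stop("extract_dwells: need at least 2 frames")
  dt <- states$dt
  durations <- numeric(0)
  censored <- 0L
  signals <- if (mode == "total_h_constant") list(states$h_series)
             else lapply(seq_len(ncol(states$states)),
                         function(b) states$states[, b])
  target <- switch(mode, per_bond_formed = 1L, per_bond_broken = 0L,
                   total_h_constant = NA_integer_)
  for (sig in signals) {
    r <- rle(sig)
    nr <- length(r$lengths)
    if (nr < 3) {  # no interior (completed) runs
      if (is.na(target)) censored <- censored + nr
      else censored <- censored + sum(r$values[unique(c(1L, nr))] == target)
      next
    }
    keep <- 2:(nr - 1L)
    if (is.na(target)) {
      durations <- c(durations, r$lengths[keep] * dt)
      censored <- censored + 2L
    } else {
      sel <- keep[r$values[keep] == target]
      durations <- c(durations, r$lengths[sel] * dt)
      censored <- censored + sum(r$values[c(1L, nr)] == target)
    }
  }
  if (length(durations) == 0)
    stop("extract_dwells: insufficient transitions (no completed dwells)")
  structure(list(durations = durations, mode = mode,
                 censored_count = censored, dt = dt),
            class = "DwellSet")
}

#' @export
print.DwellSet <- function(x, ...) {
  cat(sprintf("DwellSet (%s): %d dwells, mean %.3g ps (%d censored excluded)\n",
              x$mode, length(x$durations), mean(x$durations),
              x$censored_count))
  invisible(x)
}

#' Logarithmic dwell-time histogram
#'
#' Bin edges uniform in log10(t); counts conserve the total dwell count.
#'
#' @param dwells a `DwellSet` from [extract_dwells()], or a numeric vector
#'   of durations.
#' @param bins_per_decade number of bins per decade (default 10).
#' @return a `DwellLogHistogram`: list with `breaks` (log10 ps), `mids`
#'   (log10 ps), `t_mids` (ps), `counts`, `total`, `bins_per_decade`.
#' @export
log_histogram <- function(dwells, bins_per_decade = 10) {
  durations <- if (inherits(dwells, "DwellSet")) dwells$durations
               else as.numeric(dwells)
  if (length(durations) < 1) stop("log_histogram: no durations")
  if (!is.numeric(bins_per_decade) || bins_per_decade <= 0)
    stop("log_histogram: 'bins_per_decade' must be > 0")
  x <- log10(durations)
  w <- 1 / bins_per_decade
  lo <- floor(min(x) / w) * w
  hi <- (floor(max(x) / w) + 1) * w
  breaks <- seq(lo, hi, by = w)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  structure(list(breaks = breaks, mids = mids, t_mids = 10^mids,
                 counts = counts, total = length(durations),
                 bins_per_decade = bins_per_decade),
            class = "DwellLogHistogram")
}

# Expected counts of the log-domain generating function for an exponential
# mixture: n(x) = N * dx * ln(10) * sum_j w_j (t/tau_j) exp(-t/tau_j),
# t = 10^x. amps are the products N*dx*ln10*w_j.
.mixture_expected <- function(t, amps, taus) {
  out <- numeric(length(t))
  for (j in seq_along(amps))
    out <- out + amps[j] * (t / taus[j]) * exp(-t / taus[j])
  out
}

#' Fit an exponential mixture to a logarithmic dwell histogram
#'
#' Least-squares fit of the log-domain generating function
#' `n(x) = W * sum_j A_j (t/tau_j) exp(-t/tau_j)` at `t = 10^x`, where `W`
#' absorbs the total count and bin width. For exponential dwell times this
#' density peaks at `t = tau`, which is what makes the log-binned
#' representation convenient. Components are returned sorted by `tau`;
#' zero-count bins enter the fit with weight 1. A two-component fit that
#' does not converge or degenerates (`tau2/tau1 < 1.2`, or a vanishing
#' weight) falls back to one component with `fallback = TRUE` and a warning.
#'
#' @param hist a `DwellLogHistogram` from [log_histogram()].
#' @param n_components 1 or 2.
#' @param method `"ls"` (least squares on counts, default) or `"poisson"`
#'   (maximum likelihood).
#' @return an `ExpMixFit`: list with `components` (data.frame `weight`,
#'   `tau`), `mean_tau` (amplitude-weighted), `n_components`, `fallback`,
#'   `goodness` (sse, rmse).
#' @export
fit_exponential_mixture <- function(hist, n_components = 2,
                                    method = c("ls", "poisson")) {
  method <- match.arg(method)
  if (!inherits(hist, "DwellLogHistogram"))
    stop("fit_exponential_mixture: 'hist' must come from log_histogram()")
  if (!n_components %in% c(1, 2))
    stop("fit_exponential_mixture: 'n_components' must be 1 or 2")
  n_par <- 2L * n_components
  if (sum(hist$counts > 0) < n_par && n_components == 2)
    return(fit_exponential_mixture(hist, 1, method))
  if (sum(hist$counts > 0) < 2)
    stop("fit_exponential_mixture: too few occupied bins")

  t <- hist$t_mids
  y <- hist$counts
  scale0 <- hist$total * log(10) / hist$bins_per_decade
  tau_bar <- sum(t * y) / sum(y)  # crude mean of the distribution

  objective <- function(p) {
    k <- length(p) / 2
    amps <- exp(p[seq_len(k)]); taus <- exp(p[k + seq_len(k)])
    mu <- .mixture_expected(t, amps, taus)
    if (method == "ls") sum((y - mu)^2)
    else {
      mu <- pmax(mu, 1e-12)
      sum(mu - y * log(mu))
    }
  }
  run_fit <- function(p0) {
    r1 <- optim(p0, objective, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-13))
    r2 <- tryCatch(optim(r1$par, objective, method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-15)),
                   error = function(e) r1)
    if (r2$value <= r1$value) r2 else r1
  }

  starts <- if (n_components == 1) {
    list(c(log(scale0), log(tau_bar)),
         c(log(scale0), log(max(tau_bar / 3, hist$t_mids[1]))))
  } else {
    list(c(log(scale0 * 0.5), log(scale0 * 0.5),
           log(tau_bar / 4), log(tau_bar * 2)),
         c(log(scale0 * 0.7), log(scale0 * 0.3),
           log(tau_bar / 10), log(tau_bar * 4)),
         c(log(scale0 * 0.5), log(scale0 * 0.5),
           log(tau_bar / 2), log(tau_bar)))
  }
  fits <- lapply(starts, run_fit)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  k <- n_components
  amps <- exp(best$par[seq_len(k)])
  taus <- exp(best$par[k + seq_len(k)])
  weights <- amps / sum(amps)
  degenerate <- FALSE
  if (k == 2) {
    ratio <- max(taus) / min(taus)
    degenerate <- !is.finite(best$value) || ratio < 1.2 ||
      any(weights < 1e-3)
  }
  if (degenerate) {
    warning("fit_exponential_mixture: two-component fit degenerate; ",
            "falling back to one component")
    out <- fit_exponential_mixture(hist, 1, method)
    out$fallback <- TRUE
    return(out)
  }
  ord <- order(taus)
  comps <- data.frame(weight = weights[ord], tau = taus[ord])
  mu <- .mixture_expected(t, amps, taus)
  sse <- sum((y - mu)^2)
  structure(list(components = comps,
                 mean_tau = sum(comps$weight * comps$tau),
                 n_components = k, fallback = FALSE,
                 goodness = list(sse = sse,
                                 rmse = sqrt(sse / length(y)),
                                 objective = best$value, method = method)),
            class = "ExpMixFit")
}

#' @export
print.ExpMixFit <- function(x, ...) {
  cat(sprintf("ExpMixFit: %d component(s), mean tau = %.4g ps%s\n",
              x$n_components, x$mean_tau,
              if (x$fallback) " [fallback]" else ""))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Ensemble dwell time from an exponential-mixture fit
#'
#' Combines the fitted component time constants into the single ensemble
#' dwell time tau feeding the local friction coefficient.
#'
#' @param fit an `ExpMixFit`.
#' @param rule `"amplitude"` (amplitude-weighted mean, default), `"slow"`
#'   (largest tau) or `"fast"` (smallest tau).
#' @return tau in ps.
#' @export
ensemble_dwell_time <- function(fit, rule = c("amplitude", "slow", "fast")) {
  rule <- match.arg(rule)
  if (!inherits(fit, "ExpMixFit"))
    stop("ensemble_dwell_time: 'fit' must be an ExpMixFit")
  switch(rule,
         amplitude = sum(fit$components$weight * fit$components$tau),
         slow = max(fit$components$tau),
         fast = min(fit$components$tau))
}
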