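# Two-state folding kinetics from the total-HB time series: autocorrelation,
# relaxation time, and the closure k_fold + k_unfold = 1/tau_f with
# K = f/(1-f). The closure is the standard two-state identity; it is
# validated against internal consistency of published rate/K tables (see the
# methods vignette).

#' Autocorrelation function of a scalar series
#'
#' `C(lag) = <dh(t) dh(t+lag)> / <dh^2>` with `dh = h - mean(h)`. The
#' numerator is averaged over the `N - lag` available products and the
#' denominator is the `1/N` variance, so `C(0) = 1` exactly. A biased
#' (`1/N` numerator) convention is available; the difference is immaterial
#' for `N >> max_lag`.
#'
#' @param series numeric vector.
#' @param max_lag maximum lag (frames), < `length(series)`.
#' @param method `"fft"` (default, O(N log N)) or `"direct"`.
#' @param normalization `"per-lag"` (default) or `"biased"`.
#' @return numeric vector of length `max_lag + 1`, lags 0..max_lag.
#' @export
autocorrelation <- function(series, max_lag,
                            method = c("fft", "direct"),
                            normalization = c("per-lag", "biased")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  n <- length(series)
  if (max_lag >= n)
    stop("autocorrelation: 'max_lag' must be < length(series)")
  d <- series - mean(series)
  ss <- sum(d^2)
  if (ss == 0) stop("autocorrelation: degenerate series (zero variance)")
  lags <- 0:max_lag
  if (method == "fft") {
    m <- nextn(2L * n)
    f <- fft(c(d, rep(0, m - n)))
    raw <- Re(fft(Mod(f)^2, inverse = TRUE))[lags + 1L] / m
  } else {
    raw <- vapply(lags, function(k) sum(d[seq_len(n - k)] * d[(k + 1):n]),
                  numeric(1))
  }
  denom <- ss / n
  if (normalization == "per-lag") raw / (n - lags) / denom
  else raw / n / denom
}

#' Fit a relaxation time to an autocorrelation function
#'
#' Least-squares fit of `C(t) = A * exp(-t / tau) + c`. By default the fit
#' window runs from lag 0 up to the first crossing of `C = 0.05` (long-lag
#' noise dominates otherwise) and the constant offset is kept only when it
#' improves AICc.
#'
#' @param acf_values output of [autocorrelation()] (lags 0..L).
#' @param dt frame interval (ps, or any time unit; `tau` is returned in the
#'   same unit).
#' @param constant `"auto"` (AICc selection, default), `"include"` or
#'   `"omit"`.
#' @param window_threshold fit window cut: lags up to the first crossing of
#'   this ACF value (default 0.05). Set to `-Inf` to use all lags.
#' @return list with `tau`, `A`, `c`, `model`, `sse`, `aicc`, `n_points`,
#'   `converged`.
#' @export
fit_relaxation <- function(acf_values, dt,
                           constant = c("auto", "include", "omit"),
                           window_threshold = 0.05) {
  constant <- match.arg(constant)
  cross <- which(acf_values < window_threshold)
  n_use <- if (length(cross) > 0) max(cross[1], 3L) else length(acf_values)
  if (n_use < 3) stop("fit_relaxation: need at least 3 lag points")
  y <- acf_values[seq_len(n_use)]
  t <- (seq_len(n_use) - 1) * dt

  fit_one <- function(with_c) {
    c0 <- if (with_c) max(0, min(y)) else 0
    pos <- which(y - c0 > 1e-12)
    tau0 <- if (length(pos) >= 2) {
      sl <- coef(lm(log(y[pos] - c0) ~ t[pos]))[2]
      if (is.finite(sl) && sl < 0) -1 / sl else max(t[n_use] / 3, dt)
    } else max(t[n_use] / 3, dt)
    a0 <- max(y[1] - c0, 1e-6)
    obj <- if (with_c) {
      function(p) sum((y - (p[2] * exp(-t / exp(p[1])) + p[3]))^2)
    } else {
      function(p) sum((y - p[2] * exp(-t / exp(p[1])))^2)
    }
    p0 <- if (with_c) c(log(tau0), a0, c0) else c(log(tau0), a0)
    r1 <- optim(p0, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
    r2 <- tryCatch(optim(r1$par, obj, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-15)),
                   error = function(e) r1)
    best <- if (r2$value <= r1$value) r2 else r1
    k <- length(p0) + 1  # + residual variance
    n <- n_use
    sse <- best$value
    aicc <- n * log(max(sse / n, 1e-300)) + 2 * k +
      2 * k * (k + 1) / max(n - k - 1, 1)
    list(tau = unname(exp(best$par[1])), A = unname(best$par[2]),
         c = if (with_c) unname(best$par[3]) else 0,
         sse = sse, aicc = aicc,
         converged = is.finite(sse))
  }

  res <- switch(constant,
    include = c(fit_one(TRUE), list(model = "exp_plus_constant")),
    omit = c(fit_one(FALSE), list(model = "exp")),
    auto = {
      f0 <- fit_one(FALSE); f1 <- fit_one(TRUE)
      if (f1$aicc < f0$aicc) c(f1, list(model = "exp_plus_constant"))
      else c(f0, list(model = "exp"))
    })
  if (!res$converged || !is.finite(res$tau) || res$tau <= 0)
    stop(sprintf(
      "fit_relaxation: did not converge (sse = %g, tau = %g, n = %d)",
      res$sse, res$tau, n_use))
  res$n_points <- n_use
  res
}

#' Rates and equilibrium constant from relaxation time and folded fraction
#'
#' Two-state closure: `k_fold + k_unfold = 1/tau_f` and
#' `K = k_fold/k_unfold = f/(1-f)`, giving `k_fold = f/tau_f` and
#' `k_unfold = (1-f)/tau_f`. Errors, when supplied, are propagated with the
#' complete-differential (maximum error) rule.
#'
#' @param tau_f relaxation time (us).
#' @param f folded fraction, strictly inside (0, 1).
#' @param tau_err,f_err optional absolute uncertainties.
#' @return a `RateEstimate`: list with `tau_f`, `f`, `k_fold`, `k_unfold`,
#'   `K` (rates in 1/us) and `_err` companions.
#' @export
rates_from_relaxation <- function(tau_f, f, tau_err = 0, f_err = 0) {
  if (!is.numeric(tau_f) || tau_f <= 0)
    stop("rates_from_relaxation: 'tau_f' must be > 0")
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("rates_from_relaxation: no transitions (f must be inside (0, 1))")
  tau_f <- unname(tau_f); f <- unname(f)
  k_fold <- f / tau_f
  k_unfold <- (1 - f) / tau_f
  K <- f / (1 - f)
  k_fold_err <- k_fold * (f_err / f + tau_err / tau_f)
  k_unfold_err <- k_unfold * (f_err / (1 - f) + tau_err / tau_f)
  K_err <- if (k_fold_err > 0 || k_unfold_err > 0)
    propagate_K_error(K, k_fold, k_fold_err, k_unfold, k_unfold_err) else 0
  structure(list(tau_f = tau_f, f = f, k_fold = k_fold, k_unfold = k_unfold,
                 K = K, tau_f_err = tau_err, f_err = f_err,
                 k_fold_err = k_fold_err, k_unfold_err = k_unfold_err,
                 K_err = K_err),
            class = "RateEstimate")
}

#' Maximum error of the equilibrium constant (complete-differential rule)
#'
#' `dK = K * (dk_fold/k_fold + dk_unfold/k_unfold)`.
#'
#' @param K equilibrium constant.
#' @param k_fold,k_unfold rates (> 0, any common unit).
#' @param dk_fold,dk_unfold absolute rate uncertainties (>= 0).
#' @return absolute uncertainty of K.
#' @export
propagate_K_error <- function(K, k_fold, dk_fold, k_unfold, dk_unfold) {
  if (k_fold <= 0 || k_unfold <= 0)
    stop("propagate_K_error: rates must be positive")
  if (dk_fold < 0 || dk_unfold < 0)
    stop("propagate_K_error: uncertainties must be >= 0")
  K * (dk_fold / k_fold + dk_unfold / k_unfold)
}
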