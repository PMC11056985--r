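# Friction coefficients. Local: Einstein relation gamma = kB*T/D with
# D = delta^2/(2*tau), where delta is the helix elongation per HB (0.15 nm,
# the rise per residue) and tau the ensemble HB dwell time. Global:
# gamma_G = kB*T / (k_fold * sum_i Dx_i^2), built from the end-to-end
# displacement increments accumulated while gaining HBs and the folding
# rate. The global closed form is a reconstruction validated against
# published tables; see the methods vignette.

.NG_PER_S <- 1e-12  # 1 ng/s in kg/s
.UG_PER_S <- 1e-9   # 1 ug/s in kg/s

new_friction_value <- function(value, error, kind, scale_hint, provenance) {
  if (value < 0 || error < 0)
    stop("FrictionValue: value and error must be >= 0")
  structure(list(value = value, error = error, kind = kind,
                 scale_hint = scale_hint, provenance = provenance),
            class = "FrictionValue")
}

#' @export
print.FrictionValue <- function(x, ...) {
  unit <- x$scale_hint
  fac <- if (unit == "ng/s") .NG_PER_S else .UG_PER_S
  cat(sprintf("%s friction: %.3g +/- %.2g %s\n", x$kind, x$value / fac,
              x$error / fac, unit))
  invisible(x)
}

#' Friction value in a reporting unit
#'
#' @param x a `FrictionValue`.
#' @param unit `"ng/s"`, `"ug/s"` or `"kg/s"`.
#' @return numeric value in the requested unit.
#' @export
friction_in <- function(x, unit = c("ng/s", "ug/s", "kg/s")) {
  unit <- match.arg(unit)
  x$value / switch(unit, "ng/s" = .NG_PER_S, "ug/s" = .UG_PER_S, "kg/s" = 1)
}

#' Local friction coefficient from the ensemble HB dwell time
#'
#' Einstein relation for the 1-D Brownian elongation/shortening of a helix
#' by one hydrogen bond: `D = delta^2 / (2 tau)` and `gamma = kB T / D`,
#' i.e. `gamma = 2 kB T tau / delta^2`. The uncertainty is propagated
#' linearly from `tau_err`.
#'
#' @param tau ensemble dwell time (ps), > 0.
#' @param consts a [physical_constants()] (delta in nm, temperature in K).
#' @param tau_err absolute uncertainty of tau (ps).
#' @return a `FrictionValue` in kg/s (reporting hint ng/s).
#' @export
local_friction <- function(tau, consts = physical_constants(), tau_err = 0) {
  if (!is.numeric(tau) || tau <= 0)
    stop("local_friction: 'tau' must be > 0")
  delta_m <- consts$delta * 1e-9
  tau_s <- tau * 1e-12
  d <- delta_m^2 / (2 * tau_s)                 # m^2/s
  gamma <- consts$kB * consts$temperature / d  # kg/s
  new_friction_value(gamma, gamma * tau_err / tau, "local", "ng/s",
                     list(tau_ps = tau, delta_nm = consts$delta,
                          temperature_K = consts$temperature))
}

#' Conversion factor between the two delta conventions
#'
#' `(delta_alt / delta)^2`, rounded to 3 significant figures for reporting.
#' With the defaults (0.34 nm vs 0.15 nm) this is 5.14: dividing a local
#' friction computed with the helix-rise delta by this factor gives the
#' value under the alternative convention.
#'
#' @param consts a [physical_constants()].
#' @return dimensionless factor (3 significant figures).
#' @export
delta_conversion_factor <- function(consts = physical_constants()) {
  signif((consts$delta_alt / consts$delta)^2, 3)
}

#' Global friction coefficient from the folding rate and end-to-end steps
#'
#' `gamma_G = kB T / (k_fold * sum_i Dx_i^2)`: the energy dissipated over
#' the sequence of end-to-end displacement increments accumulated while
#' gaining HBs, per unit folding rate. Uncertainty follows the
#' complete-differential rule from the rate and step-aggregate errors.
#'
#' @param k_fold folding rate (1/us), > 0.
#' @param delta_x_sq_total `sum_i Dx_i^2` (nm^2), > 0; e.g.
#'   `histogram_centers(...)$delta_x_sq_total`.
#' @param consts a [physical_constants()].
#' @param k_err,dxsq_err absolute uncertainties of the inputs.
#' @return a `FrictionValue` in kg/s (reporting hint ug/s).
#' @export
global_friction <- function(k_fold, delta_x_sq_total,
                            consts = physical_constants(),
                            k_err = 0, dxsq_err = 0) {
  if (!is.numeric(k_fold) || k_fold <= 0)
    stop("global_friction: 'k_fold' must be > 0")
  if (!is.numeric(delta_x_sq_total) || delta_x_sq_total <= 0)
    stop("global_friction: 'delta_x_sq_total' must be > 0")
  k_si <- k_fold * 1e6                    # 1/s
  dx2_si <- delta_x_sq_total * 1e-18      # m^2
  gamma <- consts$kB * consts$temperature / (k_si * dx2_si)
  err <- gamma * (k_err / k_fold +
                    dxsq_err / delta_x_sq_total)
  new_friction_value(gamma, err, "global", "ug/s",
                     list(k_fold_per_us = k_fold,
                          delta_x_sq_nm2 = delta_x_sq_total,
                          temperature_K = consts$temperature))
}
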