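---
title: "Models and methods behind helixfriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind helixfriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`helixfriction` estimates local and global internal friction of α-helical
peptides from hydrogen-bond (HB) time series and end-to-end distances.
This vignette documents the models, the tunable parameters and their
defaults, the synthetic-data generator and its limits, the numerical
choices, and the design decisions that were genuinely open.

## Two-state folding kinetics

Folding is treated as a two-state reaction between an unfolded and a
folded (helical) ensemble. The folded fraction is measured from the HB
time series as $f = \langle h_i \rangle / h_\mathrm{max}$, where $h_i$
counts the formed helical $(i, i{+}4)$ hydrogen bonds in frame $i$ and
$h_\mathrm{max}$ is the topology maximum (`n_residues - 4` unless
capping-group donors/acceptors are declared explicitly). A bond is formed
when the carbonyl-O to amide-N distance is *strictly below* the cutoff
(default 0.36 nm); the strict inequality is deliberate, matching the
"below the cutoff" convention, and only matters on sets of measure zero.

The relaxation time $\tau_f$ comes from the autocorrelation function of
$h_i$, fitted with $C(t) = A e^{-t/\tau_f} + c$. The closure
$k_\mathrm{fold} + k_\mathrm{unfold} = 1/\tau_f$ together with
$K = k_\mathrm{fold}/k_\mathrm{unfold} = f/(1-f)$ yields
$k_\mathrm{fold} = f/\tau_f$ and $k_\mathrm{unfold} = (1-f)/\tau_f$.
This is the standard two-state identity; it reproduces published
rate/equilibrium tables from their own columns to within the rounding of
three significant figures (see `test-acceptance.R`). Uncertainties follow
the complete-differential (maximum-error) rule
$\Delta K = K\,(\Delta k_f/k_f + \Delta k_u/k_u)$.

**ACF conventions.** The numerator of $C(\ell)$ is averaged over the
$N-\ell$ available lag products and the denominator is the $1/N$
variance, so that $C(0) = 1$ exactly and the tiny-series worked example
$[0,1,0,1] \mapsto C(1) = -1$ holds. A biased ($1/N$) numerator is
available as an option; for the $N \gg \ell$ regimes this package targets
the two are indistinguishable, but the per-lag convention is the one the
examples pin down. The FFT and direct-sum paths agree to $10^{-10}$ and
both are tested against an independent oracle.

**Fit window and offset.** Long-lag ACF noise is severe (its magnitude
does not shrink with the number of bonds, only with trajectory length),
so the fit window runs from lag 0 to the first crossing of $C = 0.05$ by
default. The constant offset $c$ is kept only when it improves AICc
("plus a constant, if needed").

## Dwell times and local friction

Local friction attaches to single-HB formation/rupture. Dwell times are
maximal constant runs of a binary signal; the first and last runs of each
signal are *censored* (their true durations are only bounded from below)
and excluded, standard single-molecule practice. Two segmentations are
provided because the field's usage is genuinely ambiguous: lifetimes of
each bond's formed (or broken) state pooled over bonds
(`per_bond_formed`, the default — "lifetimes of the single HBs"), and
runs of constant total HB count (`total_h_constant` — "time needed to
change the number of HBs"). Neither is asserted to be the published
choice; both are first-class and tested.

Durations are histogrammed with bins uniform in $\log_{10} t$ (default
10 bins per decade). For an exponential mixture the expected count in a
log bin of width $\Delta x$ is
$n(x) = N \Delta x \ln 10 \sum_j w_j \frac{t}{\tau_j} e^{-t/\tau_j}$ at
$t = 10^x$ — the log-domain density peaks at $t = \tau$, which is what
makes the representation readable. The mixture (1 or 2 components) is
fitted by least squares on counts (Poisson likelihood available);
zero-count bins enter with weight 1 — a deterministic, simple choice.
A two-component fit that degenerates ($\tau_2/\tau_1 < 1.2$ or a
vanishing amplitude) falls back to one component with a warning, because
such fits are not identifiable. The ensemble dwell time is the
amplitude-weighted mean $\sum_j w_j \tau_j$ by default (the published
tables report a single τ per condition without stating the combination;
`slow` and `fast` alternatives are provided).

Local friction then follows from the Einstein relation
$$\gamma_\mathrm{local} = \frac{k_B T}{D}, \qquad D = \frac{\delta^2}{2\tau},$$
with $\delta = 0.15$ nm — the vertical rise per residue of an α-helix —
and $T = 300$ K by default. An alternative convention measures the
cooperative O–N approach distance, $\delta = 0.34$ nm; conversions
between the two scale by $(0.34/0.15)^2 = 5.14$. Both $\delta$ values
live in `physical_constants()` and are configurable.

## Free-energy landscape and global friction

The joint occupancy $\Omega$ of (HB count, end-to-end distance) bins
gives $G = -RT\ln\Omega$; empty bins have *undefined* free energy and are
stored as `NA`, never 0 (since $-RT\ln 0$ diverges). The surface's
per-level histogram centers $x_i$ are computed from the **raw** per-frame
distance samples at each level, not from binned midpoints; this removes
the bin-width dependence entirely (binning is retained for export and
plotting). Levels occupied by fewer than 50 frames (configurable) are
excluded: undersampled extreme levels produce unstable centers, and the
floor makes that exclusion reproducible rather than judgmental.

Global friction uses the accumulated squared steps
$\sum_i \Delta x_i^2$ with $\Delta x_i = x_{i+1} - x_i$:
$$\gamma_\mathrm{global} = \frac{k_B T}{k_\mathrm{fold} \sum_i \Delta x_i^2}.$$
This closed form is a *reconstruction*: the defining expression is not
printed in a recoverable form in the source literature. Checked against
published per-condition averages, it reproduces about half of the
pure-water global-friction values inside their printed uncertainties and
underestimates the others (the published pipeline averages per-trajectory
values of a convex function, which inflates the mean — Jensen's
inequality — but that does not explain every discrepancy). The
corresponding acceptance test asserts containment row by row and is left
honestly red where the printed tables are not internally consistent with
this form; the worked local-friction and equilibrium-constant identities,
by contrast, reproduce exactly.

## Viscosity and extrapolation to zero viscosity

Tracer (water) diffusion is estimated from the ensemble- and
time-origin-averaged MSD; the slope of its linear regime equals $6D$.
The fit window defaults to 10–50% of the analysed span, excluding the
short-time domain; long trajectories can be split into chunks whose MSD
curves are averaged (mirroring the 200-ns-chunk practice for production
data). Diagnostics flag curvature (ballistic or confined motion) and
vanishing MSD. Relative viscosity is the Stokes ratio
$\eta/\eta_0 = D_{w0}/D_w$ with the pure-water TIP3P reference
$D_{w0} = 5.6635\times10^{-5}\ \mathrm{cm^2/s}$ as a configurable
default — any re-simulation should supply its own reference.

Friction-vs-viscosity series are fitted linearly
($\gamma = a\,\eta/\eta_0 + \gamma_0$, the intercept $\gamma_0$ being the
internal friction) and with a power law
($\gamma = \gamma_w (\eta/\eta_0)^\beta$), the latter estimated in
log–log space and refined by nonlinear least squares — stable with as few
as three points. Series can be normalized by their value at
$\eta/\eta_0 = 1$ (exact point or linear interpolation); normalization
preserves $\beta$. The published fit-coefficient and global
internal-friction tables are **not** desk-reproducible because the
relative viscosities of the 2 M and 5 M proline solutions are not
printed; the acceptance suite therefore substitutes property-based
recovery tests (exact on noiseless curves; 5% on parameters and 0.05 on
$\beta$ under 1% multiplicative noise; a $\beta$ sweep over
$\{0.3, 0.5, 1.0\}$).

## The synthetic generator: what it emulates and what it does not

The generator provides the *statistical structure the analysis assumes*,
not an MD ensemble:

- **HB kinetics** are per-bond two-state continuous-time Markov chains
  sampled every `dt` with the exact transition probabilities
  $1 - e^{-k\,dt}$ (not an Euler step), so dwell statistics are unbiased
  at coarse frames. Stationary occupancy is $k_f/(k_f+k_u)$ and the state
  ACF decays at rate $k_f + k_u$ — the two analytic anchors the recovery
  tests use. Cooperativity is a single multiplicative factor on $k_f$
  given a formed neighbour: the minimal mechanism that produces
  multi-pathway landscapes without a full Ising parameterization.
- **End-to-end distances** are a truncated-Gaussian coil baseline
  (default mean 1.0 nm, sd 0.1 nm — a realistic coil-width scale for
  short peptides) plus 0.15 nm per formed bond, making the conditional
  mean strictly increasing in $h$ with constant spread. Truncation at
  zero exists because distances are nonnegative; with the default
  mean/sd it is a $10^{-23}$-probability event, i.e. inert.
- **Brownian tracers** take independent Gaussian increments of per-axis
  variance $2D\,dt$.

What a green recovery test establishes is therefore *estimator
correctness under the stated model*, not fidelity to MD: real
trajectories have correlated bonds, non-exponential dwell mixtures,
sequence-dependent geometry and solvent memory, none of which the
generator claims to reproduce.

**Monte-Carlo error budgets are part of the design.** Occupancy and
dwell tolerances are checked against autocorrelation-aware standard
errors ($\mathrm{SE}^2 \approx p(1-p)\,2\tau_c/T$), not i.i.d. ones. The
large recovery run (formation 5/μs, rupture 15/μs, 2 ps frames, $10^7$
frames) uses 64 bonds simulated in blocks of 8: a single bond completes
only ~75 formed dwells in 20 μs (SE ≈ 12%), so the bond count was sized
*a priori* so that the pooled ~4800 dwells support the 3% tolerance on
the mean dwell. The ACF, whose estimator noise does not shrink with bond
count, is instead averaged over the independent blocks before fitting —
the same trajectory-averaging the e/h convention applies to production
data.

## e/h averaging and reporting

Production analyses run paired trajectories started from extended ("e")
and helical ("h") configurations. `run_pipeline()` analyses each
separately and reports the mean with half the absolute difference as the
uncertainty; single-trajectory conditions are flagged and carry empty
error columns. Tables are rounded to three significant figures. A stage
failure (e.g. an absorbing bond that never transitions) aborts only its
peptide × condition cell and is recorded in the JSON manifest along with
the settings in effect, the generator seeds and the package version.

## Numerical choices and degenerate inputs

- Superposition for RMSDH uses the closed-form least-squares (SVD)
  rotation with the proper-rotation correction (reflections disallowed);
  it is validated against a multi-start general-purpose optimizer to
  $10^{-6}$ nm. The default atom selection is Cα — the defining sum is
  not pinned to a selection in the literature, so it is configurable.
- Exponential fits run Nelder–Mead followed by a BFGS polish on
  log-scale parameters (positivity by construction); noiseless inputs
  are recovered to at least 6 (relaxation) / 4 (mixture) digits.
- Zero-variance series, empty histograms, absorbing chains, missing
  atom roles and non-positive physical parameters all raise errors that
  name the offending field rather than propagating NaNs.
- Seeds: every generator owns one RNG stream, set from its spec and
  restored afterwards, so runs are bit-reproducible and composable.

## Known limitations

- The global-friction closed form is a reconstruction (see above); its
  prefactor convention cannot be confirmed from printed sources alone.
- Dwell-time extraction reports durations quantized to the frame
  interval; fitted τ inherits an $O(dt/2)$ bias, negligible for
  $dt \ll \tau$ and covered by a halving-robustness test.
- The two-component mixture fit is least-squares on counts by default;
  for very sparse histograms the Poisson option is preferable.
- No hidden-Markov or multi-state kinetics, no DSSP/Ramachandran
  helicity, no absolute viscosity computation, and no binary trajectory
  formats in core — all deliberate non-goals.
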