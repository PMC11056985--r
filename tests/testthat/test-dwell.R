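# Dwell-time extraction, log-binned histograms, exponential-mixture fits.

test_that("dwell extraction censoring convention (hand-traced)", {
  st <- hb_state_matrix(matrix(c(1, 1, 1, 0, 0, 1, 1, 0), ncol = 1),
                        dt = 2)
  dw <- extract_dwells(st, "per_bond_formed")
  # leading [1,1,1] censored, trailing [0] censored; completed formed run
  # is the 2-frame [1,1] = 4 ps
  expect_equal(dw$durations, 4)
  expect_equal(dw$censored_count, 1L)

  dwb <- extract_dwells(st, "per_bond_broken")
  expect_equal(dwb$durations, 4)  # interior [0,0]
  expect_equal(dwb$censored_count, 1L)  # trailing broken run

  alt <- hb_state_matrix(matrix(rep(c(1L, 0L), 10), ncol = 1), dt = 2)
  expect_true(all(extract_dwells(alt, "per_bond_formed")$durations == 2))
  expect_true(all(extract_dwells(alt, "per_bond_broken")$durations == 2))

  allz <- hb_state_matrix(matrix(0L, 10, 1), dt = 2)
  expect_error(extract_dwells(allz, "per_bond_formed"),
               "insufficient transitions")
})

test_that("total_h_constant mode segments the h series", {
  m <- rbind(c(1, 0), c(1, 0), c(1, 1), c(1, 1), c(1, 1), c(0, 1), c(0, 0))
  st <- hb_state_matrix(m, dt = 2)
  # h = 1,1,2,2,2,1,0: interior runs are the three-frame h=2 (6 ps) and the
  # one-frame h=1 (2 ps)
  dw <- extract_dwells(st, "total_h_constant")
  expect_equal(sort(dw$durations), c(2, 6))
})

test_that("dwell extraction matches the naive per-frame scan oracle", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rbinom(3000, 1, 0.4), ncol = 3)
    st <- hb_state_matrix(m, dt = 2)
    for (mode in c("per_bond_formed", "per_bond_broken",
                   "total_h_constant")) {
      got <- tryCatch(extract_dwells(st, mode)$durations,
                      error = function(e) numeric(0))
      expect_equal(sort(got), sort(oracle_dwells(m, 2, mode)),
                   info = paste("seed", s, mode))
    }
  }
})

test_that("simulated mean formed dwell approaches 1/k_break", {
  # k_break = 0.1/ps (1e5 per us), dt = 0.1 ps; ~1e4 completed dwells
  spec <- kinetics_spec(n_bonds = 1, k_form = 2e4, k_break = 1e5,
                        dt = 0.1, n_frames = 6e6, seed = 23)
  st <- simulate_hb_states(spec)
  dw <- extract_dwells(st, "per_bond_formed")
  expect_gt(length(dw$durations), 5e3)
  expect_lt(abs(mean(dw$durations) / 10 - 1), 0.03)
})

test_that("log histogram: conservation, mode location, validation", {
  expect_error(log_histogram(numeric(0)), "no durations")
  expect_error(log_histogram(c(1, 2), bins_per_decade = 0),
               "bins_per_decade")

  h1 <- log_histogram(rep(25, 100))
  expect_equal(sum(h1$counts), 100)
  expect_equal(sum(h1$counts > 0), 1)

  set.seed(41)
  tau <- 50
  samp <- rexp(2e4, 1 / tau)
  h2 <- log_histogram(samp, bins_per_decade = 10)
  expect_equal(sum(h2$counts), 2e4)
  # the log-domain density t*exp(-t/tau)/tau peaks at t = tau
  modal_t <- h2$t_mids[which.max(h2$counts)]
  expect_gt(modal_t, tau / 2)
  expect_lt(modal_t, tau * 2)
})

test_that("mixture fit recovers a noiseless single exponential", {
  # expected counts of Exp(tau = 20) on an exact log grid
  tau <- 20; n <- 1e4; bpd <- 10
  breaks <- seq(-1, 4, by = 1 / bpd)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  t <- 10^mids
  counts <- n * log(10) / bpd * (t / tau) * exp(-t / tau)
  hist <- structure(list(breaks = breaks, mids = mids, t_mids = t,
                         counts = counts, total = n,
                         bins_per_decade = bpd),
                    class = "DwellLogHistogram")
  fit <- fit_exponential_mixture(hist, 1)
  expect_equal(fit$components$tau, 20, tolerance = 1e-4)
  expect_equal(ensemble_dwell_time(fit), fit$components$tau)
})

test_that("biexponential recovery from sampled dwells", {
  set.seed(53)
  n <- 5e4
  comp <- runif(n) < 0.7
  samp <- ifelse(comp, rexp(n, 1 / 10), rexp(n, 1 / 100))
  fit <- fit_exponential_mixture(log_histogram(samp, 10), 2)
  expect_equal(fit$n_components, 2)
  taus <- sort(fit$components$tau)
  ws <- fit$components$weight[order(fit$components$tau)]
  expect_lt(abs(taus[1] / 10 - 1), 0.10)
  expect_lt(abs(taus[2] / 100 - 1), 0.10)
  expect_lt(abs(ws[1] - 0.7), 0.05)
  expect_lt(abs(ws[2] - 0.3), 0.05)
})

test_that("two-component fit on single-exponential data is flagged", {
  set.seed(61)
  samp <- rexp(2e4, 1 / 30)
  fit <- suppressWarnings(
    fit_exponential_mixture(log_histogram(samp, 10), 2))
  near_equal <- fit$n_components == 2 &&
    max(fit$components$tau) / min(fit$components$tau) < 3
  tiny_weight <- fit$n_components == 2 && min(fit$components$weight) < 0.1
  expect_true(fit$fallback || near_equal || tiny_weight)
  expect_lt(abs(fit$mean_tau / 30 - 1), 0.15)
})

test_that("histogram-fit tau is consistent with the sample mean", {
  set.seed(67)
  samp <- rexp(2e4, 1 / 40)
  fit <- fit_exponential_mixture(log_histogram(samp, 10), 1)
  se <- 40 / sqrt(2e4)
  expect_lt(abs(fit$components$tau - mean(samp)), 3 * se)
})

test_that("fitted tau is robust to halving dt", {
  mk <- function(dt, seed) {
    spec <- kinetics_spec(n_bonds = 1, k_form = 1e4, k_break = 2e4,
                          dt = dt, n_frames = round(3e6 / dt), seed = seed)
    dw <- extract_dwells(simulate_hb_states(spec), "per_bond_formed")
    fit <- fit_exponential_mixture(log_histogram(dw, 10), 1)
    fit$components$tau
  }
  tau_coarse <- mk(1, 71)
  tau_fine <- mk(0.5, 71)
  expect_lt(abs(tau_fine / tau_coarse - 1), 0.05)
})

test_that("ensemble_dwell_time combination rules", {
  fit <- structure(list(components = data.frame(weight = c(0.5, 0.5),
                                                tau = c(10, 30)),
                        mean_tau = 20, n_components = 2, fallback = FALSE,
                        goodness = list()),
                   class = "ExpMixFit")
  expect_equal(ensemble_dwell_time(fit), 20)
  expect_equal(ensemble_dwell_time(fit, "slow"), 30)
  expect_equal(ensemble_dwell_time(fit, "fast"), 10)
})
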