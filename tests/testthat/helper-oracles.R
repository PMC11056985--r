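# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# Direct-sum autocorrelation with the per-lag numerator convention.
oracle_acf <- function(x, max_lag) {
  n <- length(x)
  d <- x - mean(x)
  v <- sum(d^2) / n
  vapply(0:max_lag, function(k) {
    mean(d[seq_len(n - k)] * d[(k + 1):n]) / v
  }, numeric(1))
}

# Naive per-frame scan dwell extraction (first/last runs censored).
oracle_dwells <- function(mat, dt, mode) {
  sigs <- if (mode == "total_h_constant") list(rowSums(mat))
          else lapply(seq_len(ncol(mat)), function(b) mat[, b])
  target <- switch(mode, per_bond_formed = 1, per_bond_broken = 0,
                   total_h_constant = NA)
  out <- numeric(0)
  for (sig in sigs) {
    run_starts <- c(1, which(diff(sig) != 0) + 1)
    run_ends <- c(run_starts[-1] - 1, length(sig))
    nr <- length(run_starts)
    if (nr < 3) next
    for (ri in 2:(nr - 1)) {
      val <- sig[run_starts[ri]]
      if (is.na(target) || val == target)
        out <- c(out, (run_ends[ri] - run_starts[ri] + 1) * dt)
    }
  }
  out
}

# Naive double-loop ensemble/time-origin-averaged MSD.
oracle_msd <- function(coords, lag) {
  nf <- dim(coords)[1]; np <- dim(coords)[2]
  tot <- 0; cnt <- 0
  for (p in seq_len(np)) {
    for (t0 in seq_len(nf - lag)) {
      dv <- coords[t0 + lag, p, ] - coords[t0, p, ]
      tot <- tot + sum(dv^2)
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

# Rigid-superposition RMSD by general-purpose optimization over Euler
# angles from many random starts (independent of the closed-form SVD path).
oracle_rmsd <- function(x, y, n_starts = 25) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  rotmat <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(a) sqrt(mean(rowSums((yc - xc %*% t(rotmat(a)))^2)))
  best <- Inf
  set.seed(99)
  for (s in seq_len(n_starts)) {
    a0 <- runif(3, -pi, pi)
    r <- optim(a0, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-15))
    r <- optim(r$par, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
    if (r$value < best) best <- r$value
  }
  best
}

# Autocorrelation-aware standard error of the mean of a stationary 0/1
# series with relaxation time tau_frames (used to test stationary
# occupancy at 3 SE).
occupancy_se <- function(p, tau_frames, n_frames, n_indep = 1) {
  sqrt(p * (1 - p) * 2 * tau_frames / (n_frames * n_indep))
}
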