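# Independent brute-force oracles and small dataset builders shared by the
# unit and acceptance tests. The oracles deliberately use the naive O(n^2)
# definitions so they share no code path with the package's estimators.

# random-walk dataset: n steps, optional second segment starting mid-way
rw_dataset <- function(n = 200, n_agents = 1, dt = 0.12, two_segments = FALSE,
                       sd = 1, seed = 1) {
  set.seed(seed)
  pos <- array(NA_real_, dim = c(n, 2L, n_agents))
  for (a in seq_len(n_agents)) {
    pos[, 1, a] <- cumsum(rnorm(n, sd = sd))
    pos[, 2, a] <- cumsum(rnorm(n, sd = sd))
  }
  segment <- if (two_segments) rep(1:2, times = c(floor(n / 2), n - floor(n / 2)))
             else rep(1L, n)
  t <- seq_len(n) * dt
  if (two_segments) t[segment == 2L] <- t[segment == 2L] + 5 * dt  # gap
  trajectory_dataset(t, pos, segment = segment, dt = dt, tank_radius = 1e4)
}

# O(n^2) mean squared displacement over segments and agents
brute_msd <- function(ds, lags_steps) {
  sums <- numeric(length(lags_steps)); counts <- numeric(length(lags_steps))
  for (idx in split(seq_along(ds$t), ds$segment)) {
    for (a in seq_len(ds$n_agents)) {
      U <- ds$pos[idx, , a, drop = FALSE]
      L <- length(idx)
      for (j in seq_along(lags_steps)) {
        k <- lags_steps[j]
        if (k >= L && k > 0) next
        for (i in seq_len(L - k)) {
          d2 <- (U[i + k, 1, 1] - U[i, 1, 1])^2 + (U[i + k, 2, 1] - U[i, 2, 1])^2
          sums[j] <- sums[j] + d2
          counts[j] <- counts[j] + 1
        }
      }
    }
  }
  sums / counts
}

# backward-difference velocities per segment (first sample dropped)
seg_velocities <- function(ds, idx, a) {
  U <- ds$pos[idx, , a, drop = FALSE]
  (U[-1, , 1, drop = FALSE] - U[-length(idx), , 1, drop = FALSE]) / ds$dt
}

brute_vac <- function(ds, lags_steps) {
  sums <- numeric(length(lags_steps)); counts <- numeric(length(lags_steps))
  for (idx in split(seq_along(ds$t), ds$segment)) {
    if (length(idx) < 2L) next
    for (a in seq_len(ds$n_agents)) {
      V <- seg_velocities(ds, idx, a)
      L <- dim(V)[1]
      for (j in seq_along(lags_steps)) {
        k <- lags_steps[j]
        if (k >= L) next
        for (i in seq_len(L - k)) {
          sums[j] <- sums[j] + V[i + k, 1, 1] * V[i, 1, 1] + V[i + k, 2, 1] * V[i, 2, 1]
          counts[j] <- counts[j] + 1
        }
      }
    }
  }
  sums / counts
}

brute_thetaw_ac <- function(ds, lags_steps) {
  sums <- numeric(length(lags_steps)); counts <- numeric(length(lags_steps))
  R <- ds$tank_radius
  for (idx in split(seq_along(ds$t), ds$segment)) {
    if (length(idx) < 2L) next
    for (a in seq_len(ds$n_agents)) {
      V <- seg_velocities(ds, idx, a)
      U <- ds$pos[idx[-1], , a, drop = FALSE]
      phi <- atan2(V[, 2, 1], V[, 1, 1])
      th <- phi - atan2(U[, 2, 1], U[, 1, 1])
      L <- length(th)
      for (j in seq_along(lags_steps)) {
        k <- lags_steps[j]
        if (k >= L) next
        for (i in seq_len(L - k)) {
          sums[j] <- sums[j] + cos(th[i + k] - th[i])
          counts[j] <- counts[j] + 1
        }
      }
    }
  }
  sums / counts
}

# closed-form Gaussian negative log-density oracle (via dnorm)
oracle_nll <- function(mu, sigma, targets) {
  -log(dnorm(targets[, 1], mu[, 1], sigma[, 1])) -
    log(dnorm(targets[, 2], mu[, 2], sigma[, 2])) - log(2 * pi)
}

# two-bin pdf_estimate with given probability masses (unit-width bins)
masses_pdf <- function(masses) {
  structure(list(variable = "x", edges = seq(0, length(masses)),
                 density = masses, counts = round(masses * 1000),
                 n = 1000L, role = "all"),
            class = "pdf_estimate")
}
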