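# Asynchronous analytical burst-and-coast simulator. Each agent moves in
# discrete kicks: at a decision instant it chooses a new heading (wall term +
# social terms + Gaussian cognitive noise), a kick length and a kick duration,
# then glides in a straight line while its speed decays. Kicks of the two
# agents are asynchronous: the agent whose next decision time is smallest
# moves next, reading its neighbour's glide-interpolated state at that instant.
# Proposed kick endpoints outside the tank are rejected and redrawn. The
# simulator doubles as the package's synthetic-data generator.

#' Burst-and-coast model parameters
#'
#' The exact interaction functions for rummy-nose tetra come from a separate
#' data-driven reconstruction and are not shipped here; instead the simulator
#' exposes a parametric family honouring the usual angular-symmetry
#' principles, with every kernel injectable:
#' \itemize{
#'   \item wall term `A_w * exp(-r_w / l_w) * sin(theta_w) + eps_w * exp(-r_w / l_w)`
#'     (odd in the incidence angle, exponentially decaying in wall distance,
#'     plus a small additive asymmetry that biases the direction of rotation);
#'   \item attraction `A_att * d/(d + d_att) * sin(psi_ij)` (odd in the viewing
#'     angle, increasing then saturating with distance);
#'   \item alignment `A_ali * exp(-d / l_ali) * sin(phi_ij)` (odd in the
#'     relative heading, decaying with distance);
#'   \item cognitive noise `gamma * g`, `g ~ N(0, 1)`, per kick.
#' }
#' Kick durations and lengths are gamma-distributed with shape 2 and means
#' 0.5 s and 7 cm, matching the experimental means for this species.
#'
#' @param tau_mean,tau_shape mean (s) and gamma shape of kick durations.
#' @param l_mean,l_shape mean (cm) and gamma shape of kick lengths.
#' @param gamma heading-noise standard deviation per kick (rad).
#' @param wall_amp,wall_decay,wall_asym wall-term amplitude (rad), decay
#'   length (cm) and asymmetry constant (rad).
#' @param att_amp,att_dist attraction amplitude (rad) and half-saturation
#'   distance (cm).
#' @param ali_amp,ali_decay alignment amplitude (rad) and decay length (cm).
#' @param glide `"exponential"` (speed decays with time constant tau/2 within
#'   a kick, renormalized to cover the kick length) or `"uniform"`.
#' @param noise_retries,rejection_cap wall-rejection bookkeeping: number of
#'   noise-only redraws before full (noise, tau, l) redraws, and the total cap.
#' @param tank_radius,body_length arena metadata (cm).
#' @return object of class `abc_model`.
#' @export
abc_model <- function(tau_mean = 0.5, tau_shape = 2,
                      l_mean = 7, l_shape = 2,
                      gamma = 0.35,
                      wall_amp = 0.45, wall_decay = 7, wall_asym = 0.04,
                      att_amp = 0.7, att_dist = 7,
                      ali_amp = 1.0, ali_decay = 20,
                      glide = c("exponential", "uniform"),
                      noise_retries = 5L, rejection_cap = 1000L,
                      tank_radius = 25, body_length = 3.5) {
  glide <- match.arg(glide)
  stopifnot(tau_mean > 0, tau_shape > 0, l_mean > 0, l_shape > 0, gamma >= 0,
            is.finite(wall_amp), is.finite(att_amp), is.finite(ali_amp))
  structure(as.list(environment()), class = "abc_model")
}

#' @export
print.abc_model <- function(x, ...) {
  cat(sprintf("<abc_model> kicks ~ gamma(mean %.2g s, %.2g cm); noise %.2g rad\n",
              x$tau_mean, x$l_mean, x$gamma))
  cat(sprintf("  wall %.2g * exp(-r_w/%.2g) * sin(theta_w) + %.2g; att %.2g; ali %.2g\n",
              x$wall_amp, x$wall_decay, x$wall_asym, x$att_amp, x$ali_amp))
  invisible(x)
}

#' Draw kick durations and lengths
#'
#' Independent gamma draws with the configured shapes and means.
#'
#' @param params an [abc_model()].
#' @param n number of kicks to draw.
#' @return list with numeric vectors `tau` (s) and `l` (cm).
#' @export
sample_kick <- function(params, n = 1L) {
  list(tau = stats::rgamma(n, shape = params$tau_shape,
                           rate = params$tau_shape / params$tau_mean),
       l = stats::rgamma(n, shape = params$l_shape,
                         rate = params$l_shape / params$l_mean))
}

#' Heading change at a kick decision
#'
#' Deterministic wall and social terms plus one Gaussian noise draw. The
#' neighbour may be `NULL` (solitary agent), in which case the social term is
#' zero.
#'
#' @param focal list with `u` (position, cm) and `phi` (heading, rad).
#' @param neighbour list with `u` and `phi`, or `NULL`.
#' @param params an [abc_model()].
#' @param noise optional fixed noise draw (for reproducibility/testing);
#'   default a fresh `N(0,1)` variate scaled by `params$gamma`.
#' @return object of class `heading_change`: list with `wall`, `social`
#'   (attraction + alignment, also split out), `noise` and `total` (rad).
#' @export
heading_change <- function(focal, neighbour, params, noise = NULL) {
  wv <- wall_variables(focal$u, focal$phi, params$tank_radius)
  decay <- exp(-max(wv$r_w, 0) / params$wall_decay)
  wall <- params$wall_amp * decay * sin(wv$theta_w) + params$wall_asym * decay
  att <- ali <- 0
  if (!is.null(neighbour)) {
    pv <- pair_variables(focal$u, neighbour$u, focal$phi, neighbour$phi)
    if (!pv$coincident_flag) {
      att <- params$att_amp * pv$d_ij / (pv$d_ij + params$att_dist) * sin(pv$psi_ij)
      ali <- params$ali_amp * exp(-pv$d_ij / params$ali_decay) * sin(pv$phi_ij)
    }
  }
  if (is.null(noise)) noise <- params$gamma * stats::rnorm(1L)
  structure(list(wall = wall, attraction = att, alignment = ali,
                 social = att + ali, noise = noise,
                 total = wall + att + ali + noise),
            class = "heading_change")
}

# fraction of the kick length covered after a fraction s in [0,1] of the kick
# duration, under the configured glide model
glide_progress <- function(s, glide) {
  if (glide == "uniform") return(pmin(pmax(s, 0), 1))
  # exponential speed decay with time constant tau/2, renormalized so the
  # kick covers its full length in its duration
  (1 - exp(-2 * pmin(pmax(s, 0), 1))) / (1 - exp(-2))
}

# neighbour state (position, heading) glide-interpolated at time `at`
glide_state <- function(kick, at, glide) {
  s <- (at - kick$t) / kick$tau
  p <- glide_progress(s, glide)
  e <- c(cos(kick$phi), sin(kick$phi))
  list(u = kick$u0 + kick$l * p * e, phi = kick$phi)
}

#' Advance one agent by one kick
#'
#' Draws a kick duration and length, computes the heading change from the
#' focal and (glide-interpolated) neighbour states, and proposes the kick
#' endpoint. Endpoints outside the tank are rejected: the Gaussian noise is
#' redrawn first (`noise_retries` attempts), then the full (noise, tau, l)
#' triplet, up to `rejection_cap` total attempts. During the full-redraw
#' phase the noise scale is progressively inflated (by a factor
#' `1 + attempt / 100`), so that the rare trap state of an agent pinned
#' against the wall while heading outward resolves through an occasional
#' large heading change rather than an error; the deterministic wall and
#' social terms are never altered.
#'
#' @param focal list: `t` (decision time), `u` (position at decision, cm),
#'   `phi` (current heading, rad).
#' @param neighbour neighbour state as in [heading_change()], or `NULL`.
#' @param params an [abc_model()].
#' @return a kick event: list with `t`, `phi` (heading during the kick), `l`,
#'   `tau`, `u0` (start position) and `delta` (the accepted [heading_change()]).
#' @export
step_kick <- function(focal, neighbour, params) {
  R <- params$tank_radius
  base <- heading_change(focal, neighbour, params, noise = 0)
  kl <- sample_kick(params)
  tau <- kl$tau; l <- kl$l
  for (attempt in seq_len(params$rejection_cap)) {
    inflate <- if (attempt > params$noise_retries) 1 + attempt / 100 else 1
    noise <- params$gamma * inflate * stats::rnorm(1L)
    if (attempt > params$noise_retries) {
      kl <- sample_kick(params)
      tau <- kl$tau; l <- kl$l
    }
    dphi <- base$total + noise
    phi_new <- wrap_angle(focal$phi + dphi)
    endpoint <- focal$u + l * c(cos(phi_new), sin(phi_new))
    if (sqrt(sum(endpoint^2)) <= R) {
      delta <- base; delta$noise <- noise; delta$total <- base$total + noise
      return(list(t = focal$t, phi = phi_new, l = l, tau = tau,
                  u0 = focal$u, delta = delta))
    }
  }
  stop(sprintf(paste0("kick rejection cap exhausted at t = %.3f s ",
                      "(u = (%.2f, %.2f) cm, phi = %.3f rad)"),
               focal$t, focal$u[1], focal$u[2], focal$phi))
}

#' Run the asynchronous burst-and-coast simulation
#'
#' Event-driven loop: the agent whose next decision time is smallest performs
#' its next kick, reading the other agent's glide-interpolated state at that
#' instant. Initial positions are sampled uniformly in the inner 90% of the
#' tank with inward-pointing random headings.
#'
#' @param params an [abc_model()].
#' @param duration simulated time, seconds.
#' @param dt output timestep for the resampled trajectory (default 0.12 s).
#' @param n_agents 1 or 2.
#' @param seed optional RNG seed.
#' @return a [trajectory_dataset()] sampled on the `dt` grid, with the kick
#'   log attached as attribute `"kicks"` (data.frame
#'   `agent, t, phi, l, tau, x, y`).
#' @export
simulate_abc <- function(params, duration, dt = 0.12, n_agents = 2L, seed = NULL) {
  stopifnot(duration > 0, n_agents %in% c(1L, 2L))
  if (!is.null(seed)) set.seed(seed)
  R <- params$tank_radius
  # per-agent growing kick logs
  cap0 <- as.integer(ceiling(duration / params$tau_mean * 2) + 16L)
  logs <- lapply(seq_len(n_agents), function(a)
    list(t = numeric(cap0), phi = numeric(cap0), l = numeric(cap0),
         tau = numeric(cap0), x0 = numeric(cap0), y0 = numeric(cap0), n = 0L))
  cur <- vector("list", n_agents)   # current (ongoing) kick per agent
  push <- function(a, k) {
    lg <- logs[[a]]
    n <- lg$n + 1L
    if (n > length(lg$t)) {  # grow
      for (f in c("t", "phi", "l", "tau", "x0", "y0"))
        lg[[f]] <- c(lg[[f]], numeric(length(lg$t)))
    }
    lg$t[n] <- k$t; lg$phi[n] <- k$phi; lg$l[n] <- k$l; lg$tau[n] <- k$tau
    lg$x0[n] <- k$u0[1]; lg$y0[n] <- k$u0[2]
    lg$n <- n
    logs[[a]] <<- lg
  }
  # initial conditions: inside the tank, heading inward
  for (a in seq_len(n_agents)) {
    rad <- 0.9 * R * sqrt(stats::runif(1L))
    ang <- stats::runif(1L, -pi, pi)
    u <- rad * c(cos(ang), sin(ang))
    phi <- wrap_angle(ang + pi + stats::runif(1L, -pi / 2, pi / 2))
    kl <- sample_kick(params)
    # containment of the very first kick: shrink l if needed
    endpoint <- u + kl$l * c(cos(phi), sin(phi))
    while (sqrt(sum(endpoint^2)) > R) {
      kl <- sample_kick(params)
      phi <- wrap_angle(ang + pi + stats::runif(1L, -pi / 2, pi / 2))
      endpoint <- u + kl$l * c(cos(phi), sin(phi))
    }
    k <- list(t = 0, phi = phi, l = kl$l, tau = kl$tau, u0 = u)
    cur[[a]] <- k
    push(a, k)
  }
  next_t <- vapply(cur, function(k) k$t + k$tau, numeric(1))
  while (min(next_t) < duration) {
    a <- which.min(next_t)
    k <- cur[[a]]
    e <- c(cos(k$phi), sin(k$phi))
    focal <- list(t = k$t + k$tau, u = k$u0 + k$l * e, phi = k$phi)
    nb <- NULL
    if (n_agents == 2L) {
      b <- 3L - a
      nb <- glide_state(cur[[b]], focal$t, params$glide)
    }
    k_new <- step_kick(focal, nb, params)
    cur[[a]] <- k_new
    push(a, k_new)
    next_t[a] <- k_new$t + k_new$tau
  }
  kicks <- do.call(rbind, lapply(seq_len(n_agents), function(a) {
    lg <- logs[[a]]
    n <- lg$n
    data.frame(agent = a - 1L, t = lg$t[1:n], phi = lg$phi[1:n],
               l = lg$l[1:n], tau = lg$tau[1:n], x = lg$x0[1:n], y = lg$y0[1:n])
  }))
  ds <- kicks_to_trajectory(kicks, dt = dt, params = params, duration = duration)
  attr(ds, "kicks") <- kicks
  ds
}

#' Resample a kick log onto a uniform time grid
#'
#' Converts the discrete kick events into a continuous-time trajectory with
#' timestep `dt`: positions are taken along each kick's straight segment, with
#' within-kick progress following the glide model, so the speed profile shows
#' the burst-and-coast sawtooth.
#'
#' @param kicks data.frame `agent, t, phi, l, tau, x, y` (kick start states).
#' @param dt output timestep (s).
#' @param params an [abc_model()] (for the glide model and arena metadata).
#' @param duration optional clip; defaults to the covered time span.
#' @return a [trajectory_dataset()].
#' @export
kicks_to_trajectory <- function(kicks, dt = 0.12, params = abc_model(),
                                duration = NULL) {
  agents <- sort(unique(kicks$agent))
  ends <- vapply(agents, function(a) {
    ka <- kicks[kicks$agent == a, ]
    max(ka$t + ka$tau)
  }, numeric(1))
  starts <- vapply(agents, function(a) min(kicks$t[kicks$agent == a]), numeric(1))
  t0 <- max(starts)
  t1 <- min(ends)
  if (!is.null(duration)) t1 <- min(t1, t0 + duration)
  if (t1 <= t0) stop("kick log has no common time coverage")
  tt <- seq(t0, t1 - 1e-9, by = dt)
  pos <- array(NA_real_, dim = c(length(tt), 2L, length(agents)))
  for (j in seq_along(agents)) {
    ka <- kicks[kicks$agent == agents[j], ]
    ka <- ka[order(ka$t), ]
    if (nrow(ka) > 1L && any(abs(ka$t[-1] - (ka$t[-nrow(ka)] + ka$tau[-nrow(ka)])) > 1e-6))
      stop("gaps in event coverage for agent ", agents[j])
    idx <- findInterval(tt, ka$t)
    idx[idx < 1L] <- 1L
    s <- (tt - ka$t[idx]) / ka$tau[idx]
    p <- glide_progress(s, params$glide)
    pos[, 1, j] <- ka$x[idx] + ka$l[idx] * p * cos(ka$phi[idx])
    pos[, 2, j] <- ka$y[idx] + ka$l[idx] * p * sin(ka$phi[idx])
  }
  trajectory_dataset(tt, pos, dt = dt,
                     tank_radius = params$tank_radius,
                     body_length = params$body_length,
                     meta = sprintf("abc:glide=%s", params$glide))
}

#' Simulate method for the burst-and-coast model
#'
#' Thin wrapper around [simulate_abc()] following the base-R `simulate()`
#' convention.
#'
#' @param object an [abc_model()].
#' @param nsim number of independent runs.
#' @param seed optional RNG seed.
#' @param duration simulated seconds per run.
#' @param dt output timestep (s).
#' @param n_agents 1 or 2.
#' @param ... unused.
#' @return a [trajectory_dataset()] for `nsim = 1`, else a list of them.
#' @export
simulate.abc_model <- function(object, nsim = 1, seed = NULL,
                               duration = 600, dt = 0.12, n_agents = 2L, ...) {
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(nsim), function(i)
    simulate_abc(object, duration = duration, dt = dt, n_agents = n_agents))
  if (nsim == 1) runs[[1]] else runs
}

#' Write a kick log to CSV
#'
#' @param kicks kick log data.frame (`agent,t,phi,l,tau,x,y`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kicks <- function(kicks, path) {
  utils::write.csv(kicks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
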