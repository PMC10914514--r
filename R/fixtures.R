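# Deterministic toy datasets with known analytic properties, used by the unit
# tests and available to users as sanity baselines.

#' Ballistic pair fixture
#'
#' Two agents gliding in straight lines at constant speeds: the mean squared
#' displacement is exactly `<v^2> t^2` at every lag and the velocity
#' autocorrelation is constant. Generated in a nominally large arena so the
#' straight paths never reach a wall.
#'
#' @param n number of samples.
#' @param speeds length-2 speeds, cm/s.
#' @param dt timestep, s.
#' @return a [trajectory_dataset()].
#' @export
fixture_ballistic_pair <- function(n = 300L, speeds = c(5, 9), dt = 0.12) {
  t <- seq_len(n) * dt
  pos <- array(0, dim = c(n, 2L, 2L))
  dirs <- rbind(c(1, 0), c(cos(pi / 4), sin(pi / 4)))
  for (a in 1:2) {
    pos[, 1, a] <- speeds[a] * t * dirs[a, 1] - 100
    pos[, 2, a] <- speeds[a] * t * dirs[a, 2] - 100
  }
  trajectory_dataset(t, pos, dt = dt, tank_radius = 1e4,
                     meta = sprintf("fixture:ballistic v=%g,%g", speeds[1], speeds[2]))
}

#' Circular swimmer fixture
#'
#' One agent in uniform circular motion of radius `r` at angular rate
#' `omega`: with backward-difference velocities the velocity autocorrelation
#' is `s^2 cos(omega t)` where `s = 2 r sin(omega dt / 2) / dt` is the chord
#' speed (approaching `omega r` as `omega dt -> 0`), and the wall-incidence
#' angle is constant so its autocorrelation is exactly 1.
#'
#' @param n number of samples.
#' @param r orbit radius, cm.
#' @param omega angular rate, rad/s.
#' @param dt timestep, s.
#' @param tank_radius arena radius, cm.
#' @return a [trajectory_dataset()].
#' @export
fixture_circular_swimmer <- function(n = 2000L, r = 20, omega = 0.02,
                                     dt = 0.12, tank_radius = 25) {
  t <- seq_len(n) * dt
  pos <- array(c(r * cos(omega * t), r * sin(omega * t)), dim = c(n, 2L, 1L))
  trajectory_dataset(t, pos, dt = dt, tank_radius = tank_radius,
                     meta = sprintf("fixture:circle r=%g,omega=%g", r, omega))
}

#' Linear-Gaussian toy process
#'
#' Two independent agents obeying `a(t) = -k u(t) + sigma_a g(t)` with
#' standard-normal `g`, integrated semi-implicitly (velocity first, position
#' with the new velocity). The conditional mean of the acceleration given the
#' state is exactly `-k u` and the conditional standard deviation is exactly
#' `sigma_a`, which makes the process a parameter-recovery benchmark for the
#' interaction network.
#'
#' Restarts keep the process stationary: the dataset is split into
#' independent segments whose initial positions and velocities are drawn from
#' the oscillator's natural amplitude scale, so every contiguous block of the
#' data covers the same state distribution.
#'
#' @param n total number of samples.
#' @param k restoring constant, 1/s^2.
#' @param sigma_a acceleration noise scale, cm/s^2.
#' @param n_segments number of independent segments.
#' @param amp initial amplitude scale, cm (positions `N(0, amp^2)` per
#'   component, velocities `N(0, k * amp^2)`).
#' @param dt timestep, s.
#' @param tank_radius arena radius, cm.
#' @param seed optional RNG seed.
#' @return a [trajectory_dataset()] with attribute `"truth"` (list `k`,
#'   `sigma_a`).
#' @export
fixture_linear_gaussian <- function(n = 20000L, k = 1, sigma_a = 0.3,
                                    n_segments = 40L, amp = 5,
                                    dt = 0.12, tank_radius = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- ceiling(n / n_segments)
  pos <- array(NA_real_, dim = c(n, 2L, 2L))
  segment <- integer(n)
  at <- 0L
  for (s in seq_len(n_segments)) {
    len <- min(per, n - at)
    if (len <= 0L) break
    u <- matrix(stats::rnorm(4L, sd = amp), 2L, 2L)
    v <- matrix(stats::rnorm(4L, sd = sqrt(k) * amp), 2L, 2L)
    for (i in seq_len(len)) {
      a <- -k * u + sigma_a * matrix(stats::rnorm(4L), 2L, 2L)
      v <- v + dt * a
      u <- u + dt * v
      pos[at + i, , 1] <- u[1, ]
      pos[at + i, , 2] <- u[2, ]
    }
    segment[at + seq_len(len)] <- s
    at <- at + len
  }
  ds <- trajectory_dataset(seq_len(n) * dt, pos, segment = segment, dt = dt,
                           tank_radius = tank_radius,
                           meta = sprintf("fixture:linear_gaussian k=%g,sigma=%g", k, sigma_a))
  attr(ds, "truth") <- list(k = k, sigma_a = sigma_a)
  ds
}

#' Write the fixture suite to a directory
#'
#' Writes the ballistic pair, circular swimmer, linear-Gaussian process and a
#' short burst-and-coast run as canonical trajectory CSVs, together with a
#' JSON manifest of their analytic properties. Byte-identical given the same
#' seed.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return invisibly, the manifest list.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  bal <- fixture_ballistic_pair()
  circ <- fixture_circular_swimmer()
  lg <- fixture_linear_gaussian(n = 5000L)
  abc <- simulate_abc(abc_model(), duration = 120, seed = seed + 1L)
  write_trajectories(bal, file.path(dir, "ballistic_pair.csv"))
  write_trajectories(circ, file.path(dir, "circular_swimmer.csv"))
  write_trajectories(lg, file.path(dir, "linear_gaussian.csv"))
  write_trajectories(abc, file.path(dir, "abc_short.csv"))
  manifest <- list(
    seed = seed,
    ballistic_pair = list(file = "ballistic_pair.csv",
                          property = "C_X(t) = <v^2> t^2 exactly; C_V constant"),
    circular_swimmer = list(file = "circular_swimmer.csv",
                            property = "C_V(t) = s^2 cos(omega t), s = chord speed; C_thetaw = 1"),
    linear_gaussian = list(file = "linear_gaussian.csv",
                           property = "E[a | state] = -k u, SD[a | state] = sigma_a",
                           k = 1, sigma_a = 0.3),
    abc_short = list(file = "abc_short.csv",
                     property = "all positions inside the tank; sawtooth speed profile")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
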