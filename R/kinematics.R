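# Instantaneous individual and pairwise variables: velocity, speed, heading,
# wall distance and incidence, inter-individual distance, relative heading,
# viewing angle, geometric leadership. All angles in radians, wrapped to
# (-pi, pi]; positive angles are counter-clockwise.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return wrapped angles; `wrap_angle(wrap_angle(x)) == wrap_angle(x)`.
#' @export
wrap_angle <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

#' Wall distance and angle of incidence
#'
#' `r_w = R - |u|` is the distance to the circular wall; `theta_w` is the angle
#' between the heading and the outward radial direction at the fish's position
#' (0 = heading straight at the wall, +/- pi/2 = swimming parallel to it).
#' At the exact tank centre the polar angle is undefined; `theta_w` is set to 0
#' there and flagged.
#'
#' @param u numeric matrix n x 2 of positions (cm) or a length-2 vector.
#' @param phi heading angles (rad).
#' @param R tank radius (cm).
#' @return list with `r_w`, `theta_w` and logical `centre_flag`.
#' @export
wall_variables <- function(u, phi, R = 25) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 2)
  rad <- sqrt(u[, 1]^2 + u[, 2]^2)
  at_centre <- rad < 1e-12
  pol <- atan2(u[, 2], u[, 1])
  theta_w <- wrap_angle(phi - pol)
  theta_w[at_centre] <- 0
  list(r_w = R - rad, theta_w = theta_w, centre_flag = at_centre)
}

#' Pairwise relative-state variables
#'
#' Distance `d_ij = |u_i - u_j|`, heading difference `phi_ij = phi_j - phi_i`
#' (wrapped), and the viewing angles: `psi_ij` is the bearing of agent j in
#' agent i's body frame, i.e. the angle i must turn (counter-clockwise
#' positive) to face j. Coincident positions leave the viewing angles
#' undefined; they are flagged and set to `NA`.
#'
#' @param u_i,u_j positions, n x 2 matrices or length-2 vectors (cm).
#' @param phi_i,phi_j headings (rad).
#' @return list with `d_ij`, `phi_ij`, `psi_ij`, `psi_ji`, `coincident_flag`.
#' @export
pair_variables <- function(u_i, u_j, phi_i, phi_j) {
  if (is.null(dim(u_i))) u_i <- matrix(u_i, ncol = 2)
  if (is.null(dim(u_j))) u_j <- matrix(u_j, ncol = 2)
  dx <- u_j[, 1] - u_i[, 1]
  dy <- u_j[, 2] - u_i[, 2]
  d <- sqrt(dx^2 + dy^2)
  coincident <- d < 1e-12
  psi_ij <- wrap_angle(atan2(dy, dx) - phi_i)
  psi_ji <- wrap_angle(atan2(-dy, -dx) - phi_j)
  psi_ij[coincident] <- NA_real_
  psi_ji[coincident] <- NA_real_
  list(d_ij = d, phi_ij = wrap_angle(phi_j - phi_i),
       psi_ij = psi_ij, psi_ji = psi_ji, coincident_flag = coincident)
}

#' Geometric leader of a pair
#'
#' Agent i is the geometric leader when `|psi_ij| > |psi_ji|`: i would have to
#' turn by a larger angle to face j than j to face i, i.e. i is ahead. Exact
#' ties keep the previous leader (sticky tie-break); an initial tie yields `NA`.
#'
#' @param psi_ij,psi_ji viewing-angle vectors (rad).
#' @param prev leader id carried in from before the first sample (1, 2 or NA).
#' @return integer vector of leader ids (1 = agent i, 2 = agent j).
#' @export
geometric_leader <- function(psi_ij, psi_ji, prev = NA_integer_) {
  n <- length(psi_ij)
  out <- integer(n)
  cur <- as.integer(prev)
  for (k in seq_len(n)) {
    ai <- abs(psi_ij[k]); aj <- abs(psi_ji[k])
    if (is.na(ai) || is.na(aj)) {
      out[k] <- cur
    } else if (ai > aj) {
      cur <- 1L; out[k] <- 1L
    } else if (aj > ai) {
      cur <- 2L; out[k] <- 2L
    } else {
      out[k] <- cur
    }
  }
  out
}

#' Kinematic series of a trajectory dataset
#'
#' Computes, per agent: backward-difference velocity, speed, heading, wall
#' distance and incidence; and, for two-agent datasets, the pairwise variables
#' and the per-timestep geometric leader. The first sample of every segment has
#' no velocity and is marked invalid for feature extraction. Zero-velocity
#' samples carry the previous heading forward and are flagged.
#'
#' @param ds a [trajectory_dataset()] (cm units; normalized input is
#'   denormalized internally).
#' @return an object of class `kinematic_series`: list of per-agent matrices
#'   `vx, vy, speed, heading, r_w, theta_w` (n x n_agents), logical `valid`
#'   (velocity defined), `heading_carried`, and for pairs the vectors `d_ij`,
#'   `phi_ij`, `psi_12`, `psi_21`, `leader`.
#' @export
compute_kinematics <- function(ds) {
  if (ds$normalized) ds <- denormalize_positions(ds)
  n <- length(ds$t)
  na <- ds$n_agents
  vx <- vy <- speed <- heading <- matrix(NA_real_, n, na)
  carried <- matrix(FALSE, n, na)
  valid <- logical(n)
  for (idx in segment_indices(ds)) {
    if (length(idx) < 2L) next
    valid[idx[-1]] <- TRUE
    for (a in seq_len(na)) {
      d <- ds$pos[idx[-1], , a, drop = FALSE] - ds$pos[idx[-length(idx)], , a, drop = FALSE]
      vxa <- d[, 1, 1] / ds$dt
      vya <- d[, 2, 1] / ds$dt
      vx[idx[-1], a] <- vxa
      vy[idx[-1], a] <- vya
      sp <- sqrt(vxa^2 + vya^2)
      speed[idx[-1], a] <- sp
      hd <- atan2(vya, vxa)
      # zero velocity: heading undefined; carry the previous heading forward
      zero <- sp < 1e-12
      if (any(zero)) {
        for (k in which(zero)) {
          hd[k] <- if (k > 1L) hd[k - 1L] else NA_real_
          carried[idx[k + 1L], a] <- TRUE
        }
      }
      heading[idx[-1], a] <- hd
    }
  }
  rad <- sqrt(ds$pos[, 1, ]^2 + ds$pos[, 2, ]^2)
  rad <- matrix(rad, n, na)
  r_w <- ds$tank_radius - rad
  theta_w <- matrix(NA_real_, n, na)
  for (a in seq_len(na)) {
    wv <- wall_variables(ds$pos[, , a], heading[, a], ds$tank_radius)
    theta_w[, a] <- wv$theta_w
    theta_w[!valid, a] <- NA_real_
  }
  out <- list(t = ds$t, segment = ds$segment, dt = ds$dt, valid = valid,
              vx = vx, vy = vy, speed = speed, heading = heading,
              heading_carried = carried,
              r_w = r_w, theta_w = theta_w,
              body_length = ds$body_length, tank_radius = ds$tank_radius)
  if (na == 2L) {
    pv <- pair_variables(ds$pos[, , 1], ds$pos[, , 2], heading[, 1], heading[, 2])
    out$d_ij <- pv$d_ij
    out$phi_ij <- ifelse(valid, pv$phi_ij, NA_real_)
    out$psi_12 <- ifelse(valid, pv$psi_ij, NA_real_)
    out$psi_21 <- ifelse(valid, pv$psi_ji, NA_real_)
    leader <- rep(NA_integer_, n)
    for (idx in segment_indices(ds)) {
      vv <- idx[valid[idx]]
      if (length(vv))
        leader[vv] <- geometric_leader(out$psi_12[vv], out$psi_21[vv])
    }
    out$leader <- leader
  }
  class(out) <- "kinematic_series"
  out
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d samples (%d with velocity), %d agent(s)\n",
              length(x$t), sum(x$valid), ncol(x$speed)))
  invisible(x)
}

#' Export a kinematic series as a wide data frame
#'
#' One row per timestep, one column per variable per agent (and per pair for
#' two-agent data), suitable for writing to CSV.
#'
#' @param x a `kinematic_series`.
#' @param row.names,optional,... passed over from the generic, unused.
#' @return a `data.frame` keyed by time.
#' @export
as.data.frame.kinematic_series <- function(x, row.names = NULL, optional = FALSE, ...) {
  na <- ncol(x$speed)
  df <- data.frame(t = x$t, segment = x$segment)
  for (a in seq_len(na)) {
    df[[paste0("vx", a - 1L)]] <- x$vx[, a]
    df[[paste0("vy", a - 1L)]] <- x$vy[, a]
    df[[paste0("V", a - 1L)]] <- x$speed[, a]
    df[[paste0("phi", a - 1L)]] <- x$heading[, a]
    df[[paste0("r_w", a - 1L)]] <- x$r_w[, a]
    df[[paste0("theta_w", a - 1L)]] <- x$theta_w[, a]
  }
  if (!is.null(x$d_ij)) {
    df$d_ij <- x$d_ij
    df$phi_ij <- x$phi_ij
    df$psi_12 <- x$psi_12
    df$psi_21 <- x$psi_21
    df$leader <- x$leader
  }
  df
}
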