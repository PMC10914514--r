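# The nine-observable validation suite: six probability density functions
# (speed, wall distance, wall incidence, inter-individual distance, relative
# heading, viewing angle) and three temporal correlation functions (mean
# squared displacement, velocity autocorrelation, wall-incidence
# autocorrelation), plus Hellinger-distance scoring against a reference.

#' Named histogram binning policy
#'
#' A fixed set of bin edges per observable, so that Hellinger distances are
#' comparable across runs. The default policy uses: speed on \[0, 35\] cm/s in
#' 70 bins; wall distance on \[0, R\] cm in 50 bins; angles on (-pi, pi\] in 72
#' bins (5 degrees each); inter-individual distance on \[0, 2R\] cm in 100 bins.
#'
#' @param name policy id.
#' @param tank_radius tank radius (cm), sets the spatial ranges.
#' @return object of class `binning_policy`: named list of edge vectors plus
#'   an `id` attribute.
#' @export
binning_policy <- function(name = "default", tank_radius = 25) {
  edges <- list(
    V = seq(0, 35, length.out = 71),
    r_w = seq(0, tank_radius, length.out = 51),
    theta_w = seq(-pi, pi, length.out = 73),
    d_ij = seq(0, 2 * tank_radius, length.out = 101),
    phi_ij = seq(-pi, pi, length.out = 73),
    psi = seq(-pi, pi, length.out = 73)
  )
  structure(edges, id = name, class = "binning_policy")
}

#' Histogram density estimate
#'
#' Normalized histogram: `density[k] = count[k] / (n * width[k])`, so that
#' `sum(density * width) == 1` over the retained samples. Samples outside the
#' edge range (and NAs) are dropped. Fewer than 100 samples triggers a warning;
#' an empty input is an error.
#'
#' @param samples numeric vector.
#' @param edges strictly increasing bin edges (a vector, or a
#'   [binning_policy()] entry).
#' @param variable variable name stored in the estimate.
#' @param role optional role tag (`"all"`, `"leader"`, `"follower"`).
#' @return object of class `pdf_estimate`: list with `variable`, `edges`,
#'   `density`, `counts`, `n`, `role`.
#' @export
estimate_pdf <- function(samples, edges, variable = "x", role = "all") {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("cannot estimate a PDF from an empty sample")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  inside <- samples >= edges[1] & samples <= edges[length(edges)]
  samples <- samples[inside]
  if (!length(samples)) stop("no samples fall inside the binning range")
  if (length(samples) < 100L)
    warning(sprintf("PDF of '%s' estimated from only %d samples", variable, length(samples)))
  counts <- graphics::hist(samples, breaks = edges, plot = FALSE)$counts
  width <- diff(edges)
  structure(list(variable = variable, edges = edges,
                 density = counts / (sum(counts) * width),
                 counts = counts, n = length(samples), role = role),
            class = "pdf_estimate")
}

#' @export
print.pdf_estimate <- function(x, ...) {
  cat(sprintf("<pdf_estimate> %s (%s): %d bins, n = %d\n",
              x$variable, x$role, length(x$counts), x$n))
  invisible(x)
}

#' Hellinger distance between two binned PDFs
#'
#' `HD = sqrt(1 - sum_k sqrt(p_k q_k))` on the per-bin probability masses;
#' lies in \[0, 1\], is 0 for identical distributions and 1 for disjoint
#' supports. Both estimates must use identical bin edges (no silent
#' re-binning).
#'
#' @param p,q [estimate_pdf()] objects on the same edges.
#' @return scalar in \[0, 1\].
#' @export
hellinger <- function(p, q) {
  if (length(p$edges) != length(q$edges) || any(abs(p$edges - q$edges) > 1e-12))
    stop("Hellinger distance requires identical bin edges")
  w <- diff(p$edges)
  pm <- p$density * w
  qm <- q$density * w
  pm <- pm / sum(pm)
  qm <- qm / sum(qm)
  sqrt(max(0, 1 - sum(sqrt(pm * qm))))
}

# Shared engine for the three correlation observables. For each segment and
# focal agent it averages fun(t' + lag, t') over all reference times t' within
# the segment; averaging never crosses segment boundaries. `series` is a list
# (one entry per segment x agent) of matrices whose rows are time samples;
# `mask` (same shape, logical vector per entry) selects admissible reference
# times (role attribution at t').
correlation_engine <- function(series, mask, lags_steps, pairfun) {
  sums <- numeric(length(lags_steps))
  counts <- numeric(length(lags_steps))
  for (s in seq_along(series)) {
    M <- series[[s]]
    m <- mask[[s]]
    L <- nrow(M)
    if (L < 1L) next
    for (j in seq_along(lags_steps)) {
      k <- lags_steps[j]
      if (k >= L) next
      i0 <- seq_len(L - k)
      use <- m[i0]
      if (!any(use)) next
      vals <- pairfun(M[i0 + k, , drop = FALSE], M[i0, , drop = FALSE])
      ok <- use & is.finite(vals)
      sums[j] <- sums[j] + sum(vals[ok])
      counts[j] <- counts[j] + sum(ok)
    }
  }
  list(values = ifelse(counts > 0, sums / counts, NA_real_), counts = counts)
}

correlation_curve <- function(kind, lags, values, counts, role = "mean") {
  structure(list(kind = kind, lags = lags, values = values,
                 counts = counts, role = role),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %s (%s): %d lags up to %.2f s\n",
              x$kind, x$role, length(x$lags), max(x$lags)))
  invisible(x)
}

# build per-(segment x agent) series matrices and role masks from a dataset
role_series <- function(ds, kin, what, role = "mean") {
  segs <- segment_indices(ds)
  na <- ds$n_agents
  series <- list(); mask <- list()
  for (idx in segs) {
    for (a in seq_len(na)) {
      M <- switch(what,
        pos = ds$pos[idx, , a, drop = TRUE],
        vel = cbind(kin$vx[idx, a], kin$vy[idx, a]),
        thetaw = cbind(kin$theta_w[idx, a])
      )
      if (is.null(dim(M))) M <- matrix(M, ncol = if (what == "thetaw") 1L else 2L)
      keep <- switch(what, pos = rep(TRUE, length(idx)), vel = kin$valid[idx],
                     thetaw = kin$valid[idx] & is.finite(kin$theta_w[idx, a]))
      # trim the undefined head of the segment but keep rows contiguous
      first <- if (any(keep)) which(keep)[1] else length(idx) + 1L
      rows <- seq.int(first, length(idx))
      if (first > length(idx)) rows <- integer(0)
      M <- M[rows, , drop = FALSE]
      if (role == "mean" || is.null(kin$leader)) {
        m <- rep(TRUE, nrow(M))
      } else {
        lead <- kin$leader[idx][rows]
        want <- if (role == "leader") a else setdiff(1:2, a)
        m <- !is.na(lead) & lead == want
      }
      series[[length(series) + 1L]] <- M
      mask[[length(mask) + 1L]] <- m
    }
  }
  list(series = series, mask = mask)
}

lag_grid <- function(ds, max_lag) {
  K <- floor(max_lag / ds$dt + 1e-9)
  seg_len <- lengths(segment_indices(ds))
  if (K >= max(seg_len))
    stop("max lag exceeds the length of every segment")
  0:K
}

#' Mean squared displacement
#'
#' `C_X(t) = <[u(t + t') - u(t')]^2>`, averaged over all reference times `t'`
#' within segments, all focal agents and all segments (stationarity assumed).
#' Units cm^2. For straight motion at speed v, `C_X(t) = v^2 t^2` exactly; for
#' confined motion it saturates.
#'
#' @param ds a [trajectory_dataset()].
#' @param max_lag largest lag evaluated, seconds (default 30).
#' @param role `"mean"`, `"leader"` or `"follower"`: restrict reference times
#'   to timesteps at which the focal agent holds that role (two-agent data).
#' @param kin optional precomputed [compute_kinematics()] result.
#' @return a `correlation_curve` with `C_X(0) = 0`.
#' @export
msd <- function(ds, max_lag = 30, role = "mean", kin = NULL) {
  if (ds$normalized) ds <- denormalize_positions(ds)
  if (is.null(kin)) kin <- compute_kinematics(ds)
  lags_steps <- lag_grid(ds, max_lag)
  rs <- role_series(ds, kin, "pos", role)
  eng <- correlation_engine(rs$series, rs$mask, lags_steps,
    function(A, B) rowSums((A - B)^2))
  correlation_curve("C_X", lags_steps * ds$dt, eng$values, eng$counts, role)
}

#' Velocity autocorrelation
#'
#' `C_V(t) = <v(t + t') . v(t')>` with backward-difference velocities; units
#' cm^2/s^2. `C_V(0)` equals the mean squared speed of the dataset.
#'
#' @inheritParams msd
#' @return a `correlation_curve`.
#' @export
velocity_autocorrelation <- function(ds, max_lag = 30, role = "mean", kin = NULL) {
  if (ds$normalized) ds <- denormalize_positions(ds)
  if (is.null(kin)) kin <- compute_kinematics(ds)
  lags_steps <- lag_grid(ds, max_lag)
  rs <- role_series(ds, kin, "vel", role)
  eng <- correlation_engine(rs$series, rs$mask, lags_steps,
    function(A, B) rowSums(A * B))
  correlation_curve("C_V", lags_steps * ds$dt, eng$values, eng$counts, role)
}

#' Wall-incidence autocorrelation
#'
#' `C_thetaw(t) = <cos[theta_w(t + t') - theta_w(t')]>`, dimensionless, equal
#' to 1 at lag 0 and bounded by 1 in magnitude.
#'
#' @inheritParams msd
#' @return a `correlation_curve`.
#' @export
thetaw_autocorrelation <- function(ds, max_lag = 30, role = "mean", kin = NULL) {
  if (ds$normalized) ds <- denormalize_positions(ds)
  if (is.null(kin)) kin <- compute_kinematics(ds)
  lags_steps <- lag_grid(ds, max_lag)
  rs <- role_series(ds, kin, "thetaw", role)
  eng <- correlation_engine(rs$series, rs$mask, lags_steps,
    function(A, B) cos(A[, 1] - B[, 1]))
  correlation_curve("C_thetaw", lags_steps * ds$dt, eng$values, eng$counts, role)
}

#' Full observable report of a two-agent dataset
#'
#' Computes the kinematics once and builds the nine observables under one
#' binning policy: PDFs of speed, wall distance (all/leader/follower), wall
#' incidence (all/leader/follower), inter-individual distance, relative
#' heading, viewing angle (leader/follower); correlation curves C_X, C_V,
#' C_thetaw (mean/leader/follower).
#'
#' @param ds a preprocessed two-agent [trajectory_dataset()].
#' @param policy a [binning_policy()].
#' @param max_lag largest correlation lag, seconds.
#' @param curves logical; set `FALSE` to skip the correlation curves.
#' @return object of class `observable_set`.
#' @export
observable_report <- function(ds, policy = binning_policy(tank_radius = ds$tank_radius),
                              max_lag = 30, curves = TRUE) {
  if (ds$normalized) ds <- denormalize_positions(ds)
  if (ds$n_agents != 2L) stop("observable_report requires a two-agent dataset")
  kin <- compute_kinematics(ds)
  v <- kin$valid
  lead <- kin$leader
  is_lead <- cbind(!is.na(lead) & lead == 1L, !is.na(lead) & lead == 2L)
  is_foll <- is_lead[, 2:1, drop = FALSE]
  pick <- function(M, sel) as.vector(M[sel])
  pdfs <- list(
    V = estimate_pdf(kin$speed[v, ], policy$V, "V"),
    r_w = list(
      all = estimate_pdf(kin$r_w[v, ], policy$r_w, "r_w"),
      leader = estimate_pdf(pick(kin$r_w, v & is_lead), policy$r_w, "r_w", "leader"),
      follower = estimate_pdf(pick(kin$r_w, v & is_foll), policy$r_w, "r_w", "follower")
    ),
    theta_w = list(
      all = estimate_pdf(kin$theta_w[v, ], policy$theta_w, "theta_w"),
      leader = estimate_pdf(pick(kin$theta_w, v & is_lead), policy$theta_w, "theta_w", "leader"),
      follower = estimate_pdf(pick(kin$theta_w, v & is_foll), policy$theta_w, "theta_w", "follower")
    ),
    d_ij = estimate_pdf(kin$d_ij[v], policy$d_ij, "d_ij"),
    phi_ij = estimate_pdf(c(kin$phi_ij[v], -kin$phi_ij[v]), policy$phi_ij, "phi_ij"),
    psi = list(
      leader = estimate_pdf(c(kin$psi_12[v & is_lead[, 1]], kin$psi_21[v & is_lead[, 2]]),
                            policy$psi, "psi", "leader"),
      follower = estimate_pdf(c(kin$psi_12[v & is_lead[, 2]], kin$psi_21[v & is_lead[, 1]]),
                              policy$psi, "psi", "follower")
    )
  )
  crv <- NULL
  if (curves) {
    crv <- list(
      C_X = lapply(c(mean = "mean", leader = "leader", follower = "follower"),
                   function(r) msd(ds, max_lag, r, kin)),
      C_V = lapply(c(mean = "mean", leader = "leader", follower = "follower"),
                   function(r) velocity_autocorrelation(ds, max_lag, r, kin)),
      C_thetaw = lapply(c(mean = "mean", leader = "leader", follower = "follower"),
                        function(r) thetaw_autocorrelation(ds, max_lag, r, kin))
    )
  }
  structure(list(pdfs = pdfs, curves = crv, policy_id = attr(policy, "id"),
                 policy = policy, n_samples = sum(v)),
            class = "observable_set")
}

#' @export
print.observable_set <- function(x, ...) {
  cat(sprintf("<observable_set> policy '%s', %d samples; PDFs: %s; curves: %s\n",
              x$policy_id, x$n_samples,
              paste(names(x$pdfs), collapse = ", "),
              if (is.null(x$curves)) "none" else paste(names(x$curves), collapse = ", ")))
  invisible(x)
}

# flatten the nested pdf list to named pdf_estimate entries
flatten_pdfs <- function(os) {
  out <- list()
  for (nm in names(os$pdfs)) {
    e <- os$pdfs[[nm]]
    if (inherits(e, "pdf_estimate")) {
      out[[nm]] <- e
    } else {
      for (r in names(e)) {
        key <- if (r == "all") nm else paste(nm, r, sep = "_")
        out[[key]] <- e[[r]]
      }
    }
  }
  out
}

#' Hellinger report: score a model dataset against a reference
#'
#' Computes the Hellinger distance between every PDF observable of the two
#' reports. Both must have been built under the same binning policy.
#'
#' @param reference,model [observable_report()] objects.
#' @return object of class `hellinger_report`: named numeric vector of
#'   distances in a list with the policy id.
#' @export
compare_observables <- function(reference, model) {
  if (!identical(reference$policy_id, model$policy_id))
    stop("observable sets were built under different binning policies")
  rp <- flatten_pdfs(reference)
  mp <- flatten_pdfs(model)
  common <- intersect(names(rp), names(mp))
  hd <- vapply(common, function(nm) hellinger(rp[[nm]], mp[[nm]]), numeric(1))
  structure(list(hd = hd, policy_id = reference$policy_id),
            class = "hellinger_report")
}

#' @export
print.hellinger_report <- function(x, ...) {
  cat(sprintf("<hellinger_report> policy '%s'\n", x$policy_id))
  print(round(x$hd, 4))
  invisible(x)
}

#' Serialize an observable set or Hellinger report to JSON
#'
#' @param x an `observable_set` or `hellinger_report`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
observables_to_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "hellinger_report")) {
    list(type = "hellinger_report", policy = x$policy_id, hd = as.list(x$hd))
  } else if (inherits(x, "observable_set")) {
    pd <- lapply(flatten_pdfs(x), function(p)
      list(edges = p$edges, density = p$density, counts = p$counts, n = p$n, role = p$role))
    cv <- NULL
    if (!is.null(x$curves)) {
      cv <- lapply(x$curves, function(group) lapply(group, function(cc)
        list(lags = cc$lags, values = cc$values, counts = cc$counts, role = cc$role)))
    }
    list(type = "observable_set", policy = x$policy_id, pdfs = pd, curves = cv)
  } else stop("unsupported object")
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Plot an observable set
#'
#' Draws the six PDFs (and optionally a second set overlaid) in a 2 x 3 panel
#' layout, mirroring the usual presentation of individual (top row) and
#' collective (bottom row) observables.
#'
#' @param x an `observable_set`.
#' @param y optional second `observable_set` drawn for comparison.
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.observable_set <- function(x, y = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  keys <- c("V", "r_w", "theta_w", "d_ij", "phi_ij", "psi_leader")
  xp <- flatten_pdfs(x)
  yp <- if (!is.null(y)) flatten_pdfs(y)
  for (k in keys) {
    p <- xp[[k]]
    mid <- (p$edges[-1] + p$edges[-length(p$edges)]) / 2
    ylim <- range(p$density, if (!is.null(yp)) yp[[k]]$density, 0)
    graphics::plot(mid, p$density, type = "l", xlab = p$variable,
                   ylab = "density", main = k, ylim = ylim)
    if (!is.null(yp)) graphics::lines(mid, yp[[k]]$density, col = 2)
  }
  invisible(x)
}
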