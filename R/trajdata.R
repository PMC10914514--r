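# Canonical trajectory container and the preprocessing pipeline applied to raw
# tracking tables before any feature extraction: inactivity filter, tracking-leap
# filter, gap interpolation, decimation to the working timestep, normalization.

#' Uniformly sampled multi-agent trajectory dataset
#'
#' The container every other part of the package consumes. Positions are planar,
#' tank-centred, in centimetres (unless `normalized = TRUE`, in which case they
#' have been divided by `tank_radius` and live in \[-1, 1\]). Sampling is uniform
#' with step `dt` inside every segment; segments mark contiguous valid stretches,
#' and filtering operations split them rather than bridging removed samples.
#'
#' @param t numeric vector of sample times in seconds.
#' @param pos numeric array of dimension `length(t) x 2 x n_agents`, x/y
#'   coordinates in cm (tank-centred).
#' @param segment integer vector of segment labels, one per sample; contiguous
#'   and non-decreasing. Defaults to a single segment.
#' @param dt time step in seconds; inferred from `t` when `NULL`.
#' @param tank_radius tank radius in cm (default 25).
#' @param body_length fish body length in cm (default 3.5).
#' @param normalized logical; `TRUE` when positions are in tank-radius units.
#' @param meta character vector of free-form provenance strings.
#'
#' @return An object of class `trajectory_dataset`.
#' @export
trajectory_dataset <- function(t, pos, segment = NULL, dt = NULL,
                               tank_radius = 25, body_length = 3.5,
                               normalized = FALSE, meta = character()) {
  t <- as.numeric(t)
  if (length(dim(pos)) == 2L) pos <- array(pos, dim = c(dim(pos), 1L))
  stopifnot(length(dim(pos)) == 3L, dim(pos)[2] == 2L, dim(pos)[1] == length(t))
  if (!all(is.finite(pos))) stop("all coordinates must be finite")
  if (is.null(segment)) segment <- rep.int(1L, length(t))
  segment <- as.integer(segment)
  stopifnot(length(segment) == length(t))
  if (is.null(dt)) {
    dts <- diff(t)[diff(segment) == 0L]
    if (!length(dts)) stop("cannot infer dt from a dataset without consecutive samples")
    # modal time difference: robust to isolated bad rows, which the
    # uniformity check then names
    r <- round(dts, 9)
    dt <- as.numeric(names(sort(table(r), decreasing = TRUE))[1])
  }
  ds <- structure(list(
    t = t, pos = pos, segment = segment, dt = dt,
    tank_radius = tank_radius, body_length = body_length,
    n_agents = dim(pos)[3], normalized = normalized, meta = as.character(meta)
  ), class = "trajectory_dataset")
  validate_trajectory_dataset(ds)
  ds
}

validate_trajectory_dataset <- function(ds) {
  segs <- segment_indices(ds)
  for (idx in segs) {
    if (length(idx) >= 2L) {
      dts <- diff(ds$t[idx])
      bad <- which(abs(dts - ds$dt) > 1e-6)
      if (length(bad)) {
        stop(sprintf("non-uniform dt at row %d", idx[bad[1] + 1L]))
      }
    }
  }
  invisible(ds)
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf(
    "<trajectory_dataset> %d agents, %d samples, %d segment(s), dt = %g s (%s)\n",
    x$n_agents, length(x$t), length(unique(x$segment)), x$dt,
    if (x$normalized) "normalized units" else "cm"
  ))
  cat(sprintf("  tank radius %g cm, body length %g cm, duration %.1f s\n",
              x$tank_radius, x$body_length, trajectory_duration(x)))
  if (length(x$meta)) cat("  meta:", paste(x$meta, collapse = "; "), "\n")
  invisible(x)
}

# list of integer index vectors, one per segment, in time order
segment_indices <- function(ds) {
  split(seq_along(ds$t), ds$segment)
}

#' Total simulated/recorded duration of a dataset
#'
#' Bookkeeping helper: the time spanned by the samples, counted as
#' `n_samples * dt` (each sample represents one timestep).
#'
#' @param ds a [trajectory_dataset()].
#' @param units `"seconds"` or `"hours"`.
#' @return numeric scalar.
#' @export
trajectory_duration <- function(ds, units = c("seconds", "hours")) {
  units <- match.arg(units)
  secs <- length(ds$t) * ds$dt
  if (units == "hours") secs / 3600 else secs
}

# Rebuild segment labels after dropping samples: a new segment starts wherever
# the kept samples are no longer dt-consecutive or crossed an old boundary.
rebuild_segments <- function(t, segment, dt) {
  n <- length(t)
  if (!n) return(integer(0))
  brk <- c(TRUE, abs(diff(t) - dt) > 1e-6 | diff(segment) != 0L)
  cumsum(brk)
}

drop_samples <- function(ds, drop) {
  keep <- !drop
  t <- ds$t[keep]
  seg <- rebuild_segments(t, ds$segment[keep], ds$dt)
  ds$t <- t
  ds$pos <- ds$pos[keep, , , drop = FALSE]
  ds$segment <- seg
  ds
}

#' Read a trajectory table from disk
#'
#' CSV dialect: header `t,x0,y0,x1,y1[,...][,segment]`, times in seconds,
#' coordinates in cm, tank-centred. The time step is inferred from the time
#' column and checked for uniformity (tolerance 1e-6 s) within each segment.
#'
#' @param path file path.
#' @param dialect `"csv"` (the canonical interchange format). An `"hdf5"`
#'   dialect token is reserved but not available in this build.
#' @param tank_radius,body_length arena metadata in cm.
#' @return a [trajectory_dataset()].
#' @export
read_trajectories <- function(path, dialect = c("csv", "hdf5"),
                              tank_radius = 25, body_length = 3.5) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5")
    stop("unsupported dialect 'hdf5': no HDF5 reader is available; use the CSV dialect")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("missing required column 't'")
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
  n_agents <- length(xcols)
  if (n_agents == 0L || length(ycols) != n_agents)
    stop("missing coordinate columns: need x0,y0[,x1,y1,...]")
  ord <- order(as.integer(sub("^x", "", xcols)))
  xcols <- xcols[ord]
  ycols <- paste0("y", sub("^x", "", xcols))
  if (!all(ycols %in% names(df))) stop("missing coordinate columns: x/y pairs must match")
  pos <- array(NA_real_, dim = c(nrow(df), 2L, n_agents))
  for (a in seq_len(n_agents)) {
    pos[, 1, a] <- df[[xcols[a]]]
    pos[, 2, a] <- df[[ycols[a]]]
  }
  segment <- if ("segment" %in% names(df)) as.integer(df$segment) else NULL
  trajectory_dataset(df$t, pos, segment = segment,
                     tank_radius = tank_radius, body_length = body_length,
                     meta = paste0("read:", basename(path)))
}

#' Write a trajectory dataset to the canonical CSV format
#'
#' @param ds a [trajectory_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ds, path) {
  n <- ds$n_agents
  cols <- list(t = sprintf("%.12g", ds$t))
  for (a in seq_len(n)) {
    cols[[paste0("x", a - 1L)]] <- sprintf("%.12g", ds$pos[, 1, a])
    cols[[paste0("y", a - 1L)]] <- sprintf("%.12g", ds$pos[, 2, a])
  }
  cols$segment <- ds$segment
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# backward-difference speed per sample and agent; NA on the first sample of
# each segment (no previous frame)
backward_speeds <- function(ds) {
  n <- length(ds$t)
  sp <- matrix(NA_real_, n, ds$n_agents)
  for (idx in segment_indices(ds)) {
    if (length(idx) < 2L) next
    for (a in seq_len(ds$n_agents)) {
      d <- ds$pos[idx[-1], , a, drop = FALSE] - ds$pos[idx[-length(idx)], , a, drop = FALSE]
      sp[idx[-1], a] <- sqrt(d[, 1, 1]^2 + d[, 2, 1]^2) / ds$dt
    }
  }
  sp
}

#' Remove inactive samples
#'
#' Drops every sample at which the backward-difference speed of any agent falls
#' below `v_min` (default one body length per second). Removals split segments;
#' the removed spans are flagged so that [interpolate_gaps()] never bridges a
#' behavioural pause.
#'
#' @param ds a [trajectory_dataset()].
#' @param v_min speed threshold, cm/s.
#' @return filtered dataset.
#' @export
filter_inactive <- function(ds, v_min = ds$body_length) {
  if (length(ds$t) < 2L) stop("dataset must contain at least 2 samples")
  if (v_min <= 0) return(ds)
  sp <- backward_speeds(ds)
  slow <- apply(sp < v_min, 1L, any)
  slow[is.na(slow)] <- FALSE
  removed <- ds$t[slow]
  out <- drop_samples(ds, slow)
  out$meta <- c(out$meta, sprintf("filter_inactive:v_min=%g,removed=%d", v_min, sum(slow)))
  attr(out, "nobridge") <- c(attr(ds, "nobridge"), removed)
  out
}

#' Remove tracking leaps
#'
#' Drops samples whose displacement from the previous frame exceeds `max_step`
#' (strictly greater) for any agent; such jumps are tracking errors, not motion.
#' Removals split segments, and the resulting short holes are candidates for
#' [interpolate_gaps()].
#'
#' @param ds a [trajectory_dataset()].
#' @param max_step displacement threshold in cm (default 1.5 body lengths).
#' @return filtered dataset.
#' @export
filter_leaps <- function(ds, max_step = 1.5 * ds$body_length) {
  n <- length(ds$t)
  disp <- matrix(NA_real_, n, ds$n_agents)
  for (idx in segment_indices(ds)) {
    if (length(idx) < 2L) next
    for (a in seq_len(ds$n_agents)) {
      d <- ds$pos[idx[-1], , a, drop = FALSE] - ds$pos[idx[-length(idx)], , a, drop = FALSE]
      disp[idx[-1], a] <- sqrt(d[, 1, 1]^2 + d[, 2, 1]^2)
    }
  }
  leap <- apply(disp > max_step, 1L, any)
  leap[is.na(leap)] <- FALSE
  out <- drop_samples(ds, leap)
  out$meta <- c(out$meta, sprintf("filter_leaps:max_step=%g,removed=%d", max_step, sum(leap)))
  attr(out, "nobridge") <- attr(ds, "nobridge")
  out
}

#' Fill short holes by linear interpolation
#'
#' Bridges holes of at most `max_gap` missing frames between consecutive
#' segments, filling each coordinate linearly, and merges the segments. Holes
#' longer than `max_gap`, and holes produced by the inactivity filter (a
#' behavioural pause, not a tracking error), remain segment boundaries.
#'
#' @param ds a [trajectory_dataset()].
#' @param max_gap maximum bridgeable hole, in frames (default 12).
#' @return dataset with short holes filled.
#' @export
interpolate_gaps <- function(ds, max_gap = 12L) {
  nobridge <- attr(ds, "nobridge")
  segs <- segment_indices(ds)
  if (length(segs) < 2L) return(ds)
  t_new <- list(); p_new <- list(); s_new <- list()
  seg_id <- 1L
  filled <- 0L
  # walk segments in time order, deciding for each junction whether to bridge
  for (k in seq_along(segs)) {
    idx <- segs[[k]]
    if (k > 1L) {
      prev_end <- segs[[k - 1L]][length(segs[[k - 1L]])]
      ta <- ds$t[prev_end]; tb <- ds$t[idx[1]]
      g <- round((tb - ta) / ds$dt) - 1L
      hole_paused <- length(nobridge) &&
        any(nobridge > ta + 1e-9 & nobridge < tb - 1e-9)
      if (g >= 1L && g <= max_gap && !hole_paused) {
        tt <- ta + ds$dt * seq_len(g)
        w <- seq_len(g) / (g + 1L)
        fill <- array(NA_real_, dim = c(g, 2L, ds$n_agents))
        for (a in seq_len(ds$n_agents)) for (cc in 1:2) {
          fill[, cc, a] <- ds$pos[prev_end, cc, a] * (1 - w) + ds$pos[idx[1], cc, a] * w
        }
        t_new[[length(t_new) + 1L]] <- tt
        p_new[[length(p_new) + 1L]] <- fill
        s_new[[length(s_new) + 1L]] <- rep.int(seg_id, g)
        filled <- filled + g
      } else {
        seg_id <- seg_id + 1L
      }
    }
    t_new[[length(t_new) + 1L]] <- ds$t[idx]
    p_new[[length(p_new) + 1L]] <- ds$pos[idx, , , drop = FALSE]
    s_new[[length(s_new) + 1L]] <- rep.int(seg_id, length(idx))
  }
  pos <- array(NA_real_, dim = c(sum(lengths(t_new)), 2L, ds$n_agents))
  at <- 0L
  for (b in seq_along(p_new)) {
    nb <- dim(p_new[[b]])[1]
    pos[at + seq_len(nb), , ] <- p_new[[b]]
    at <- at + nb
  }
  out <- trajectory_dataset(unlist(t_new), pos, segment = unlist(s_new), dt = ds$dt,
                            tank_radius = ds$tank_radius, body_length = ds$body_length,
                            normalized = ds$normalized,
                            meta = c(ds$meta, sprintf("interpolate_gaps:max_gap=%d,filled=%d",
                                                      as.integer(max_gap), filled)))
  attr(out, "nobridge") <- nobridge
  out
}

#' Decimate a dataset to a coarser timestep
#'
#' Keeps every k-th frame per segment (k = `target_dt / dt`, which must be an
#' integer), starting at the segment's first frame. Positions are preserved
#' exactly; no averaging is performed.
#'
#' @param ds a [trajectory_dataset()].
#' @param target_dt new timestep in seconds; integer multiple of `ds$dt`.
#' @return decimated dataset.
#' @export
resample_trajectories <- function(ds, target_dt) {
  ratio <- target_dt / ds$dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("target_dt must be an integer multiple of dt (ratio %g)", ratio))
  k <- as.integer(round(ratio))
  if (k == 1L) return(ds)
  keep <- logical(length(ds$t))
  for (idx in segment_indices(ds)) keep[idx[seq(1L, length(idx), by = k)]] <- TRUE
  out <- ds
  out$t <- ds$t[keep]
  out$pos <- ds$pos[keep, , , drop = FALSE]
  out$segment <- ds$segment[keep]
  out$dt <- target_dt
  out$meta <- c(out$meta, sprintf("resample:dt=%g", target_dt))
  validate_trajectory_dataset(out)
  out
}

#' Normalize / denormalize positions by the tank radius
#'
#' `normalize_positions()` divides all coordinates by `tank_radius`, mapping the
#' tank to the unit disc (the range fed to the network); `denormalize_positions()`
#' inverts it. The two are exact inverses.
#'
#' @param ds a [trajectory_dataset()].
#' @return dataset with the `normalized` flag toggled.
#' @export
normalize_positions <- function(ds) {
  if (ds$normalized) stop("dataset is already normalized")
  ds$pos <- ds$pos / ds$tank_radius
  ds$normalized <- TRUE
  ds
}

#' @rdname normalize_positions
#' @export
denormalize_positions <- function(ds) {
  if (!ds$normalized) stop("dataset is not normalized")
  ds$pos <- ds$pos * ds$tank_radius
  ds$normalized <- FALSE
  ds
}

#' Full preprocessing pipeline
#'
#' Applies, in order: inactivity filter, tracking-leap filter, gap
#' interpolation, decimation to `target_dt`. The order is recorded in `meta`.
#'
#' @param ds a [trajectory_dataset()].
#' @param v_min inactivity threshold, cm/s.
#' @param max_step leap threshold, cm.
#' @param max_gap maximum bridgeable hole, frames.
#' @param target_dt working timestep, s (default 0.12); `NULL` to skip.
#' @return preprocessed dataset.
#' @export
preprocess_trajectories <- function(ds, v_min = ds$body_length,
                                    max_step = 1.5 * ds$body_length,
                                    max_gap = 12L, target_dt = 0.12) {
  out <- filter_inactive(ds, v_min)
  out <- filter_leaps(out, max_step)
  out <- interpolate_gaps(out, max_gap)
  if (!is.null(target_dt) && abs(target_dt - out$dt) > 1e-12)
    out <- resample_trajectories(out, target_dt)
  out$meta <- c(out$meta, "preprocess:inactivity>leaps>interpolation>resampling")
  out
}
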