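# The deep-learning interaction model: state/history construction, the
# recurrent probabilistic network (trained in C++), sampling and integration,
# closed-loop rollout with wall rejection, survival experiments, and the
# influential-neighbour extension to groups larger than two.

#' Network architecture configuration
#'
#' Two LSTM layers and five dense layers. The full-size architecture uses a
#' 256-unit first LSTM; the dense widths descend, a second LSTM scales back
#' up, and a two-layer dense head reduces to the 4-dimensional output
#' (mu_x, mu_y and the raw values mapped to sigma_x, sigma_y through a
#' softplus, which keeps both standard deviations strictly positive). All
#' widths are configurable; reduced widths train much faster with only a
#' modest fidelity cost on synthetic data.
#'
#' @param lstm1,dense1,dense2,lstm2,head1,head2 layer widths.
#' @param history history length (number of past system states fed in).
#' @return object of class `dli_network_config`.
#' @export
dli_network_config <- function(lstm1 = 256L, dense1 = 128L, dense2 = 64L,
                               lstm2 = 128L, head1 = 64L, head2 = 32L,
                               history = 5L) {
  stopifnot(history >= 1L, lstm1 > 0, dense1 > 0, dense2 > 0,
            lstm2 > 0, head1 > 0, head2 > 0)
  structure(list(lstm1 = as.integer(lstm1), dense1 = as.integer(dense1),
                 dense2 = as.integer(dense2), lstm2 = as.integer(lstm2),
                 head1 = as.integer(head1), head2 = as.integer(head2),
                 history = as.integer(history), output = 4L),
            class = "dli_network_config")
}

#' Training configuration
#'
#' Adam with a time-decaying learning rate; the dataset is split into
#' contiguous 80/15/5 train/validation/test blocks (contiguity prevents
#' leakage between overlapping history windows), and shuffling happens within
#' the training block only.
#'
#' @param epochs training epochs (default 45).
#' @param batch batch size (default 512).
#' @param lr initial learning rate (default 1e-4).
#' @param lr_decay multiplicative decay per epoch (default 0.95).
#' @param split train/validation/test fractions, summing to 1.
#' @param augment both-orderings augmentation: each timestep contributes one
#'   sample per agent as focal (default `TRUE`).
#' @param clip global-norm gradient clip (0 disables).
#' @return object of class `dli_train_config`.
#' @export
dli_train_config <- function(epochs = 45L, batch = 512L, lr = 1e-4,
                             lr_decay = 0.95, split = c(0.80, 0.15, 0.05),
                             augment = TRUE, clip = 5) {
  stopifnot(abs(sum(split) - 1) < 1e-9, length(split) == 3L, epochs >= 1L)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, lr_decay = lr_decay, split = split,
                 augment = isTRUE(augment), clip = clip),
            class = "dli_train_config")
}

# one 11-dim system state per (time, focal) in normalized units
# (u_i, v_i, rw_i, u_j, v_j, rw_j, d_ij)
state_block <- function(u, v, focal) {
  other <- 3L - focal
  rw <- function(a) 1 - sqrt(u[, 1, a]^2 + u[, 2, a]^2)
  d <- sqrt((u[, 1, focal] - u[, 1, other])^2 + (u[, 2, focal] - u[, 2, other])^2)
  cbind(u[, 1, focal], u[, 2, focal], v[, 1, focal], v[, 2, focal], rw(focal),
        u[, 1, other], u[, 2, other], v[, 1, other], v[, 2, other], rw(other), d)
}

#' Build the supervised training set from a two-agent dataset
#'
#' Sliding windows of `history` consecutive 11-dimensional system states per
#' focal agent; the target is the focal agent's next-step acceleration
#' `(v(t + dt) - v(t)) / dt`. Positions are normalized by the tank radius,
#' velocities by radius per second, accelerations by radius per second
#' squared. Windows never straddle segment boundaries; segments shorter than
#' `history + 2` samples are skipped.
#'
#' @param ds a two-agent [trajectory_dataset()].
#' @param history history length (default 5).
#' @param augment both-orderings augmentation (default `TRUE`).
#' @return list with `x` (K x history x 11 array), `y` (K x 2 matrix), `dt`,
#'   `tank_radius`, and `skipped` (number of too-short segments).
#' @export
build_training_set <- function(ds, history = 5L, augment = TRUE) {
  if (ds$n_agents != 2L) stop("build_training_set requires a two-agent dataset")
  if (!ds$normalized) ds <- normalize_positions(ds)
  need <- history + 2L   # history states + target step + one step for velocity
  xs <- list(); ys <- list()
  skipped <- 0L
  for (idx in segment_indices(ds)) {
    L <- length(idx)
    if (L < need) { skipped <- skipped + 1L; next }
    u <- ds$pos[idx, , , drop = FALSE]
    v <- (u[-1, , , drop = FALSE] - u[-L, , , drop = FALSE]) / ds$dt
    uv <- u[-1, , , drop = FALSE]   # positions aligned with velocities
    Lv <- L - 1L
    nwin <- Lv - history            # windows ending at m = history..Lv-1
    focals <- if (augment) 1:2 else 1L
    for (f in focals) {
      S <- state_block(uv, v, f)    # Lv x 11
      a <- (v[-1, , f, drop = TRUE] - v[-Lv, , f, drop = TRUE]) / ds$dt
      X <- array(NA_real_, dim = c(nwin, history, 11L))
      for (h in seq_len(history)) X[, h, ] <- S[(h):(h + nwin - 1L), ]
      xs[[length(xs) + 1L]] <- X
      ys[[length(ys) + 1L]] <- a[history:(Lv - 1L), , drop = FALSE]
    }
  }
  if (!length(xs)) stop("no segment is long enough to build training windows")
  x <- do.call(abind_1, xs)
  y <- do.call(rbind, ys)
  list(x = x, y = y, dt = ds$dt, tank_radius = ds$tank_radius, skipped = skipped)
}

# minimal abind along dim 1 for 3-d arrays
abind_1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(NA_real_, dim = c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

# Glorot-uniform initial weights; forget-gate biases start at 1
dli_init_weights <- function(cfg) {
  gl <- function(nr, nc) {
    a <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -a, a), nr, nc)
  }
  lstm_b <- function(h) {
    b <- matrix(0, 4 * h, 1)
    b[(h + 1):(2 * h), 1] <- 1
    b
  }
  list(
    Wx1 = gl(4 * cfg$lstm1, 11L), Wh1 = gl(4 * cfg$lstm1, cfg$lstm1),
    b1 = lstm_b(cfg$lstm1),
    Wd1 = gl(cfg$dense1, cfg$lstm1), bd1 = matrix(0, cfg$dense1, 1),
    Wd2 = gl(cfg$dense2, cfg$dense1), bd2 = matrix(0, cfg$dense2, 1),
    Wx2 = gl(4 * cfg$lstm2, cfg$dense2), Wh2 = gl(4 * cfg$lstm2, cfg$lstm2),
    b2 = lstm_b(cfg$lstm2),
    We1 = gl(cfg$head1, cfg$lstm2), be1 = matrix(0, cfg$head1, 1),
    We2 = gl(cfg$head2, cfg$head1), be2 = matrix(0, cfg$head2, 1),
    Wo = gl(4L, cfg$head2), bo = matrix(0, 4L, 1)
  )
}

# K x history x 11 array -> 11 x K x history cube layout used by the C++ core
to_cube <- function(x) aperm(x, c(3, 1, 2))

#' Evaluate the network on one or more histories
#'
#' Deterministic forward pass mapping each 5 x 11 history matrix to a
#' diagonal-Gaussian acceleration distribution.
#'
#' @param model a fitted `"dli"` object, or a raw weight list.
#' @param history a single `history x 11` matrix or a `K x history x 11`
#'   array (normalized units, rows oldest first).
#' @return data.frame with columns `mu_x, mu_y, sigma_x, sigma_y` (normalized
#'   acceleration units); one row per history.
#' @export
model_forward <- function(model, history) {
  w <- if (inherits(model, "dli")) model$weights else model
  sc <- if (inherits(model, "dli") && !is.null(model$target_scale))
    model$target_scale else c(1, 1)
  if (is.matrix(history)) history <- array(history, dim = c(1L, dim(history)))
  out <- cpp_dli_forward(w, to_cube(history))
  if (!all(is.finite(out))) stop("non-finite network activations")
  data.frame(mu_x = out[1, ] * sc[1], mu_y = out[2, ] * sc[2],
             sigma_x = out[3, ] * sc[1], sigma_y = out[4, ] * sc[2])
}

#' Gaussian negative log-likelihood of acceleration predictions
#'
#' Per-sample diagonal-Gaussian NLL
#' `0.5 * eps' C^-1 eps + 0.5 * log det C` with `C = diag(sigma_x^2,
#' sigma_y^2)` and `eps` the prediction error, averaged over the batch when
#' `reduce = TRUE`. This is the training loss of the network.
#'
#' @param mu K x 2 matrix (or data.frame from [model_forward()]).
#' @param sigma K x 2 matrix of standard deviations (> 0).
#' @param targets K x 2 matrix of observed accelerations.
#' @param reduce return the batch mean (default) or per-sample values.
#' @return scalar or numeric vector.
#' @export
nll_loss <- function(mu, sigma, targets, reduce = TRUE) {
  if (is.data.frame(mu) && all(c("mu_x", "sigma_x") %in% names(mu))) {
    sigma <- cbind(mu$sigma_x, mu$sigma_y)
    mu <- cbind(mu$mu_x, mu$mu_y)
  }
  mu <- as.matrix(mu); sigma <- as.matrix(sigma); targets <- as.matrix(targets)
  stopifnot(all(dim(mu) == dim(targets)), all(dim(sigma) == dim(mu)))
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  l <- as.numeric(cpp_dli_nll(t(mu), t(sigma), t(targets)))
  if (reduce) mean(l) else l
}

#' Sample an acceleration from a Gaussian prediction
#'
#' `a = mu + sigma * g` with independent standard-normal `g` per component
#' (each component scaled by its own standard deviation).
#'
#' @param pred one-row data.frame from [model_forward()] or a list with `mu`
#'   and `sigma` length-2 vectors.
#' @param n number of draws.
#' @return n x 2 matrix of accelerations.
#' @export
sample_acceleration <- function(pred, n = 1L) {
  if (is.data.frame(pred)) {
    mu <- c(pred$mu_x[1], pred$mu_y[1]); sg <- c(pred$sigma_x[1], pred$sigma_y[1])
  } else {
    mu <- pred$mu; sg <- pred$sigma
  }
  g <- matrix(stats::rnorm(2L * n), n, 2L)
  sweep(g, 2L, sg, `*`) + matrix(mu, n, 2L, byrow = TRUE)
}

#' Semi-implicit state update
#'
#' Velocity first, then position with the new velocity:
#' `v' = v + dt * a`, `u' = u + dt * v'`.
#'
#' @param u,v,a length-2 position, velocity and acceleration vectors.
#' @param dt timestep (s).
#' @return list with `u` and `v`.
#' @export
integrate_state <- function(u, v, a, dt) {
  v2 <- v + dt * a
  list(u = u + dt * v2, v = v2)
}

#' Fit the deep-learning interaction model
#'
#' Builds the supervised set from a two-agent trajectory dataset, splits it
#' into contiguous train/validation/test blocks, and trains the recurrent
#' probabilistic network by Adam on the Gaussian negative log-likelihood.
#' Deterministic given `seed`.
#'
#' @param ds a preprocessed two-agent [trajectory_dataset()].
#' @param net a [dli_network_config()].
#' @param train a [dli_train_config()].
#' @param seed RNG seed for weight initialization and shuffling.
#' @param verbose print per-epoch losses.
#' @return object of class `dli`: weights, configs, learning curves
#'   (`$curves`: data.frame epoch/train/validation), held-out test loss,
#'   normalization constants.
#' @export
fit_dli <- function(ds, net = dli_network_config(), train = dli_train_config(),
                    seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  tset <- build_training_set(ds, history = net$history, augment = train$augment)
  K <- dim(tset$x)[1]
  n_tr <- floor(train$split[1] * K)
  n_val <- floor(train$split[2] * K)
  if (n_tr < 1L || K - n_tr - n_val < 0L) stop("dataset too small for the requested split")
  i_tr <- seq_len(n_tr)
  i_val <- seq.int(n_tr + 1L, n_tr + n_val)
  i_te <- if (n_tr + n_val < K) seq.int(n_tr + n_val + 1L, K) else integer(0)
  # standardize the acceleration targets per component: identical likelihood
  # up to an additive constant, but keeps the first optimizer steps from
  # saturating the recurrent stack when accelerations are numerically large
  target_scale <- pmax(apply(tset$y[i_tr, , drop = FALSE], 2, stats::sd), 1e-12)
  ys <- sweep(tset$y, 2L, target_scale, `/`)
  w0 <- dli_init_weights(net)
  fit <- cpp_dli_train(w0,
                       to_cube(tset$x[i_tr, , , drop = FALSE]), t(ys[i_tr, , drop = FALSE]),
                       to_cube(tset$x[i_val, , , drop = FALSE]), t(ys[i_val, , drop = FALSE]),
                       train$epochs, train$batch, train$lr, train$lr_decay,
                       train$clip, verbose)
  test_loss <- NA_real_
  if (length(i_te)) {
    pred <- model_forward(fit$weights, tset$x[i_te, , , drop = FALSE])
    test_loss <- nll_loss(pred, targets = ys[i_te, , drop = FALSE])
  }
  structure(list(
    weights = fit$weights, net = net, train = train,
    target_scale = target_scale,
    curves = data.frame(epoch = seq_len(train$epochs),
                        train = as.numeric(fit$train_loss),
                        validation = as.numeric(fit$val_loss)),
    test_loss = test_loss,
    norm = list(tank_radius = tset$tank_radius, dt = tset$dt),
    n_samples = K, body_length = ds$body_length,
    call = match.call()
  ), class = "dli")
}

n_weights <- function(w) sum(vapply(w, length, integer(1)))

#' @export
print.dli <- function(x, ...) {
  cat(sprintf("<dli> recurrent probabilistic interaction model (%d parameters)\n",
              n_weights(x$weights)))
  cat(sprintf("  architecture: LSTM(%d) > %d > %d > LSTM(%d) > %d > %d > 4; history %d\n",
              x$net$lstm1, x$net$dense1, x$net$dense2, x$net$lstm2,
              x$net$head1, x$net$head2, x$net$history))
  cat(sprintf("  trained %d epochs on %d samples; final val NLL %.4f; test NLL %.4f\n",
              x$train$epochs, x$n_samples,
              utils::tail(x$curves$validation, 1), x$test_loss))
  invisible(x)
}

#' @export
summary.dli <- function(object, ...) {
  out <- list(parameters = n_weights(object$weights),
              n_samples = object$n_samples,
              final_train = utils::tail(object$curves$train, 1),
              final_validation = utils::tail(object$curves$validation, 1),
              test_loss = object$test_loss, net = object$net,
              train = object$train)
  class(out) <- "summary.dli"
  out
}

#' @export
print.summary.dli <- function(x, ...) {
  cat("Deep-learning interaction model\n")
  cat(sprintf("  parameters: %d, training samples: %d\n", x$parameters, x$n_samples))
  cat(sprintf("  NLL: train %.4f, validation %.4f, test %.4f\n",
              x$final_train, x$final_validation, x$test_loss))
  invisible(x)
}

#' @export
coef.dli <- function(object, ...) object$weights

#' @export
plot.dli <- function(x, ...) {
  graphics::matplot(x$curves$epoch, cbind(x$curves$train, x$curves$validation),
                    type = "l", lty = 1, col = c(1, 2),
                    xlab = "epoch", ylab = "mean NLL", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1, col = c(1, 2))
  invisible(x)
}

#' One-step-ahead predictions on a dataset
#'
#' @param object a fitted `"dli"`.
#' @param newdata a two-agent [trajectory_dataset()], or a `K x history x 11`
#'   array of prepared histories.
#' @param ... unused.
#' @return data.frame `mu_x, mu_y, sigma_x, sigma_y` plus, for dataset input,
#'   the observed targets `a_x, a_y` (all in normalized units).
#' @export
predict.dli <- function(object, newdata, ...) {
  if (inherits(newdata, "trajectory_dataset")) {
    tset <- build_training_set(newdata, history = object$net$history,
                               augment = object$train$augment)
    pred <- model_forward(object, tset$x)
    pred$a_x <- tset$y[, 1]
    pred$a_y <- tset$y[, 2]
    pred
  } else {
    model_forward(object, newdata)
  }
}

#' One-step prediction residuals
#'
#' `eps = a_observed - mu_predicted` per component, in normalized units;
#' standardized residuals divide by the predicted sigma.
#'
#' @param object a fitted `"dli"`.
#' @param newdata a two-agent [trajectory_dataset()].
#' @param standardized divide by the predicted standard deviations.
#' @param ... unused.
#' @return K x 2 matrix of residuals.
#' @export
residuals.dli <- function(object, newdata, standardized = FALSE, ...) {
  pred <- predict(object, newdata)
  eps <- cbind(pred$a_x - pred$mu_x, pred$a_y - pred$mu_y)
  if (standardized) eps <- eps / cbind(pred$sigma_x, pred$sigma_y)
  colnames(eps) <- c("x", "y")
  eps
}

# sample a 6-frame initial window (both agents jointly) from a dataset,
# returned as a 6 x 2 x 2 array in normalized units
sample_init_window <- function(ds, history = 5L) {
  if (!ds$normalized) ds <- normalize_positions(ds)
  need <- history + 1L
  segs <- Filter(function(idx) length(idx) >= need, segment_indices(ds))
  if (!length(segs)) stop("no segment long enough to draw an initial history")
  idx <- segs[[sample.int(length(segs), 1L)]]
  at <- sample.int(length(idx) - need + 1L, 1L)
  ds$pos[idx[at:(at + need - 1L)], , , drop = FALSE]
}

#' Closed-loop rollout of a fitted model
#'
#' Both agents carry a copy of the network; at each timestep each predicts its
#' own acceleration distribution (itself as focal), samples, and integrates.
#' With rejection enabled, moves ending outside the tank redraw the Gaussian
#' variates up to `cap` attempts at the predicted standard deviations; if all
#' fail (a trap state the model was never trained on, where the predicted
#' distribution may put essentially no mass inside the tank), the proposal is
#' progressively widened -- sigma doubled per further block of `cap` draws,
#' bounded so the one-step displacement scale never exceeds half the tank
#' radius -- before the rollout gives up with an error.
#'
#' @param model a fitted `"dli"`.
#' @param steps number of timesteps.
#' @param init a [trajectory_dataset()] to sample the initial 5-step history
#'   from, or a `6 x 2 x 2` array of normalized positions.
#' @param rejection enforce the wall by rejection sampling (default `TRUE`).
#' @param cap rejection attempts per step and agent (default 100).
#' @param stop_margin stop early once any agent is farther than
#'   `(1 + stop_margin) * R` from the centre; `NULL` never stops (used with
#'   `rejection = FALSE` in survival runs).
#' @param seed optional RNG seed.
#' @return a [trajectory_dataset()] (cm units) with attribute
#'   `"escaped_step"` (0 when no agent left the tank).
#' @export
dli_rollout <- function(model, steps, init, rejection = TRUE, cap = 100L,
                        stop_margin = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- model$norm$tank_radius
  dt <- model$norm$dt
  win <- if (inherits(init, "trajectory_dataset"))
    sample_init_window(init, model$net$history) else init
  stopifnot(length(dim(win)) == 3L, dim(win)[1] == model$net$history + 1L)
  sc <- if (!is.null(model$target_scale)) model$target_scale else c(1, 1)
  res <- cpp_dli_rollout(model$weights, win, dt, as.integer(steps),
                         isTRUE(rejection), as.integer(cap),
                         if (is.null(stop_margin)) -1 else stop_margin, sc)
  pos <- res$pos * R
  n <- dim(pos)[1]
  ds <- trajectory_dataset(seq_len(n) * dt, pos, dt = dt, tank_radius = R,
                           body_length = model$body_length,
                           meta = sprintf("dli_rollout:steps=%d,rejection=%s",
                                          as.integer(steps), rejection))
  attr(ds, "escaped_step") <- res$escaped_step
  ds
}

#' Simulate method for the fitted interaction model
#'
#' Convention-following wrapper around [dli_rollout()].
#'
#' @param object a fitted `"dli"`.
#' @param nsim number of rollouts.
#' @param seed optional RNG seed.
#' @param steps timesteps per rollout.
#' @param init initial-history source (see [dli_rollout()]).
#' @param rejection enforce the wall (default `TRUE`).
#' @param ... passed to [dli_rollout()].
#' @return a [trajectory_dataset()] or a list of them.
#' @export
simulate.dli <- function(object, nsim = 1, seed = NULL, steps = 5000L,
                         init, rejection = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(nsim), function(i)
    dli_rollout(object, steps, init, rejection = rejection, ...))
  if (nsim == 1) runs[[1]] else runs
}

#' Wall-learning survival experiment
#'
#' Runs `n_runs` rollouts with the rejection procedure disabled and records,
#' per run, the first time any agent is farther than `margin` cm beyond the
#' wall (runs that never escape within `horizon` seconds are censored). The
#' survival curve is the fraction of runs still inside at each time.
#'
#' @param model a fitted `"dli"`.
#' @param n_runs number of independent runs.
#' @param horizon run length, seconds.
#' @param margin escape margin beyond the wall, cm (default 1: "in or very
#'   near the tank").
#' @param init initial-history source (a [trajectory_dataset()]).
#' @param seed optional RNG seed.
#' @return object of class `survival_result`: data.frame of per-run escape
#'   times (`NA` = censored), and the survival curve (`$curve`: time,
#'   fraction).
#' @export
survival_experiment <- function(model, n_runs, horizon, margin = 1,
                                init, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- model$norm$dt
  steps <- ceiling(horizon / dt)
  escape <- rep(NA_real_, n_runs)
  for (r in seq_len(n_runs)) {
    ds <- dli_rollout(model, steps, init, rejection = FALSE,
                      stop_margin = margin / model$norm$tank_radius)
    es <- attr(ds, "escaped_step")
    if (es > 0) escape[r] <- es * dt
  }
  tt <- seq(0, horizon, by = max(dt * 10, 1))
  frac <- vapply(tt, function(s) mean(is.na(escape) | escape > s), numeric(1))
  structure(list(escape_time = escape, horizon = horizon, margin = margin,
                 curve = data.frame(time = tt, fraction = frac)),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("<survival_result> %d runs, horizon %.0f s: %d survived, %d escaped\n",
              length(x$escape_time), x$horizon,
              sum(is.na(x$escape_time)), sum(!is.na(x$escape_time))))
  if (any(!is.na(x$escape_time)))
    cat(sprintf("  mean escape time %.0f s\n", mean(x$escape_time, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.survival_result <- function(x, ...) {
  graphics::plot(x$curve$time, x$curve$fraction, type = "s", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "fraction of runs inside", ...)
  invisible(x)
}

# rank neighbours by |mu| of the predicted acceleration, keep the k largest,
# aggregate as mean of mu and root-mean-square of sigma
aggregate_influential <- function(mu, sigma, k) {
  strength <- sqrt(rowSums(mu^2))
  keep <- order(strength, decreasing = TRUE)[seq_len(min(k, nrow(mu)))]
  list(mu = colMeans(mu[keep, , drop = FALSE]),
       sigma = sqrt(colMeans(sigma[keep, , drop = FALSE]^2)))
}

#' Group rollout with influential-neighbour selection
#'
#' Extends the trained pair model to `n_agents > 2` without retraining: at
#' each step and for each focal agent, the pair network is evaluated against
#' every neighbour, neighbours are ranked by the magnitude of the predicted
#' mean acceleration `|mu|`, the `k_influential` largest are kept, and their
#' predictions are aggregated (mean of mu, root-mean-square of sigma) before
#' sampling and integration.
#'
#' @param model a fitted `"dli"`.
#' @param n_agents group size (> 2; `n_agents = 2` reduces to [dli_rollout()]).
#' @param steps number of timesteps.
#' @param init a [trajectory_dataset()] used to draw each agent's initial
#'   history (agents draw independent windows), or a
#'   `(history + 1) x 2 x m` array of normalized positions recycled over
#'   agents.
#' @param k_influential neighbours retained per focal agent (default 2).
#' @param rejection,cap wall rejection as in [dli_rollout()].
#' @param seed optional RNG seed.
#' @return a [trajectory_dataset()] with `n_agents` agents.
#' @export
multi_agent_rollout <- function(model, n_agents, steps, init,
                                k_influential = 2L, rejection = TRUE,
                                cap = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_agents < 2L) stop("n_agents must be at least 2")
  Rt <- model$norm$tank_radius
  dt <- model$norm$dt
  Th <- model$net$history
  # initial positions/velocities per agent from independent windows
  u <- matrix(NA_real_, n_agents, 2L)
  v <- matrix(NA_real_, n_agents, 2L)
  upast <- array(NA_real_, dim = c(Th + 1L, 2L, n_agents))
  if (is.array(init) && length(dim(init)) == 3L) {
    stopifnot(dim(init)[1] == Th + 1L)
    for (a in seq_len(n_agents))
      upast[, , a] <- init[, , ((a - 1L) %% dim(init)[3]) + 1L]
  } else {
    for (a in seq_len(n_agents)) {
      win <- sample_init_window(init, Th)
      upast[, , a] <- win[, , sample.int(dim(win)[3], 1L)]
    }
  }
  vpast <- (upast[-1, , , drop = FALSE] - upast[-(Th + 1L), , , drop = FALSE]) / dt
  u <- t(upast[Th + 1L, , ])
  v <- t(vpast[Th, , ])
  # pair history H[[a]][[b]]: 11 x Th matrix (cols oldest first)
  pair_state <- function(ua, va, ub, vb) {
    c(ua, va, 1 - sqrt(sum(ua^2)), ub, vb, 1 - sqrt(sum(ub^2)),
      sqrt(sum((ua - ub)^2)))
  }
  H <- lapply(seq_len(n_agents), function(a) lapply(seq_len(n_agents), function(b) {
    if (a == b) return(NULL)
    sapply(seq_len(Th), function(h)
      pair_state(upast[h + 1L, , a], vpast[h, , a], upast[h + 1L, , b], vpast[h, , b]))
  }))
  pairs <- which(outer(seq_len(n_agents), seq_len(n_agents), `!=`), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  out <- array(NA_real_, dim = c(steps, 2L, n_agents))
  for (n in seq_len(steps)) {
    X <- array(NA_real_, dim = c(nrow(pairs), Th, 11L))
    for (p in seq_len(nrow(pairs)))
      X[p, , ] <- t(H[[pairs[p, 1]]][[pairs[p, 2]]])
    pred <- model_forward(model, X)
    unew <- u; vnew <- v
    for (a in seq_len(n_agents)) {
      rows <- which(pairs[, 1] == a)
      agg <- aggregate_influential(cbind(pred$mu_x[rows], pred$mu_y[rows]),
                                   cbind(pred$sigma_x[rows], pred$sigma_y[rows]),
                                   k_influential)
      mu_a <- agg$mu
      sg_a <- agg$sigma
      ok <- FALSE
      sig_max <- 0.5 / dt^2
      for (attempt in seq_len(max(cap, 1L) * 64L)) {
        k <- (attempt - 1L) %/% max(cap, 1L)
        sg_k <- if (k > 0) pmin(sg_a * 2^k, pmax(sg_a, sig_max)) else sg_a
        acc <- mu_a + sg_k * stats::rnorm(2L)
        st <- integrate_state(u[a, ], v[a, ], acc, dt)
        if (!rejection || sqrt(sum(st$u^2)) <= 1) {
          unew[a, ] <- st$u; vnew[a, ] <- st$v; ok <- TRUE; break
        }
      }
      if (!ok) stop(sprintf("rejection cap exhausted at step %d (agent %d)", n, a))
    }
    u <- unew; v <- vnew
    out[n, , ] <- t(u)
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      H[[a]][[b]] <- cbind(H[[a]][[b]][, -1, drop = FALSE],
                           pair_state(u[a, ], v[a, ], u[b, ], v[b, ]))
    }
  }
  trajectory_dataset(seq_len(steps) * dt, out * Rt, dt = dt, tank_radius = Rt,
                     body_length = model$body_length,
                     meta = sprintf("multi_agent_rollout:n=%d,k=%d", n_agents,
                                    as.integer(k_influential)))
}
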