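# The recurrent probabilistic interaction model: training-set construction,
# forward pass, loss, sampling, integration, gradient correctness, and the
# closed-loop machinery.

small_net <- function() dli_network_config(lstm1 = 8, dense1 = 6, dense2 = 5,
                                           lstm2 = 5, head1 = 5, head2 = 4)

tiny_fit <- function(seed = 3, epochs = 2) {
  ds <- fixture_linear_gaussian(n = 1500, n_segments = 5, seed = 14)
  fit_dli(ds, small_net(), dli_train_config(epochs = epochs, batch = 128,
                                            lr = 2e-3), seed = seed)
}

test_that("training windows have the documented shapes and counts", {
  # one segment of 107 usable timesteps, both orderings -> 202 samples
  ds <- fixture_linear_gaussian(n = 107, n_segments = 1, seed = 1)
  ts <- build_training_set(ds)
  expect_equal(dim(ts$x), c(202L, 5L, 11L))
  expect_equal(dim(ts$y), c(202L, 2L))
  ts1 <- build_training_set(ds, augment = FALSE)
  expect_equal(dim(ts1$x)[1], 101L)

  # segments shorter than 7 samples are skipped
  ds$segment <- rep(c(1L, 2L), times = c(5L, 102L))
  ds2 <- trajectory_dataset(ds$t, ds$pos, segment = ds$segment, dt = ds$dt)
  ts2 <- build_training_set(ds2)
  expect_equal(ts2$skipped, 1L)
})

test_that("constant-velocity trajectories give zero acceleration targets", {
  n <- 40; dt <- 0.12
  pos <- array(0, dim = c(n, 2, 2))
  pos[, 1, 1] <- seq_len(n) * dt * 2
  pos[, 1, 2] <- seq_len(n) * dt * 3 + 1
  ds <- trajectory_dataset(seq_len(n) * dt, pos, dt = dt)
  ts <- build_training_set(ds)
  expect_lt(max(abs(ts$y)), 1e-9)
})

test_that("state vectors keep their redundant fields self-consistent", {
  ds <- simulate_abc(abc_model(), duration = 60, seed = 5)
  ts <- build_training_set(ds)
  u_f <- ts$x[, , 1:2]; rw_f <- ts$x[, , 5]
  u_n <- ts$x[, , 6:7]; rw_n <- ts$x[, , 10]
  d <- ts$x[, , 11]
  expect_lt(max(abs(rw_f - (1 - sqrt(u_f[, , 1]^2 + u_f[, , 2]^2)))), 1e-9)
  expect_lt(max(abs(rw_n - (1 - sqrt(u_n[, , 1]^2 + u_n[, , 2]^2)))), 1e-9)
  d2 <- sqrt((u_f[, , 1] - u_n[, , 1])^2 + (u_f[, , 2] - u_n[, , 2])^2)
  expect_lt(max(abs(d - d2)), 1e-9)
})

test_that("the Gaussian NLL matches hand values and the dnorm oracle", {
  expect_equal(nll_loss(matrix(0, 1, 2), matrix(1, 1, 2), matrix(0, 1, 2)), 0)
  expect_equal(nll_loss(matrix(c(0, 0), 1), matrix(1, 1, 2),
                        matrix(c(1, 0), 1)), 0.5)
  set.seed(23)
  mu <- matrix(rnorm(40), 20); sg <- matrix(rexp(40) + 0.1, 20)
  y <- matrix(rnorm(40), 20)
  expect_lt(max(abs(nll_loss(mu, sg, y, reduce = FALSE) - oracle_nll(mu, sg, y))),
            1e-9)
  expect_error(nll_loss(mu, -sg, y), "strictly positive")
})

test_that("the forward pass is deterministic, positive-sigma and order-sensitive", {
  set.seed(6)
  w <- pairswim:::dli_init_weights(small_net())
  h <- matrix(rnorm(55), 5, 11)
  p1 <- model_forward(w, h)
  p2 <- model_forward(w, h)
  expect_identical(p1, p2)
  expect_true(p1$sigma_x > 0 && p1$sigma_y > 0)
  hp <- h[c(3, 1, 5, 2, 4), ]
  p3 <- model_forward(w, hp)
  expect_false(isTRUE(all.equal(p1$mu_x, p3$mu_x)))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(2)
  cfg <- dli_network_config(lstm1 = 4, dense1 = 3, dense2 = 3, lstm2 = 3,
                            head1 = 3, head2 = 3)
  w <- pairswim:::dli_init_weights(cfg)
  B <- 5
  x <- array(rnorm(B * 5 * 11, sd = 0.5), dim = c(B, 5, 11))
  Xc <- aperm(x, c(3, 1, 2))
  y <- t(matrix(rnorm(B * 2), B, 2))
  g <- pairswim:::cpp_dli_grad(w, Xc, y)
  lossfun <- function(w) pairswim:::cpp_dli_grad(w, Xc, y)$loss
  for (nm in names(w)) {
    for (i in sample(length(w[[nm]]), min(4, length(w[[nm]])))) {
      h <- 1e-5
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      fd <- (lossfun(wp) - lossfun(wm)) / (2 * h)
      expect_lt(abs(fd - g[[nm]][i]) / max(1e-6, abs(fd) + abs(g[[nm]][i])), 1e-4)
    }
  }
})

test_that("acceleration sampling has the requested moments and degenerate limit", {
  pred <- data.frame(mu_x = 1, mu_y = -2, sigma_x = 0.5, sigma_y = 2)
  set.seed(8)
  a <- sample_acceleration(pred, n = 1e5)
  expect_equal(colMeans(a), c(1, -2), tolerance = 3 * 2 / sqrt(1e5) + 0.01)
  expect_equal(apply(a, 2, sd), c(0.5, 2), tolerance = 0.02)
  z <- sample_acceleration(list(mu = c(3, 4), sigma = c(0, 0)), n = 5)
  expect_true(all(z[, 1] == 3 & z[, 2] == 4))
  set.seed(9); a1 <- sample_acceleration(pred, 10)
  set.seed(9); a2 <- sample_acceleration(pred, 10)
  expect_identical(a1, a2)
})

test_that("the semi-implicit integrator updates velocity before position", {
  st <- integrate_state(c(0, 0), c(0, 0), c(0, 0), 0.12)
  expect_equal(st$u, c(0, 0))
  st <- integrate_state(c(0, 0), c(1, 0), c(0, 0), 0.12)
  expect_equal(st$u, c(0.12, 0))
  st <- integrate_state(c(0, 0), c(1, 0), c(1, 0), 0.12)
  expect_equal(st$v, c(1.12, 0))
  expect_equal(st$u, c(0.1344, 0))
})

test_that("training is seeded, improves the validation loss, and records curves", {
  m1 <- tiny_fit(seed = 3, epochs = 3)
  m2 <- tiny_fit(seed = 3, epochs = 3)
  expect_identical(m1$weights, m2$weights)
  expect_lte(tail(m1$curves$validation, 1), m1$curves$validation[1])
  expect_equal(nrow(m1$curves), 3L)
  expect_s3_class(m1, "dli")
  expect_output(print(m1), "recurrent probabilistic")
  s <- summary(m1)
  expect_output(print(s), "NLL")
  expect_true(is.finite(m1$test_loss))
  expect_named(coef(m1), names(pairswim:::dli_init_weights(small_net())))
})

test_that("prediction and residual methods work on datasets", {
  m <- tiny_fit()
  ds <- fixture_linear_gaussian(n = 600, n_segments = 2, seed = 15)
  pred <- predict(m, ds)
  expect_true(all(c("mu_x", "sigma_x", "a_x") %in% names(pred)))
  expect_true(all(pred$sigma_x > 0))
  res <- residuals(m, ds)
  expect_equal(dim(res), c(nrow(pred), 2L))
  expect_equal(res[, 1], pred$a_x - pred$mu_x, ignore_attr = TRUE)
  resz <- residuals(m, ds, standardized = TRUE)
  expect_equal(resz[, 2], (pred$a_y - pred$mu_y) / pred$sigma_y,
               ignore_attr = TRUE)
})

test_that("closed-loop rollouts respect the wall when rejection is on", {
  m <- tiny_fit()
  ds <- fixture_linear_gaussian(n = 600, n_segments = 2, seed = 16)
  roll <- dli_rollout(m, steps = 400, init = ds, rejection = TRUE, seed = 21)
  expect_s3_class(roll, "trajectory_dataset")
  expect_equal(length(roll$t), 400L)
  expect_true(all(sqrt(roll$pos[, 1, ]^2 + roll$pos[, 2, ]^2) <=
                  m$norm$tank_radius + 1e-9))
  expect_equal(attr(roll, "escaped_step"), 0L)
  # simulate() convention wrapper
  r2 <- simulate(m, steps = 50, init = ds, seed = 22)
  expect_equal(length(r2$t), 50L)
})

test_that("weights save/load round-trips the model", {
  m <- tiny_fit()
  stem <- withr::local_tempfile()
  save_dli(m, stem)
  m2 <- load_dli(stem)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$target_scale, m$target_scale, tolerance = 1e-12)
  h <- matrix(rnorm(55, sd = 0.3), 5, 11)
  expect_equal(model_forward(m2, h), model_forward(m, h), tolerance = 1e-10)
})

test_that("survival bookkeeping: infinite margin censors every run", {
  m <- tiny_fit()
  ds <- fixture_linear_gaussian(n = 600, n_segments = 2, seed = 17)
  sv <- survival_experiment(m, n_runs = 3, horizon = 12, margin = Inf,
                            init = ds, seed = 31)
  expect_true(all(is.na(sv$escape_time)))
  expect_true(all(sv$curve$fraction == 1))
  # the survival curve never increases and starts at 1
  sv2 <- survival_experiment(m, n_runs = 4, horizon = 12, margin = 0.5,
                             init = ds, seed = 32)
  expect_equal(sv2$curve$fraction[1], 1)
  expect_true(all(diff(sv2$curve$fraction) <= 1e-12))
})

test_that("influential-neighbour aggregation is permutation invariant", {
  set.seed(41)
  mu <- matrix(rnorm(8), 4, 2)
  sg <- matrix(rexp(8) + 0.2, 4, 2)
  agg1 <- pairswim:::aggregate_influential(mu, sg, k = 2)
  perm <- c(3, 1, 4, 2)
  agg2 <- pairswim:::aggregate_influential(mu[perm, ], sg[perm, ], k = 2)
  expect_equal(agg1, agg2)
  # k = 1 keeps exactly the strongest neighbour
  strongest <- which.max(sqrt(rowSums(mu^2)))
  agg3 <- pairswim:::aggregate_influential(mu, sg, k = 1)
  expect_equal(agg3$mu, mu[strongest, ])
  expect_equal(agg3$sigma, sg[strongest, ])
})

test_that("the pair case of the group rollout matches the pair rollout", {
  m <- tiny_fit()
  ds <- fixture_linear_gaussian(n = 600, n_segments = 2, seed = 18)
  set.seed(51)
  win <- pairswim:::sample_init_window(ds)
  set.seed(52)
  r1 <- dli_rollout(m, steps = 60, init = win, rejection = FALSE)
  set.seed(52)
  r2 <- multi_agent_rollout(m, n_agents = 2, steps = 60, init = win,
                            k_influential = 1, rejection = FALSE)
  expect_equal(r2$pos, r1$pos, tolerance = 1e-10)
})

test_that("a five-agent group stays finite and inside with rejection", {
  m <- tiny_fit()
  ds <- fixture_linear_gaussian(n = 600, n_segments = 2, seed = 19)
  roll <- multi_agent_rollout(m, n_agents = 5, steps = 40, init = ds,
                              k_influential = 2, seed = 61)
  expect_equal(dim(roll$pos), c(40L, 2L, 5L))
  expect_true(all(is.finite(roll$pos)))
  expect_true(all(sqrt(roll$pos[, 1, ]^2 + roll$pos[, 2, ]^2) <=
                  m$norm$tank_radius + 1e-9))
})
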