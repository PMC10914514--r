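# The asynchronous burst-and-coast simulator: kick sampling, heading-change
# kernels, rejection at the wall, event bookkeeping, and kick-to-continuous
# resampling.

test_that("kick draws have the configured means and are seeded", {
  params <- abc_model()
  set.seed(100)
  ks <- sample_kick(params, n = 1e5)
  expect_equal(mean(ks$tau), 0.5, tolerance = 0.01)
  expect_equal(mean(ks$l), 7, tolerance = 0.1)
  expect_true(all(ks$tau > 0) && all(ks$l >= 0))

  set.seed(42); a <- sample_kick(params, 100)
  set.seed(42); b <- sample_kick(params, 100)
  expect_identical(a, b)
})

test_that("heading change decomposes into wall, social and noise terms", {
  params <- abc_model()
  focal <- list(u = c(10, 0), phi = 1)
  nb <- list(u = c(12, 3), phi = 0.5)
  hc <- heading_change(focal, nb, params, noise = 0.1)
  expect_s3_class(hc, "heading_change")
  expect_equal(hc$total, hc$wall + hc$attraction + hc$alignment + hc$noise)
  expect_equal(hc$social, hc$attraction + hc$alignment)

  # no neighbour: social terms vanish exactly; at the centre the wall kernel
  # has decayed to almost nothing
  hc0 <- heading_change(list(u = c(0, 0), phi = 0.3), NULL, params, noise = 0)
  expect_equal(hc0$attraction, 0)
  expect_equal(hc0$alignment, 0)
  expect_lt(abs(hc0$wall), 0.02)

  # all amplitudes and noise zero: no turn at all
  p0 <- abc_model(gamma = 0, wall_amp = 0, wall_asym = 0, att_amp = 0, ali_amp = 0)
  expect_equal(heading_change(focal, nb, p0, noise = 0)$total, 0)
})

test_that("the deterministic heading change is mirror-antisymmetric", {
  params <- abc_model(wall_asym = 0)
  set.seed(55)
  for (i in 1:25) {
    focal <- list(u = runif(2, -15, 15), phi = runif(1, -pi, pi))
    nb <- list(u = runif(2, -15, 15), phi = runif(1, -pi, pi))
    h1 <- heading_change(focal, nb, params, noise = 0)
    # reflect the whole configuration about the x-axis
    rf <- function(s) list(u = c(s$u[1], -s$u[2]), phi = wrap_angle(-s$phi))
    h2 <- heading_change(rf(focal), rf(nb), params, noise = 0)
    expect_equal(h2$total, -h1$total, tolerance = 1e-12)
  }
})

test_that("kick geometry follows heading + length, with wall rejection", {
  # no noise, no interactions: heading unchanged, endpoint = u + l e(phi)
  p0 <- abc_model(gamma = 0, wall_amp = 0, wall_asym = 0, att_amp = 0, ali_amp = 0)
  set.seed(9)
  k <- step_kick(list(t = 0, u = c(0, 0), phi = 0), NULL, p0)
  expect_equal(k$phi, 0)
  endpoint <- k$u0 + k$l * c(cos(k$phi), sin(k$phi))
  expect_equal(endpoint, c(k$l, 0))

  # 1 cm from the wall heading straight out: only a short kick can be
  # accepted, so the rejection loop must have shortened the draw
  set.seed(10)
  k2 <- step_kick(list(t = 0, u = c(24, 0), phi = 0), NULL, p0)
  expect_lte(k2$l, 1)

  # near-deterministic long kicks cannot fit: the cap is an error
  pstuck <- abc_model(gamma = 0, wall_amp = 0, wall_asym = 0, att_amp = 0,
                      ali_amp = 0, l_shape = 1e4, rejection_cap = 50L)
  set.seed(11)
  expect_error(step_kick(list(t = 0, u = c(24, 0), phi = 0), NULL, pstuck),
               "rejection cap exhausted")
})

test_that("the event loop is asynchronous, time-ordered and contained", {
  params <- abc_model()
  ds <- simulate_abc(params, duration = 120, seed = 303)
  kicks <- attr(ds, "kicks")
  expect_s3_class(ds, "trajectory_dataset")
  # per-agent timelines are strictly increasing and consistent: each kick
  # starts where and when the previous one ended
  for (a in unique(kicks$agent)) {
    ka <- kicks[kicks$agent == a, ]
    expect_true(all(diff(ka$t) > 0))
    expect_equal(ka$t[-1], ka$t[-nrow(ka)] + ka$tau[-nrow(ka)], tolerance = 1e-9)
    ex <- ka$x[-nrow(ka)] + ka$l[-nrow(ka)] * cos(ka$phi[-nrow(ka)])
    expect_equal(ka$x[-1], ex, tolerance = 1e-9)
  }
  # the interleaved global log alternates between agents irregularly
  expect_gt(length(unique(kicks$agent)), 1L)
  # kick endpoints and resampled positions stay inside the tank
  ends <- sqrt((kicks$x + kicks$l * cos(kicks$phi))^2 +
               (kicks$y + kicks$l * sin(kicks$phi))^2)
  expect_true(all(ends <= params$tank_radius + 1e-9))
  expect_true(all(sqrt(ds$pos[, 1, ]^2 + ds$pos[, 2, ]^2) <= params$tank_radius + 1e-9))
})

test_that("seeded runs are bit-reproducible", {
  a <- simulate_abc(abc_model(), duration = 60, seed = 77)
  b <- simulate_abc(abc_model(), duration = 60, seed = 77)
  expect_identical(a$pos, b$pos)
  expect_identical(attr(a, "kicks"), attr(b, "kicks"))
})

test_that("kick resampling follows the glide model on the dt grid", {
  params <- abc_model(glide = "uniform")
  kicks <- data.frame(agent = 0L, t = c(0, 0.6), phi = 0, l = 7, tau = 0.6,
                      x = c(0, 7), y = 0)
  ds <- kicks_to_trajectory(kicks, dt = 0.12, params = params)
  expect_equal(ds$pos[1:5, 1, 1], c(0, 1.4, 2.8, 4.2, 5.6), tolerance = 1e-12)

  # dt equal to the kick duration: only kick endpoints
  ds2 <- kicks_to_trajectory(kicks, dt = 0.6, params = params)
  expect_equal(ds2$pos[, 1, 1], c(0, 7))

  # exponential glide front-loads the displacement but hits the same endpoint
  pe <- abc_model(glide = "exponential")
  dse <- kicks_to_trajectory(kicks, dt = 0.12, params = pe)
  expect_gt(dse$pos[2, 1, 1], 1.4)
  expect_equal(dse$pos[6, 1, 1], 7, tolerance = 1e-9)

  # a hole in the event coverage is an error
  bad <- data.frame(agent = 0L, t = c(0, 1.0), phi = 0, l = 7, tau = 0.6,
                    x = c(0, 7), y = 0)
  expect_error(kicks_to_trajectory(bad, dt = 0.12, params = params),
               "gaps in event coverage")
})

test_that("the resampled path length never exceeds the summed kick lengths", {
  ds <- simulate_abc(abc_model(), duration = 60, seed = 88)
  kicks <- attr(ds, "kicks")
  for (j in 1:2) {
    a <- j - 1L
    steps <- sqrt(diff(ds$pos[, 1, j])^2 + diff(ds$pos[, 2, j])^2)
    expect_lte(sum(steps), sum(kicks$l[kicks$agent == a]))
  }
})

test_that("without social terms the two agents are independent", {
  p0 <- abc_model(att_amp = 0, ali_amp = 0)
  ds <- simulate_abc(p0, duration = 1500, seed = 91)
  kin <- compute_kinematics(ds)
  d_obs <- kin$d_ij[kin$valid]
  # product-measure prediction: distances between the two agents at
  # independently shuffled times
  set.seed(92)
  i <- sample(which(kin$valid)); j <- sample(which(kin$valid))
  d_ind <- sqrt((ds$pos[i, 1, 1] - ds$pos[j, 1, 2])^2 +
                (ds$pos[i, 2, 1] - ds$pos[j, 2, 2])^2)
  edges <- seq(0, 50, length.out = 51)
  hd <- hellinger(estimate_pdf(d_obs, edges, "d"), estimate_pdf(d_ind, edges, "d"))
  expect_lt(hd, 0.1)
})

test_that("default social interactions produce cohesion, alignment and wall following", {
  ds <- simulate_abc(abc_model(), duration = 1500, seed = 93)
  kin <- compute_kinematics(ds)
  v <- kin$valid
  # cohesion: modal distance below 4 body lengths
  hd <- graphics::hist(kin$d_ij[v], breaks = seq(0, 50, 0.5), plot = FALSE)
  expect_lt(hd$mids[which.max(hd$counts)], 4 * ds$body_length)
  # alignment: modal relative heading at zero (within one 15-degree bin)
  hp <- graphics::hist(c(kin$phi_ij[v], -kin$phi_ij[v]),
                       breaks = seq(-pi, pi, length.out = 25), plot = FALSE)
  expect_lt(abs(hp$mids[which.max(hp$counts)]), 15 * pi / 180)
  expect_gt(mean(cos(kin$phi_ij[v])), 0.4)
  # wall following: most mass within two body lengths of the wall
  expect_gt(mean(kin$r_w[v, ] < 2 * ds$body_length), 0.5)
})
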