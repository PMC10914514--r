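# PDF estimation, Hellinger scoring, and the three temporal correlation
# estimators against brute-force oracles and closed forms.

test_that("histogram density estimates are normalized and calibrated", {
  set.seed(31)
  x <- rnorm(1e6)
  p <- estimate_pdf(x, seq(-5, 5, by = 0.1), "z")
  expect_equal(sum(p$density * diff(p$edges)), 1, tolerance = 1e-9)
  at0 <- p$density[which(p$edges == 0)]  # bin [0, 0.1)
  expect_equal(at0, dnorm(0), tolerance = 0.01)

  # degenerate distribution: one occupied bin with density 1/binwidth
  q <- estimate_pdf(rep(2.5, 1000), 0:5)
  expect_equal(sum(q$density > 0), 1L)
  expect_equal(max(q$density), 1)

  # uniform samples: density about 1 everywhere
  u <- estimate_pdf(runif(20000), seq(0, 1, by = 0.1))
  expect_true(all(abs(u$density - 1) < 0.1))

  expect_error(estimate_pdf(numeric(0), 0:1), "empty")
  expect_warning(estimate_pdf(rnorm(50), seq(-5, 5, 0.5)), "only 50")
})

test_that("Hellinger distance matches the hand-computed two-bin case", {
  p <- masses_pdf(c(0.5, 0.5))
  q <- masses_pdf(c(0.9, 0.1))
  expect_equal(hellinger(p, q), sqrt(1 - (sqrt(0.45) + sqrt(0.05))),
               tolerance = 1e-12)
  expect_equal(round(hellinger(p, q), 4), 0.3249)
  expect_equal(hellinger(p, p), 0)
  expect_equal(hellinger(q, p), hellinger(p, q))  # symmetry
  disjoint <- list(masses_pdf(c(1, 0)), masses_pdf(c(0, 1)))
  expect_equal(hellinger(disjoint[[1]], disjoint[[2]]), 1)
  r <- masses_pdf(c(0.5, 0.5)); r$edges <- c(0, 1, 3)
  expect_error(hellinger(p, r), "identical bin edges")
})

test_that("correlation estimators equal the O(n^2) brute-force oracles", {
  ds <- rw_dataset(n = 400, n_agents = 2, two_segments = TRUE, seed = 7)
  lags <- 0:40
  mx <- msd(ds, max_lag = 40 * ds$dt)
  expect_equal(mx$lags, lags * ds$dt)
  expect_lt(max(abs(mx$values - brute_msd(ds, lags)) /
                pmax(1e-12, abs(brute_msd(ds, lags)))), 1e-9)

  vc <- velocity_autocorrelation(ds, max_lag = 40 * ds$dt)
  expect_lt(max(abs(vc$values - brute_vac(ds, lags)) /
                pmax(1e-12, abs(brute_vac(ds, lags)))), 1e-9)

  tc <- thetaw_autocorrelation(ds, max_lag = 40 * ds$dt)
  expect_lt(max(abs(tc$values - brute_thetaw_ac(ds, lags))), 1e-9)

  # lag-0 anchors
  expect_equal(mx$values[1], 0)
  expect_equal(tc$values[1], 1)
  kin <- compute_kinematics(ds)
  expect_equal(vc$values[1], mean(kin$speed[kin$valid, ]^2))
})

test_that("a max lag longer than every segment is an error", {
  ds <- rw_dataset(n = 50, seed = 3)
  expect_error(msd(ds, max_lag = 100), "max lag")
})

test_that("ballistic motion gives the exact short-time law C_X = <v^2> t^2", {
  ds <- fixture_ballistic_pair(n = 300, speeds = c(5, 9))
  mx <- msd(ds, max_lag = 20)
  v2 <- mean(c(5, 9)^2)
  tt <- mx$lags[-1]
  expect_lt(max(abs(mx$values[-1] / (v2 * tt^2) - 1)), 1e-9)
  vc <- velocity_autocorrelation(ds, max_lag = 20)
  expect_equal(vc$values[1], v2, tolerance = 1e-12)
  # static point: zero at all lags
  still <- trajectory_dataset(seq_len(100) * 0.12,
                              array(1, dim = c(100, 2, 1)), dt = 0.12)
  expect_true(all(msd(still, max_lag = 5)$values == 0))
})

test_that("uniform circular motion matches the closed-form autocorrelations", {
  r <- 20; omega <- 0.02; dt <- 0.12
  ds <- fixture_circular_swimmer(n = 2000, r = r, omega = omega, dt = dt)
  vc <- velocity_autocorrelation(ds, max_lag = 30)
  s <- 2 * r * sin(omega * dt / 2) / dt      # chord speed
  expected <- s^2 * cos(omega * vc$lags)
  expect_lt(max(abs(vc$values - expected)), 1e-6)
  # and the coarse law with the nominal speed omega*r
  expect_lt(max(abs(vc$values - (omega * r)^2 * cos(omega * vc$lags))), 1e-4)
  # constant wall incidence: correlation identically 1
  tc <- thetaw_autocorrelation(ds, max_lag = 30)
  expect_lt(max(abs(tc$values - 1)), 1e-9)
})

test_that("white-noise velocities and headings decorrelate immediately", {
  ds <- rw_dataset(n = 4000, sd = 1, seed = 17)
  vc <- velocity_autocorrelation(ds, max_lag = 10 * ds$dt)
  # v(t).v(t') for iid steps: mean 0, sd ~ 2*sd_v^2 per product
  sdv <- sqrt(2) / ds$dt  # per-component velocity sd is sd/dt
  se <- 2 * sdv^2 / sqrt(vc$counts[-1])
  expect_true(all(abs(vc$values[-1]) < 3 * se))

  # theta_w approximately iid uniform for a centred random walk
  ds2 <- rw_dataset(n = 4000, sd = 0.01, seed = 19)
  ds2$pos <- ds2$pos + 100  # keep far from the arena centre
  ds2$tank_radius <- 1e4
  tc <- thetaw_autocorrelation(ds2, max_lag = 10 * ds2$dt)
  expect_true(all(abs(tc$values[-1]) < 4 / sqrt(tc$counts[-1])))
  expect_equal(tc$values[1], 1)
})

test_that("the observable report populates all nine observables", {
  params <- abc_model()
  ds <- simulate_abc(params, duration = 300, seed = 71)
  os <- observable_report(ds, max_lag = 10)
  expect_s3_class(os, "observable_set")
  expect_named(os$pdfs, c("V", "r_w", "theta_w", "d_ij", "phi_ij", "psi"))
  expect_named(os$curves, c("C_X", "C_V", "C_thetaw"))
  for (k in names(os$curves))
    expect_named(os$curves[[k]], c("mean", "leader", "follower"))
  # six pdf observables, some split by role
  expect_equal(length(flatten_pdfs_for_test(os)), 11L)
  # every pdf integrates to 1
  for (p in flatten_pdfs_for_test(os))
    expect_equal(sum(p$density * diff(p$edges)), 1, tolerance = 1e-9)
  # |C_thetaw| <= 1 and starts at 1
  expect_true(all(abs(os$curves$C_thetaw$mean$values) <= 1 + 1e-12))
  expect_equal(os$curves$C_thetaw$mean$values[1], 1)
})

test_that("small datasets warn instead of failing", {
  params <- abc_model()
  ds <- simulate_abc(params, duration = 8, seed = 72)
  w <- capture_warnings(observable_report(ds, max_lag = 2, curves = FALSE))
  expect_true(any(grepl("only", w)))
})

test_that("mirror reflection mirrors the angular PDFs and fixes the even ones", {
  ds <- simulate_abc(abc_model(), duration = 400, seed = 73)
  mir <- ds
  mir$pos[, 2, ] <- -mir$pos[, 2, ]
  o1 <- observable_report(ds, curves = FALSE)
  o2 <- observable_report(mir, curves = FALSE)
  # speed and distance PDFs unchanged
  expect_equal(o2$pdfs$V$density, o1$pdfs$V$density)
  expect_equal(o2$pdfs$d_ij$density, o1$pdfs$d_ij$density)
  expect_equal(o2$pdfs$r_w$all$density, o1$pdfs$r_w$all$density)
  # angular PDFs mirrored (density reversed across symmetric bins)
  expect_equal(o2$pdfs$theta_w$all$density, rev(o1$pdfs$theta_w$all$density))
  expect_equal(o2$pdfs$phi_ij$density, rev(o1$pdfs$phi_ij$density))
  expect_equal(o2$pdfs$psi$leader$density, rev(o1$pdfs$psi$leader$density))
})

test_that("Hellinger reports: self-comparison is zero, mismatched models score high", {
  ds <- simulate_abc(abc_model(), duration = 400, seed = 74)
  os <- observable_report(ds, curves = FALSE)
  self <- compare_observables(os, os)
  expect_true(all(self$hd == 0))

  # a rigid circular pair never hugs the wall: r_w distance is large
  n <- 3000; dt <- 0.12; tt <- seq_len(n) * dt
  pos <- array(NA_real_, dim = c(n, 2, 2))
  pos[, 1, 1] <- 15 * cos(0.5 * tt); pos[, 2, 1] <- 15 * sin(0.5 * tt)
  pos[, 1, 2] <- 13 * cos(0.5 * tt); pos[, 2, 2] <- 13 * sin(0.5 * tt)
  circ <- trajectory_dataset(tt, pos, dt = dt)
  oc <- observable_report(circ, curves = FALSE)
  hd <- compare_observables(os, oc)
  expect_gt(hd$hd[["r_w"]], 0.3)
  expect_true(all(hd$hd >= 0 & hd$hd <= 1))

  # policy mismatch is an error
  o3 <- observable_report(ds, policy = binning_policy("alt"), curves = FALSE)
  expect_error(compare_observables(os, o3), "policies")
})

test_that("two runs of the same model differ only by sampling noise", {
  a <- observable_report(simulate_abc(abc_model(), duration = 1200, seed = 81),
                         curves = FALSE)
  b <- observable_report(simulate_abc(abc_model(), duration = 1200, seed = 82),
                         curves = FALSE)
  hd <- compare_observables(a, b)
  expect_true(all(hd$hd < 0.12))
})

test_that("correlation averaging never crosses segment boundaries", {
  # two ballistic segments with very different speeds: a cross-boundary
  # estimator would mix them and break the exact per-segment law
  dt <- 0.12; n <- 60
  x1 <- 5 * seq_len(n) * dt
  x2 <- 500 + 50 * seq_len(n) * dt
  pos <- array(0, dim = c(2 * n, 2, 1))
  pos[, 1, 1] <- c(x1, x2)
  ds <- trajectory_dataset(c(seq_len(n) * dt, 100 + seq_len(n) * dt),
                           pos, segment = rep(1:2, each = n), dt = dt,
                           tank_radius = 1e6)
  mx <- msd(ds, max_lag = 2)
  v2 <- mean(c(rep(25, n - 1), rep(2500, n - 1)))
  expect_lt(max(abs(mx$values[-1] / (v2 * mx$lags[-1]^2) - 1)), 1e-9)
})

test_that("observable sets and reports serialize to JSON", {
  ds <- simulate_abc(abc_model(), duration = 120, seed = 75)
  os <- observable_report(ds, max_lag = 5)
  path <- withr::local_tempfile(fileext = ".json")
  observables_to_json(os, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$type, "observable_set")
  expect_true("V" %in% names(parsed$pdfs))
  hd <- compare_observables(os, os)
  txt <- observables_to_json(hd)
  expect_true(jsonlite::validate(txt))
})
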