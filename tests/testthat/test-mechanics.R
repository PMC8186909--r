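test_that("force unit conversions are exact and invertible", {
  expect_equal(convert_force_units(1, "kJ/mol/nm", "pN"), 1.66054,
               tolerance = 1e-5)
  x <- c(0, 1.5, -7.2)
  expect_close(convert_force_units(convert_force_units(x, "pN", "kJ/mol/nm"),
                                   "kJ/mol/nm", "pN"), x, 1e-12)
  expect_equal(convert_force_units(0, "N", "pN"), 0)
  expect_error(convert_force_units(1, "lbf", "pN"), "unknown")
})

const_trace <- function(f_per_chain, n = 100, points = NULL) {
  nc <- nrow(f_per_chain)
  forces <- array(NA_real_, dim = c(n, nc, 3))
  for (c in seq_len(nc)) for (d in 1:3) forces[, c, d] <- f_per_chain[c, d]
  force_trace(seq_len(n), forces, points = points)
}

test_that("reaction-force summary averages correctly", {
  f <- rbind(c(1, 2, 3), c(-1, -2, 5))
  tr <- const_trace(f)
  s <- reaction_force_summary(tr)
  expect_close(s$mean, f, 1e-12)
  expect_close(s$sd, matrix(0, 2, 3), 1e-12)
  expect_close(s$net, colSums(f), 1e-12)
  # a window of one sample is that sample
  s1 <- reaction_force_summary(tr, window = c(5, 5))
  expect_close(s1$mean, f, 1e-12)
  expect_error(reaction_force_summary(tr, window = c(1000, 2000)), "window")
  expect_error(force_trace(1:5, array(0, c(4, 2, 3))), "length")
})

test_that("planar torque: radial null, tangential arithmetic, mirror flip", {
  # chain application points on a 2 nm circle (stored in Angstrom)
  pts <- 20 * cbind(cos(pi / 2 * 0:3), sin(pi / 2 * 0:3), 0)
  # purely radial forces -> zero torque
  fr <- 5 * cbind(cos(pi / 2 * 0:3), sin(pi / 2 * 0:3), 0)
  expect_equal(planar_torque(const_trace(fr, points = pts))$torque_z, 0,
               tolerance = 1e-10)
  # one tangential 5 pN force at radius 2 nm -> 10 pN nm
  f1 <- rbind(c(0, 5, 0))
  t1 <- planar_torque(const_trace(f1, points = pts[1, , drop = FALSE]),
                      symmetrize = FALSE)
  expect_equal(t1$torque_z, 10, tolerance = 1e-10)
  # tangential forces on all four chains, symmetrized: net force 0, torque 4x
  ft <- 5 * cbind(-sin(pi / 2 * 0:3), cos(pi / 2 * 0:3), 0)
  ts <- planar_torque(const_trace(ft, points = pts))
  expect_close(ts$net_planar_force, c(0, 0), 1e-10)
  expect_equal(ts$torque_z, 40, tolerance = 1e-10)
  # mirror (x -> -x) flips the torque sign exactly
  mf <- ft %*% diag(c(-1, 1, 1))
  mp <- pts %*% diag(c(-1, 1, 1))
  tm <- planar_torque(const_trace(mf, points = mp))
  expect_equal(tm$torque_z, -ts$torque_z, tolerance = 1e-10)
  expect_error(planar_torque(const_trace(ft)), "application points")
})

test_that("achiral spring toy under axial load produces no torque", {
  m <- spring_model(twist_per_bead = 0)
  run <- simulate_overdamped(m, -5, n_steps = 2e4, temperature = 0, seed = 1)
  tq <- planar_torque(run$force_trace,
                      window = c(40, max(run$force_trace$times)))
  expect_lt(abs(tq$torque_z), 1e-6)
})

test_that("spring constant: formula, error paths, noisy recovery", {
  # deterministic Hooke numbers
  free <- rep(15, 200)
  forced <- rep(15 - 1.5, 200)
  fit <- spring_constant(free, forced, 5)
  expect_equal(fit$k, 5 / 1.5, tolerance = 1e-12)
  expect_equal(fit$dz, 1.5)
  # dz below the resolution floor errors
  expect_error(spring_constant(free, rep(15 - 0.01, 200), 5), "inelastic")
  # non-stationary series errors
  drifty <- seq(15, 10, length.out = 400) + rnorm(400, 0, 0.01)
  expect_error(spring_constant(drifty, forced, 5), "stationary")
  # noisy parameter recovery against the generator truth (k_true = 3)
  m <- spring_model(n_chains = 1)
  xf <- spring_length_series(simulate_overdamped(m, 0, n_steps = 1.5e6,
                                                 seed = 21, save_every = 50))
  xc <- spring_length_series(simulate_overdamped(m, -5, n_steps = 1.5e6,
                                                 seed = 22, save_every = 50))
  fit2 <- spring_constant(xf, xc, 5)
  expect_close(fit2$k, 3.0, 0.45)  # within 15 percent
  expect_gt(fit2$k_sd, 0)
})

test_that("parallel bundle constant is the sum of branches", {
  expect_equal(parallel_bundle_constant(rep(3.3, 4)), 13.2)
  expect_equal(parallel_bundle_constant(5.5), 5.5)
  # network oracle: brute-force compliance reduction of 4 parallel branches,
  # each branch a series pair (2k, 2k) so branch stiffness is k
  ks <- c(2.1, 3.0, 3.3, 4.4)
  branch <- vapply(ks, function(k) 1 / (1 / (2 * k) + 1 / (2 * k)), numeric(1))
  expect_equal(parallel_bundle_constant(branch), sum(ks), tolerance = 1e-12)
  expect_error(parallel_bundle_constant(c(1, -2)), "positive")
})

test_that("elastic-range scan classifies Hookean and softening responses", {
  free <- rep(15, 400)
  hook <- lapply(1:5, function(F)
    list(F = F, series = rep(15 - F / 3, 400)))
  scan <- elastic_range_scan(free, hook)
  expect_equal(scan$verdict, "elastic")
  expect_close(scan$table$k, 3, 1e-9)
  # softening spring: dz grows superlinearly at high force
  soft <- lapply(1:5, function(F)
    list(F = F, series = rep(15 - (F / 3) * (1 + 0.25 * F), 400)))
  expect_equal(elastic_range_scan(free, soft)$verdict, "nonlinear")
  expect_equal(elastic_range_scan(free, hook[3])$verdict, "undetermined")
})

test_that("onset detection recovers an imposed delay within one sample", {
  tr <- make_delayed_force_traces(n_samples = 2000, dt = 0.01, delay = 8.0,
                                  amplitude = 5, noise_sd = 0.25, seed = 31)
  onset <- arrival_onset(tr$free, tr$perturbed, times = tr$times)
  expect_close(onset, 8.0, 0.011)
  # identical traces never deviate
  expect_true(is.na(arrival_onset(tr$free, tr$free + 0, times = tr$times)))
  # common offsets cancel
  onset2 <- arrival_onset(tr$free + 3.3, tr$perturbed + 3.3, times = tr$times)
  expect_equal(onset2, onset)
})

test_that("transfer speed recovers an imposed 1.8 nm/ps over replicas", {
  onsets <- vapply(1:5, function(i) {
    tr <- make_delayed_force_traces(n_samples = 2000, dt = 0.01,
                                    delay = 15 / 1.8, amplitude = 5,
                                    noise_sd = 0.3, seed = 40 + i)
    arrival_onset(tr$free, tr$perturbed, times = tr$times)
  }, numeric(1))
  est <- transfer_speed(onsets, L = 15)
  expect_close(est$v, 1.8, 0.18)
  # closed-form case
  expect_equal(transfer_speed(7.5, 15)$v, 2.0)
  expect_error(transfer_speed(numeric(0), 15), "no onset")
})
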