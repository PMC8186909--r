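test_that("helical spring geometry: span, symmetry, chirality", {
  m1 <- spring_model(n_chains = 1, n_beads = 29, rise = 0.517)
  s1 <- make_helical_spring(m1)
  expect_equal(diff(range(s1$xyz[, 3])) / 10, 29 * 0.517, tolerance = 1e-9)

  m4 <- spring_model()
  s4 <- make_helical_spring(m4)
  # C4 symmetry: rotating by 90 deg permutes chains A->B->C->D
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- s4$xyz %*% t(R)
  # rotated chain A coincides with original chain B, etc.
  expect_close(rot, s4$xyz[c(31:120, 1:30), ], 1e-9)

  # zero twist gives straight parallel chains
  s0 <- make_helical_spring(spring_model(twist_per_bead = 0))
  expect_true(all(abs(diff(s0$xyz[1:30, 1])) < 1e-12))
  expect_true(all(abs(diff(s0$xyz[1:30, 2])) < 1e-12))

  expect_error(spring_model(rise = -1), "positive")
  expect_error(spring_model(k_chain = 0), "positive")
})

test_that("T=0 dynamics: fixed point at rest, Hooke compression, scaling", {
  m <- spring_model(n_chains = 1)
  free <- simulate_overdamped(m, 0, n_steps = 2e4, temperature = 0, seed = 1)
  lf <- spring_length_series(free)
  expect_close(lf, 15, 1e-6)  # constant at rest length

  push <- simulate_overdamped(m, -5, n_steps = 6e4, temperature = 0, seed = 1)
  expect_close(tail(spring_length_series(push), 1), 15 - 5 / 3, 1e-4)

  # doubling F doubles dz, leaving k unchanged (1e-9 at T = 0)
  push2 <- simulate_overdamped(m, -10, n_steps = 6e4, temperature = 0, seed = 1)
  dz1 <- 15 - tail(spring_length_series(push), 1)
  dz2 <- 15 - tail(spring_length_series(push2), 1)
  expect_equal(dz2 / dz1, 2, tolerance = 1e-6)

  # pull stretches by the same Hooke amount
  pull <- simulate_overdamped(m, +5, n_steps = 6e4, temperature = 0, seed = 1)
  expect_close(tail(spring_length_series(pull), 1), 15 + 5 / 3, 1e-4)
})

test_that("head reaction force balances the applied force", {
  m <- spring_model()
  run <- simulate_overdamped(m, -5, n_steps = 4e5, temperature = 300,
                             seed = 11, save_every = 25)
  tr <- run$force_trace
  expect_equal(dim(tr$forces)[1], length(tr$times))
  s <- reaction_force_summary(tr, window = c(400, max(tr$times)))
  # mean head reaction per chain ~ +5 pN along z (reaction opposes the push)
  sem <- apply(tr$forces[, , 3], 2, sd) / sqrt(200)  # generous dof estimate
  for (c in 1:4)
    expect_lt(abs(s$mean[c, 3] - 5), 3 * max(sem[c], 0.25))
})

test_that("simulator is a pure function of its seed", {
  m <- spring_model(n_chains = 2, n_beads = 5)
  a <- simulate_overdamped(m, -1, n_steps = 2000, seed = 9)
  b <- simulate_overdamped(m, -1, n_steps = 2000, seed = 9)
  c <- simulate_overdamped(m, -1, n_steps = 2000, seed = 10)
  expect_identical(a$trajectory$xyz, b$trajectory$xyz)
  expect_identical(a$force_trace$forces, b$force_trace$forces)
  expect_false(identical(a$trajectory$xyz, c$trajectory$xyz))
})

test_that("unstable integration aborts with a diagnostic", {
  m <- spring_model(n_chains = 1, n_beads = 3, gamma = 1e-4)
  expect_error(simulate_overdamped(m, -500, n_steps = 1000, dt = 1,
                                   temperature = 0, seed = 1),
               "unstable")
})

test_that("pore cylinder fixture encodes its radius profile by construction", {
  cyl <- make_pore_cylinder(function(z) 3, axial_extent = c(-5, 5))
  # ring atoms sit exactly at accessible radius + vdw
  r <- sqrt(cyl$xyz[, 1]^2 + cyl$xyz[, 2]^2)
  expect_close(r, 3 + 1.7, 1e-9)
  expect_error(make_pore_cylinder(function(z) -1, axial_extent = c(0, 1)),
               ">= 0")
})

test_that("ion drift generator returns wrapped coordinates and a truth log", {
  sim <- make_ion_drift_trajectory(n_ions = 10, drift = 4, n_frames = 150,
                                   seed = 3)
  expect_equal(n_frames(sim$trajectory), 150L)
  z <- sim$trajectory$xyz[, , 3]
  expect_true(all(z >= 0 & z <= 80))
  expect_true(all(c("ion", "entry_time", "exit_time", "direction") %in%
                    names(sim$events)))
  if (nrow(sim$events) > 0)
    expect_true(all(sim$events$exit_time > sim$events$entry_time))
  # pure function of the seed
  sim2 <- make_ion_drift_trajectory(n_ions = 10, drift = 4, n_frames = 150,
                                    seed = 3)
  expect_identical(sim$trajectory$xyz, sim2$trajectory$xyz)
  expect_identical(sim$events, sim2$events)
})

test_that("distance-trace generator injects the requested jump", {
  x <- make_distance_trace_with_jump(300, baseline = 8, noise_sd = 0.1,
                                     jump_at_frame = 250,
                                     jump_amplitude = 1, seed = 5)
  expect_equal(length(x), 300L)
  expect_close(mean(x[1:250]), 8, 0.05)
  expect_close(mean(x[251:300]), 9, 0.1)
  # amplitude 0 is equivalent to no jump
  a <- make_distance_trace_with_jump(100, jump_at_frame = 50,
                                     jump_amplitude = 0, seed = 6)
  b <- make_distance_trace_with_jump(100, jump_at_frame = NULL, seed = 6)
  expect_identical(a, b)
})

test_that("hydrogen-bond toy reproduces the requested geometry exactly", {
  s <- make_hbond_toy(2.9, 170)
  d <- sqrt(sum((s$xyz[1, ] - s$xyz[3, ])^2))
  expect_equal(d, 2.9, tolerance = 1e-12)
  u <- s$xyz[1, ] - s$xyz[2, ]; v <- s$xyz[3, ] - s$xyz[2, ]
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(ang, 170, tolerance = 1e-9)
  expect_error(make_hbond_toy(0.5, 180), "no geometry")
})

test_that("rigid-rotation fixture leaves non-selected atoms untouched", {
  s <- synthetic_channel_model()
  map <- synthetic_channel_map()
  sel <- select_domain(s, map, "TRP")
  tr <- make_rigid_rotation_trajectory(s, sel, c(0, 10), c(0, 30))
  expect_equal(n_frames(tr), 2L)
  other <- setdiff(seq_len(nrow(s$xyz)), sel)
  expect_close(frame_xyz(tr, 2)[other, ], s$xyz[other, ], 1e-12)
  expect_close(frame_xyz(tr, 1), s$xyz, 1e-12)  # (0, 0) frame identical
})
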