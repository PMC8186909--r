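random_structure <- function(n = 40, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(serial = 1:n, name = "CA", resname = "GLY", chain = "A",
                      resno = 1:n, insert = "", occupancy = 1, element = "C",
                      stringsAsFactors = FALSE)
  structure_new(atoms, matrix(rnorm(3 * n, sd = 8), ncol = 3))
}

test_that("superposition recovers a known rigid transform", {
  s <- random_structure()
  expect_equal(superpose(s$xyz, s$xyz)$rmsd, 0, tolerance = 1e-10)

  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(s$xyz %*% t(R), 2, c(3, -2, 5), "+")
  fit <- superpose(moved, s$xyz)
  expect_lt(fit$rmsd, 1e-9)
  expect_close(fit$R %*% R, diag(3), 1e-9)  # recovered rotation inverts R
  expect_equal(det(fit$R), 1, tolerance = 1e-9)

  # mirror images require a reflection, which is refused: RMSD stays > 0
  mirror <- s$xyz %*% diag(c(-1, 1, 1))
  fitm <- superpose(mirror, s$xyz)
  expect_equal(det(fitm$R), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.5)

  # collinear selections are degenerate
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("com distance series tracks constructed separations in nm", {
  tr <- drift_trajectory(5)  # atom 1 moves +2 A in z per frame
  d <- com_distance_series(tr, selA = 1L, selB = 2L)
  expect_length(d, 5L)
  d0 <- sqrt(sum((tr$topology$xyz[1, ] - tr$topology$xyz[2, ])^2))
  expect_equal(d[1], sqrt(sum((c(0, 0, 0) - tr$topology$xyz[2, ])^2)) / 10,
               tolerance = 1e-9)
  # static selections give a constant series
  d2 <- com_distance_series(tr, selA = 3L, selB = 4L)
  expect_close(diff(d2), 0, 1e-12)
})

test_that("sharp-change filter retains exactly the pre-jump prefix", {
  no_jump <- make_distance_trace_with_jump(500, noise_sd = 0.1, seed = 1)
  f <- sharp_change_filter(no_jump)
  expect_equal(f$retained, 500L)
  expect_true(is.na(f$onset))

  jmp <- make_distance_trace_with_jump(300, noise_sd = 0.1,
                                       jump_at_frame = 250,
                                       jump_amplitude = 1.0, seed = 2)
  f2 <- sharp_change_filter(jmp)
  expect_equal(f2$retained, 250L)
  expect_equal(f2$onset, 251L)

  # idempotence: filtering the retained prefix keeps all of it
  f3 <- sharp_change_filter(jmp[seq_len(f2$retained)])
  expect_equal(f3$retained, f2$retained)

  # zero-SD baseline falls back to the absolute threshold with a warning
  const <- c(rep(1, 50), rep(5, 50))
  expect_error(sharp_change_filter(const, baseline_window = 20), "zero")
  expect_warning(f4 <- sharp_change_filter(const, baseline_window = 20,
                                           abs_threshold = 1), "absolute")
  expect_equal(f4$retained, 50L)
  expect_error(sharp_change_filter(1:5, baseline_window = 10), "longer")
})

test_that("PCA equals a brute-force covariance eigendecomposition", {
  set.seed(7)
  n <- 10; m <- 6
  dat <- matrix(rnorm(n * 3 * m), n)
  model <- fit_pca(dat)
  # brute force: explicit covariance then eigen()
  cen <- sweep(dat, 2, colMeans(dat))
  C <- matrix(0, ncol(dat), ncol(dat))
  for (i in seq_len(n)) C <- C + tcrossprod(cen[i, ])
  C <- C / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  k <- length(model$values)
  expect_close(model$values, e$values[seq_len(k)], 1e-8)
  for (j in seq_len(min(5, k))) {
    # eigenvectors match up to sign
    expect_lt(min(sum((model$vectors[, j] - e$vectors[, j])^2),
                  sum((model$vectors[, j] + e$vectors[, j])^2)), 1e-8)
  }
  # orthonormality and variance conservation
  expect_close(crossprod(model$vectors), diag(k), 1e-8)
  expect_equal(sum(model$values), sum(diag(C)), tolerance = 1e-8)
  # projections of the mean frame are zero
  expect_close(colMeans(model$projections), 0, 1e-8)
})

test_that("PCA degenerate and directional cases behave", {
  # frames along one line in conformation space: exactly 1 nonzero eigenvalue
  base <- rnorm(12)
  dirn <- rnorm(12)
  dat <- t(sapply(seq(0, 1, length.out = 8), function(a) base + a * dirn))
  model <- fit_pca(dat)
  expect_gt(model$values[1], 0)
  expect_close(model$values[-1], 0, 1e-10)
  expect_error(fit_pca(dat[1, , drop = FALSE]), "at least 2")

  # sign convention: the designated group projects positively
  grp <- rep(c("free", "push"), each = 4)
  m2 <- fit_pca(dat, groups = grp, positive_group = "push")
  expect_gte(mean(m2$projections[grp == "push", 1]), 0)
})

test_that("extreme structures are the projection extrema with early ties", {
  dat <- matrix(rnorm(20 * 9), 20)
  model <- fit_pca(dat)
  ex <- extreme_structures(model, 1)
  p <- model$projections[, 1]
  expect_equal(ex$min, which.min(p))
  expect_equal(ex$max, which.max(p))
  expect_true(ex$min != ex$max)
  # monotone projections: first and last frames
  mono <- t(sapply(1:6, function(a) a * c(1, 0, 0, 1, 0, 0)))
  mm <- fit_pca(mono)
  exm <- extreme_structures(mm, 1)
  expect_setequal(c(exm$min, exm$max), c(1, 6))
})

test_that("domain axis matches an ideal helix axis and rotates equivariantly", {
  t <- seq(0, 20 * pi, length.out = 201)
  helix <- cbind(cos(t), sin(t), seq(0, 100, length.out = 201))
  ax <- domain_axis(helix)
  expect_lt(acos(abs(sum(ax * c(0, 0, 1)))) * 180 / pi, 1)

  th <- 40 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  ax2 <- domain_axis(helix %*% t(R), ref_dir = as.vector(R %*% ax))
  expect_close(abs(sum(ax2 * (R %*% ax))), 1, 1e-6)
})

# a compact helix segment whose axis is tilted 45 deg from z: a stand-in for
# an amphipathic domain helix, with a well-separated principal axis
tilted_helix_structure <- function() {
  t <- seq(0, 6 * pi, length.out = 40)
  helix <- cbind(cos(t), sin(t), seq(0, 25, length.out = 40))
  th <- 45 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  core <- matrix(c(60, 0, 0, 60, 5, 0, 60, 0, 5, 65, 0, 0, 65, 5, 5),
                 ncol = 3, byrow = TRUE)  # immobile reference cluster
  xyz <- rbind(helix %*% t(R), core)
  n <- nrow(xyz)
  atoms <- data.frame(serial = 1:n, name = "CA", resname = "GLY",
                      chain = c(rep("A", 40), rep("B", 5)),
                      resno = 1:n, insert = "", occupancy = 1, element = "C",
                      stringsAsFactors = FALSE)
  structure_new(atoms, xyz)
}

test_that("tilt/rotation angles invert the rigid-rotation fixture", {
  s <- tilted_helix_structure()
  sel <- 1:40
  fit_sel <- 41:45

  tilt_in <- c(0, 5, 10, 15, 25)
  rot_in <- c(0, 20, 40, -30, 120)
  tr <- make_rigid_rotation_trajectory(s, sel, tilt_in, rot_in)
  ang <- tilt_rotation_series(tr, sel, fit_sel = fit_sel)
  expect_close(ang$tilt, tilt_in, 1e-6)
  expect_close(ang$rotation, rot_in, 1e-6)

  # additivity: two successive 15 deg z-rotations equal one 30 deg rotation
  tr2 <- make_rigid_rotation_trajectory(s, sel, c(0, 0, 0), c(0, 15, 30))
  ang2 <- tilt_rotation_series(tr2, sel, fit_sel = fit_sel)
  expect_close(ang2$rotation[3], 2 * ang2$rotation[2], 1e-6)

  # identity frame reads (0, 0)
  expect_close(c(ang$tilt[1], ang$rotation[1]), c(0, 0), 1e-9)
})
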