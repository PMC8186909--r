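# PCA over concatenated trajectories, extreme-structure extraction, domain
# tilt/rotation angles, and the sharp-change trajectory filter.

# ---- superposition ----------------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation that minimise the
#' RMSD between the selected atoms of a mobile and a reference coordinate
#' set. A reflection is never returned: when the optimal orthogonal
#' transform would be improper, the smallest singular direction is flipped,
#' which leaves a nonzero RMSD on mirror-image inputs.
#'
#' @param mobile,reference n-by-3 coordinate matrices (or `Structure`s).
#' @param sel atom indices used for the fit (>= 3 non-collinear atoms);
#'   default all.
#' @return list with `R` (3x3 rotation), `t` (translation), `rmsd`
#'   (Angstrom, over `sel`), and `xyz`, the whole mobile set transformed.
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  mx <- if (inherits(mobile, "Structure")) mobile$xyz else as.matrix(mobile)
  rx <- if (inherits(reference, "Structure")) reference$xyz else as.matrix(reference)
  if (is.null(sel)) sel <- seq_len(nrow(mx))
  if (length(sel) < 3L) stop("need at least 3 atoms to superpose")
  A <- mx[sel, , drop = FALSE]
  B <- rx[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2L)
    stop("degenerate (collinear) selection geometry")
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tvec <- cb - as.vector(R %*% ca)
  fitted <- sweep(mx %*% t(R), 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((fitted[sel, , drop = FALSE] - B)^2)))
  list(R = R, t = tvec, rmsd = rmsd, xyz = fitted)
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' @param traj a `Trajectory`.
#' @param sel fit selection (atom indices).
#' @param ref_frame reference frame index (default first).
#' @return a `Trajectory` with all frames rigidly fitted on `sel`.
#' @export
superpose_trajectory <- function(traj, sel, ref_frame = 1L) {
  ref <- frame_xyz(traj, ref_frame)
  out <- traj$xyz
  for (i in seq_len(n_frames(traj)))
    out[i, , ] <- superpose(frame_xyz(traj, i), ref, sel)$xyz
  trajectory_new(out, traj$times, topology = traj$topology, box = traj$box)
}

# ---- centre-of-mass distance series ----------------------------------------

#' Per-frame centre-of-mass distance between two selections
#'
#' @param traj a `Trajectory` with topology.
#' @param selA,selB atom index vectors.
#' @return numeric vector, one distance per frame, in nm.
#' @export
com_distance_series <- function(traj, selA, selB) {
  if (is.null(traj$topology)) stop("trajectory has no topology")
  masses <- mass_of(traj$topology$atoms$element)
  vapply(seq_len(n_frames(traj)), function(i) {
    a <- com_of_frame(traj, i, selA, masses)
    b <- com_of_frame(traj, i, selB, masses)
    sqrt(sum((a - b)^2)) / 10
  }, numeric(1))
}

# ---- sharp-change filter ----------------------------------------------------

#' Discard frames after a sharp change of a monitored series
#'
#' Implements the rule that data after a sharp change of a monitored
#' distance are discarded: a baseline mean and SD are taken from the first
#' `baseline_window` frames; the first index where the series deviates from
#' the baseline mean by more than `threshold_sd` baseline SDs for at least
#' `min_persist` consecutive frames marks the change, and only frames
#' strictly before it are retained. If no such run exists, all frames are
#' retained.
#'
#' @param series numeric vector.
#' @param baseline_window number of leading frames defining the baseline
#'   (default: 10 percent of the series, at least 5).
#' @param threshold_sd deviation threshold in baseline SDs (default 5).
#' @param min_persist minimum consecutive deviating frames (default 3).
#' @param abs_threshold absolute fallback threshold, used with a warning when
#'   the baseline SD is zero.
#' @return list with `retained` (prefix length), `onset` (first deviating
#'   frame index, or `NA`), and `threshold` (the absolute deviation cut
#'   used).
#' @export
sharp_change_filter <- function(series, baseline_window = NULL,
                                threshold_sd = 5, min_persist = 3,
                                abs_threshold = NULL) {
  n <- length(series)
  if (is.null(baseline_window)) baseline_window <- max(5L, floor(0.1 * n))
  if (n <= baseline_window)
    stop("series must be longer than the baseline window")
  mu <- mean(series[seq_len(baseline_window)])
  s <- sd(series[seq_len(baseline_window)])
  if (s == 0) {
    if (is.null(abs_threshold))
      stop("baseline SD is zero and no abs_threshold given")
    warning("baseline SD is zero; falling back to the absolute threshold")
    cut <- abs_threshold
  } else cut <- threshold_sd * s
  dev <- abs(series - mu) > cut
  r <- rle(dev)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_persist)
  if (length(hit) == 0L)
    return(list(retained = n, onset = NA_integer_, threshold = cut))
  onset <- starts[hit[1]]
  list(retained = onset - 1L, onset = onset, threshold = cut)
}

# ---- PCA --------------------------------------------------------------------

#' Principal component analysis of superposed coordinates
#'
#' Covariance eigendecomposition of the selected atoms' coordinates over
#' frames (essential dynamics). Input frames are expected to be
#' concatenated, sharp-change-filtered and rigidly superposed already; this
#' function only centres and decomposes. Computed through the thin SVD of
#' the centred data matrix, which equals the covariance eigendecomposition.
#'
#' @param x a `Trajectory`, or a frames-by-3m coordinate matrix.
#' @param sel atom indices entering the analysis (Trajectory input only;
#'   default all atoms).
#' @param groups optional factor, one label per frame (e.g. free / push /
#'   pull), stored with the model and used by `positive_group`.
#' @param positive_group optional group label: each eigenvector's sign is
#'   fixed so that this group's mean projection is non-negative (the
#'   convention that larger values on the gating component correspond to the
#'   more dilated, pushed states).
#' @return a `PCAModel`: list with `mean`, `vectors` (columns, orthonormal),
#'   `values` (variances, Angstrom^2, non-increasing), `projections`
#'   (frames x components), `sel`, `groups`.
#' @export
fit_pca <- function(x, sel = NULL, groups = NULL, positive_group = NULL) {
  if (inherits(x, "Trajectory")) {
    if (is.null(sel)) sel <- seq_len(dim(x$xyz)[2])
    nf <- n_frames(x)
    dat <- matrix(NA_real_, nf, 3L * length(sel))
    for (i in seq_len(nf))
      dat[i, ] <- as.vector(t(frame_xyz(x, i)[sel, , drop = FALSE]))
  } else {
    dat <- as.matrix(x)
    nf <- nrow(dat)
  }
  if (nf < 2L) stop("need at least 2 frames for PCA")
  mu <- colMeans(dat)
  cen <- sweep(dat, 2, mu)
  s <- svd(cen, nu = 0)
  keep <- seq_len(min(nf - 1L, ncol(dat)))
  values <- (s$d^2 / (nf - 1L))[keep]
  vectors <- s$v[, keep, drop = FALSE]
  proj <- cen %*% vectors
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != nf) stop("groups length must equal frame count")
    if (!is.null(positive_group)) {
      gsel <- groups == positive_group
      if (!any(gsel)) stop("positive_group not present in groups")
      flip <- colMeans(proj[gsel, , drop = FALSE]) < 0
      vectors[, flip] <- -vectors[, flip]
      proj[, flip] <- -proj[, flip]
    }
  }
  obj <- list(mean = mu, vectors = vectors, values = values,
              projections = proj, sel = sel, groups = groups)
  class(obj) <- "PCAModel"
  obj
}

#' @export
print.PCAModel <- function(x, ...) {
  tot <- sum(x$values)
  cat("PCAModel:", nrow(x$projections), "frames,",
      length(x$values), "components; var explained by PC1/PC2:",
      sprintf("%.1f%% / %.1f%%", 100 * x$values[1] / tot,
              100 * x$values[2] / tot), "\n")
  invisible(x)
}

#' Frames with extreme projections along a component
#'
#' @param model a `PCAModel`.
#' @param component component index.
#' @return list with `min` and `max` frame indices (ties resolved to the
#'   earlier frame).
#' @export
extreme_structures <- function(model, component = 2L) {
  p <- model$projections[, component]
  list(min = which.min(p), max = which.max(p))
}

# ---- domain axis and angles -------------------------------------------------

#' Dominant principal axis of a coordinate set
#'
#' The unit eigenvector of the coordinate covariance with the largest
#' eigenvalue (the direction of largest spread), sign-fixed by a reference
#' direction.
#'
#' @param xyz n-by-3 coordinate matrix (e.g. the C-alpha atoms of a domain).
#' @param ref_dir sign convention: the axis is flipped if its dot product
#'   with `ref_dir` is negative (default +z).
#' @return unit length-3 vector.
#' @export
domain_axis <- function(xyz, ref_dir = c(0, 0, 1)) {
  xyz <- as.matrix(xyz)
  cen <- sweep(xyz, 2, colMeans(xyz))
  e <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  ax <- e$vectors[, 1]
  if (sum(ax * ref_dir) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

angle_deg <- function(u, v) {
  c0 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(c0, -1), 1)) * 180 / pi
}

#' Tilt and rotation angles of a domain over a trajectory
#'
#' Frames are first rigidly superposed on an immobile reference selection
#' (e.g. the transmembrane core); the domain axis is then computed per frame
#' from the analysis selection. The tilt angle is the change of the angle
#' between the domain axis and the z axis relative to the reference frame;
#' the rotation angle is the signed angle between the XY-plane projections
#' of the current and reference axes, positive for a clockwise rotation
#' viewed from -z (the intracellular side). Frames whose axis is parallel to
#' z have an undefined rotation and are flagged `NA`. Axis sign is kept
#' stable across contiguous frames by continuity with the previous frame.
#'
#' @param traj a `Trajectory`.
#' @param sel analysis selection (domain atoms, typically C-alpha).
#' @param fit_sel immobile selection used for superposition; `NULL` skips
#'   the fit (frames already aligned).
#' @param ref_frame reference frame index (default first).
#' @param ref_dir initial axis sign convention passed to [domain_axis()].
#' @return `AngleSeries` data.frame: `time`, `tilt`, `rotation` (degrees).
#' @export
tilt_rotation_series <- function(traj, sel, fit_sel = NULL, ref_frame = 1L,
                                 ref_dir = c(0, 0, 1)) {
  work <- if (is.null(fit_sel)) traj
          else superpose_trajectory(traj, fit_sel, ref_frame)
  ax0 <- domain_axis(frame_xyz(work, ref_frame)[sel, , drop = FALSE], ref_dir)
  th0 <- angle_deg(ax0, c(0, 0, 1))
  prev <- ax0
  nf <- n_frames(work)
  tilt <- rotation <- numeric(nf)
  for (i in seq_len(nf)) {
    ax <- domain_axis(frame_xyz(work, i)[sel, , drop = FALSE], ref_dir)
    # when the axis is nearly orthogonal to ref_dir the fixed sign rule is
    # unreliable; fall back to continuity with the previous frame
    if (abs(sum(ax * ref_dir)) < 0.1 && sum(ax * prev) < 0) ax <- -ax
    prev <- ax
    tilt[i] <- angle_deg(ax, c(0, 0, 1)) - th0
    p0 <- ax0[1:2]; p <- ax[1:2]
    if (sqrt(sum(p^2)) < 1e-9 || sqrt(sum(p0^2)) < 1e-9) {
      rotation[i] <- NA_real_
    } else {
      rotation[i] <- atan2(p0[1] * p[2] - p0[2] * p[1],
                           sum(p0 * p)) * 180 / pi
    }
  }
  out <- data.frame(time = work$times, tilt = tilt, rotation = rotation)
  class(out) <- c("AngleSeries", "data.frame")
  out
}
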