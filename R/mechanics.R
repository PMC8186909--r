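# Reaction-force aggregation, in-plane torque, spring-constant estimation,
# elastic-range scan, and force-transfer onset/speed.

KJ_MOL_NM_TO_PN <- 1000 / (6.02214076e23 * 1e-9) * 1e12  # = 1.66054 pN

#' Exact force unit conversion
#'
#' Converts between piconewton, newton and the MD-engine unit
#' kJ mol^-1 nm^-1 (1 kJ mol^-1 nm^-1 = 1.66054 pN, from the Avogadro
#' constant).
#'
#' @param value numeric.
#' @param from,to one of `"pN"`, `"N"`, `"kJ/mol/nm"`.
#' @return converted value.
#' @export
convert_force_units <- function(value, from, to) {
  to_pn <- c("pN" = 1, "N" = 1e12, "kJ/mol/nm" = KJ_MOL_NM_TO_PN)
  if (!from %in% names(to_pn)) stop("unknown force unit: ", from)
  if (!to %in% names(to_pn)) stop("unknown force unit: ", to)
  value * to_pn[[from]] / to_pn[[to]]
}

# ---- ForceTrace -------------------------------------------------------------

#' Per-chain restraint reaction-force trace
#'
#' Times in ps, per-chain 3-vector forces in pN, and the chains' force
#' application points in Angstrom (static, or per frame). The reaction force
#' of a position restraint is equal and opposite to the force the rest of
#' the system exerts on the restrained atoms.
#'
#' @param times numeric vector, ps.
#' @param forces array `n_frames x n_chains x 3`, pN.
#' @param points `n_chains x 3` matrix (static application points, Angstrom)
#'   or `n_frames x n_chains x 3` array.
#' @param meta free-form metadata list (restrained selection, source, ...).
#' @return object of class `ForceTrace`.
#' @export
force_trace <- function(times, forces, points = NULL, meta = list()) {
  if (length(dim(forces)) != 3L || dim(forces)[3] != 3L)
    stop("forces must be an n_frames x n_chains x 3 array")
  if (dim(forces)[1] != length(times))
    stop("reaction-force record length must equal frame count")
  if (dim(forces)[2] < 1L) stop("need at least one chain")
  obj <- list(times = as.numeric(times), forces = forces, points = points,
              meta = meta)
  class(obj) <- "ForceTrace"
  obj
}

#' Read a whitespace/TSV reaction-force table
#'
#' Expected layout: a time column (ps) followed by fx fy fz triples, one per
#' chain, in pN.
#'
#' @param path file path.
#' @param points optional application points forwarded to [force_trace()].
#' @return a `ForceTrace`.
#' @export
read_force_trace <- function(path, points = NULL) {
  dat <- as.matrix(data.table::fread(path))
  nc <- (ncol(dat) - 1L) / 3L
  if (nc != round(nc)) stop("column count must be 1 + 3 x n_chains")
  forces <- array(NA_real_, dim = c(nrow(dat), nc, 3L))
  for (c in seq_len(nc))
    forces[, c, ] <- dat[, (2L + 3L * (c - 1L)):(1L + 3L * c)]
  force_trace(dat[, 1], forces, points = points,
              meta = list(source = path))
}

window_index <- function(times, window) {
  if (is.null(window)) return(seq_along(times))
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0L) stop("window contains no samples")
  idx
}

#' Time-averaged reaction forces
#'
#' Mean and SD of the per-chain force vectors over a time window, plus the
#' net (chain-summed) mean force.
#'
#' @param trace a `ForceTrace`.
#' @param window `c(t0, t1)` in ps, or `NULL` for the whole trace.
#' @return list with `mean` (n_chains x 3), `sd` (n_chains x 3), `net`
#'   (length 3), all pN.
#' @export
reaction_force_summary <- function(trace, window = NULL) {
  idx <- window_index(trace$times, window)
  f <- trace$forces[idx, , , drop = FALSE]
  m <- apply(f, c(2, 3), mean)
  s <- apply(f, c(2, 3), sd)
  if (length(idx) == 1L) s[] <- 0
  list(mean = m, sd = s, net = colSums(m))
}

# ---- planar torque ----------------------------------------------------------

#' Net torque of the planar reaction-force components about the z axis
#'
#' Projects the time-averaged per-chain reaction forces onto the membrane
#' plane and computes the net torque about the z axis at the mean
#' application points, tau_z = sum_chains (r x F)_z, in pN nm. The sign
#' convention matches the rotation-angle convention: positive tau_z drives a
#' clockwise rotation viewed from the intracellular (-z) side.
#'
#' With `symmetrize = TRUE` the chains' (point, force) pairs are rotated
#' into a common quadrant by the C4 symmetry and averaged before the torque
#' is taken; the symmetrized net planar force is then zero by construction.
#'
#' @param trace a `ForceTrace` with application points.
#' @param window averaging window `c(t0, t1)` ps, or `NULL`.
#' @param symmetrize average the chains under the C4 symmetry (default TRUE).
#' @param axis_origin xy point the torque is taken about (Angstrom).
#' @return a `TorqueSummary`: list with per-chain planar mean forces (pN),
#'   `net_planar_force` (pN), `torque_z` (pN nm), `symmetrized`.
#' @export
planar_torque <- function(trace, window = NULL, symmetrize = TRUE,
                          axis_origin = c(0, 0)) {
  if (is.null(trace$points)) stop("force trace has no application points")
  idx <- window_index(trace$times, window)
  fmean <- apply(trace$forces[idx, , , drop = FALSE], c(2, 3), mean)
  nc <- nrow(fmean)
  pts <- if (length(dim(trace$points)) == 3L)
    apply(trace$points[idx, , , drop = FALSE], c(2, 3), mean)
  else as.matrix(trace$points)
  r_nm <- sweep(pts[, 1:2, drop = FALSE], 2, axis_origin) / 10
  f_xy <- fmean[, 1:2, drop = FALSE]
  # per-chain torque contributions are rotation-invariant scalars, so the
  # total torque is the plain sum in both modes; symmetrization shapes the
  # reported per-chain force pattern (and zeroes the net planar force)
  tau <- sum(r_nm[, 1] * f_xy[, 2] - r_nm[, 2] * f_xy[, 1])
  if (symmetrize) {
    rot2 <- function(v, a) {
      ca <- cos(a); sa <- sin(a)
      cbind(ca * v[, 1] - sa * v[, 2], sa * v[, 1] + ca * v[, 2])
    }
    angs <- -2 * pi * (seq_len(nc) - 1) / nc
    f_rot <- matrix(0, nc, 2)
    for (c in seq_len(nc))
      f_rot[c, ] <- rot2(f_xy[c, , drop = FALSE], angs[c])
    f_bar <- colMeans(f_rot)
    per_chain <- t(vapply(seq_len(nc), function(c)
      as.vector(rot2(matrix(f_bar, 1), -angs[c])), numeric(2)))
    net <- colSums(per_chain)  # zero by construction for nc-fold symmetry
  } else {
    per_chain <- f_xy
    net <- colSums(f_xy)
  }
  obj <- list(planar_force_per_chain = per_chain, net_planar_force = net,
              torque_z = tau, symmetrized = symmetrize)
  class(obj) <- "TorqueSummary"
  obj
}

# ---- spring constant --------------------------------------------------------

is_stationary <- function(series, tol_sd = 0.5) {
  n <- length(series)
  h <- floor(n / 2)
  s <- sd(series)
  if (s == 0) return(TRUE)
  abs(mean(series[seq_len(h)]) - mean(series[(h + 1L):n])) < tol_sd * s
}

equil_window <- function(series) {
  n <- length(series)
  w <- series[(floor(n / 2) + 1L):n]
  if (!is_stationary(w))
    stop("series is not stationary over its second half")
  w
}

#' Spring constant from free and force-loaded length series
#'
#' Hooke estimate k = F / dz: dz is the difference of the equilibrated mean
#' region lengths between the free and the force-loaded run, F the applied
#' force per chain. Both series must reach stationarity (split-half mean
#' drift of the equilibration window below half its SD); the equilibration
#' window is the last half of each run. Uncertainty is estimated by block
#' averaging (`n_blocks` paired blocks).
#'
#' @param length_free,length_forced region-length series, nm.
#' @param force applied force per chain, pN (magnitude).
#' @param min_dz resolution floor for dz, nm; smaller responses error
#'   ("inelastic/no response").
#' @param n_blocks blocks for the uncertainty estimate.
#' @return a `SpringFit`: list with `k` (pN/nm), `dz` (nm, positive =
#'   compression under push), `F`, `k_sd`, `dz_sd`, window sizes.
#' @export
spring_constant <- function(length_free, length_forced, force,
                            min_dz = 0.05, n_blocks = 5L) {
  wf <- equil_window(length_free)
  wx <- equil_window(length_forced)
  dz <- abs(mean(wf) - mean(wx))
  if (dz < min_dz)
    stop("inelastic/no response: |dz| = ", signif(dz, 3),
         " nm is below the resolution floor")
  k <- abs(force) / dz
  split_blocks <- function(x) {
    nb <- min(n_blocks, length(x))
    split(x, cut(seq_along(x), nb, labels = FALSE))
  }
  bf <- vapply(split_blocks(wf), mean, numeric(1))
  bx <- vapply(split_blocks(wx), mean, numeric(1))
  nb <- min(length(bf), length(bx))
  dz_b <- abs(bf[seq_len(nb)] - bx[seq_len(nb)])
  k_b <- abs(force) / pmax(dz_b, 1e-9)
  fit <- list(k = k, dz = dz, F = abs(force), k_sd = sd(k_b),
              dz_sd = sd(dz_b), n_free = length(wf), n_forced = length(wx))
  class(fit) <- "SpringFit"
  fit
}

#' @export
print.SpringFit <- function(x, ...) {
  cat(sprintf("SpringFit: k = %.2f +/- %.2f pN/nm (F = %g pN, dz = %.3f nm)\n",
              x$k, x$k_sd, x$F, x$dz))
  invisible(x)
}

#' Stiffness of parallel springs
#'
#' Parallel composition: the bundle constant is the sum of the branch
#' constants.
#'
#' @param per_chain_ks numeric vector of per-chain spring constants, pN/nm.
#' @return bundle spring constant, pN/nm.
#' @export
parallel_bundle_constant <- function(per_chain_ks) {
  if (length(per_chain_ks) < 1L || any(per_chain_ks <= 0))
    stop("per-chain constants must be positive")
  sum(per_chain_ks)
}

#' Spring constant versus applied force, with a linearity verdict
#'
#' Fits k = F/dz for each force-loaded run against the common free run and
#' classifies the response as `"elastic"` when the relative spread of k
#' across forces stays below `spread_threshold`, `"nonlinear"` otherwise
#' (`"undetermined"` for a single run).
#'
#' @param length_free free-run length series, nm.
#' @param runs named or unnamed list of `list(F = force pN, series = nm)`.
#' @param spread_threshold maximum relative spread (max-min)/mean for an
#'   elastic verdict (default 0.25).
#' @return list with `table` (data.frame F, dz, k, k_sd) and `verdict`.
#' @export
elastic_range_scan <- function(length_free, runs, spread_threshold = 0.25) {
  fits <- lapply(runs, function(r)
    spring_constant(length_free, r$series, r$F))
  tab <- data.frame(F = vapply(fits, `[[`, numeric(1), "F"),
                    dz = vapply(fits, `[[`, numeric(1), "dz"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    k_sd = vapply(fits, `[[`, numeric(1), "k_sd"))
  verdict <- if (nrow(tab) < 2L) "undetermined"
  else if ((max(tab$k) - min(tab$k)) / mean(tab$k) < spread_threshold)
    "elastic" else "nonlinear"
  list(table = tab, verdict = verdict)
}

# ---- force-transfer onset and speed -----------------------------------------

#' Onset of deviation between two aligned traces
#'
#' First time at which the absolute difference of two time-aligned series
#' exceeds `threshold_sd` baseline SDs of the difference for at least
#' `min_persist` consecutive samples. Returns `NA` when the traces never
#' deviate. Adding a common offset to both traces does not change the
#' result.
#'
#' @param trace_free,trace_perturbed numeric series on the same time grid.
#' @param times sample times, ps (default index * dt).
#' @param dt sampling interval, ps, used when `times` is missing.
#' @param baseline_window baseline length, ps.
#' @param threshold_sd threshold in baseline SDs (default 3).
#' @param min_persist consecutive samples required (default 5).
#' @return onset time, ps, or `NA`.
#' @export
arrival_onset <- function(trace_free, trace_perturbed, times = NULL,
                          dt = 0.01, baseline_window = 2,
                          threshold_sd = 3, min_persist = 5L) {
  if (length(trace_free) != length(trace_perturbed))
    stop("traces must have equal length")
  if (is.null(times)) times <- seq_along(trace_free) * dt
  d <- trace_perturbed - trace_free
  base <- d[times <= times[1] + baseline_window]
  if (length(base) < 2L) stop("baseline window too short")
  mu <- mean(base)
  s <- sd(base)
  if (s == 0) {
    if (all(d == mu)) return(NA_real_)  # no deviation at all
    stop("zero baseline SD in the trace difference")
  }
  dev <- abs(d - mu) > threshold_sd * s
  r <- rle(dev)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_persist)
  if (length(hit) == 0L) return(NA_real_)
  times[starts[hit[1]]]
}

#' Force-transfer speed from onset times
#'
#' v = L / mean(onsets), with the SD propagated from the onset spread
#' (first order: sd_v = v * sd(t) / mean(t)).
#'
#' @param onsets onset times, ps (NA entries dropped).
#' @param L region length, nm.
#' @return a `TransferEstimate`: list with `v` (nm/ps), `v_sd`, `onsets`,
#'   `L`.
#' @export
transfer_speed <- function(onsets, L) {
  onsets <- onsets[!is.na(onsets)]
  if (length(onsets) == 0L) stop("no onset times")
  if (any(onsets <= 0)) stop("onset times must be positive")
  v <- L / mean(onsets)
  v_sd <- if (length(onsets) > 1L) v * sd(onsets) / mean(onsets) else NA_real_
  obj <- list(v = v, v_sd = v_sd, onsets = onsets, L = L)
  class(obj) <- "TransferEstimate"
  obj
}

#' @export
print.TransferEstimate <- function(x, ...) {
  cat(sprintf("TransferEstimate: v = %.2f +/- %.2f nm/ps over L = %g nm (%d onsets)\n",
              x$v, x$v_sd, x$L, length(x$onsets)))
  invisible(x)
}
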