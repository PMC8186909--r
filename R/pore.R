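# Pore-radius profile along the permeation axis (largest inscribed sphere,
# HOLE-like), constriction search, and gate-region water counts.

# objective: accessible radius of a probe centred at (cx, cy, z)
pore_objective <- function(cx, cy, z, axyz, avdw) {
  d <- sqrt((axyz[, 1] - cx)^2 + (axyz[, 2] - cy)^2 + (axyz[, 3] - z)^2)
  min(d - avdw)
}

# gradient-free 2-D pattern search, 0.05 Angstrom final step
pore_maximise <- function(seed_xy, z, axyz, avdw, step0 = 1.0,
                          step_min = 0.05, max_wander = 15) {
  cx <- seed_xy[1]; cy <- seed_xy[2]
  best <- pore_objective(cx, cy, z, axyz, avdw)
  step <- step0
  dirs <- cbind(c(1, -1, 0, 0, 1, 1, -1, -1), c(0, 0, 1, -1, 1, -1, 1, -1))
  while (step >= step_min) {
    improved <- FALSE
    for (k in seq_len(nrow(dirs))) {
      nx <- cx + step * dirs[k, 1]; ny <- cy + step * dirs[k, 2]
      if (sqrt((nx - seed_xy[1])^2 + (ny - seed_xy[2])^2) > max_wander) next
      v <- pore_objective(nx, ny, z, axyz, avdw)
      if (v > best) {
        best <- v; cx <- nx; cy <- ny; improved <- TRUE
      }
    }
    if (!improved) step <- step / 2
  }
  c(cx, cy, best)
}

#' Pore-radius profile along the z axis
#'
#' For each z slice, the accessible pore radius is the largest inscribed
#' sphere radius: the maximum, over in-plane probe centres c, of the minimum
#' over nearby atoms of (distance to atom centre - atom vdW radius). Atoms
#' within a slab of half-width `z_step` around the slice (overlapping slabs)
#' participate. The in-plane maximisation is a gradient-free pattern search
#' seeded at the previous slice's centre (the axis seed at the first
#' slice), in the spirit of the HOLE algorithm but without simulated
#' annealing - adequate for near-axial channel pores.
#'
#' Slabs with no atoms, or whose accessible radius exceeds `unbounded_radius`,
#' are flagged unbounded (radius `NA`); negative maxima (occluded slices)
#' are clamped to 0 and flagged.
#'
#' @param x a `Structure` (one frame).
#' @param sel atom indices lining the pore (default: all atoms).
#' @param z_range `c(z_min, z_max)`, Angstrom; must cover the region of
#'   interest (e.g. the gate).
#' @param z_step slice spacing and slab half-width, Angstrom (default 0.5).
#' @param vdw_table named vdW radius table (default [vdw_radii()]).
#' @param backbone_only restrict the selection to backbone N/CA/C/O atoms.
#' @param axis_xy in-plane seed for the first slice (default the selection
#'   centroid).
#' @param unbounded_radius radius, Angstrom, beyond which a slice is flagged
#'   unbounded rather than reported (default 15).
#' @return a `PoreProfile` data.frame: `z`, `radius` (Angstrom, `NA` when
#'   unbounded), `cx`, `cy`, `status` (`"ok"`, `"occluded"`, `"unbounded"`),
#'   with attributes `backbone_only` and `z_step`.
#' @export
pore_profile <- function(x, sel = NULL, z_range = NULL, z_step = 0.5,
                         vdw_table = vdw_radii(), backbone_only = FALSE,
                         axis_xy = NULL, unbounded_radius = 15) {
  stopifnot(inherits(x, "Structure"))
  if (is.null(sel)) sel <- seq_len(n_atoms(x))
  if (length(sel) == 0L) stop("empty pore selection")
  if (backbone_only) {
    sel <- sel[x$atoms$name[sel] %in% BACKBONE_NAMES]
    if (length(sel) == 0L) stop("backbone-only selection is empty")
  }
  axyz <- x$xyz[sel, , drop = FALSE]
  avdw <- vdw_of(x$atoms$element[sel], table = vdw_table)
  if (is.null(z_range)) z_range <- range(axyz[, 3])
  zs <- seq(z_range[1], z_range[2], by = z_step)
  if (is.null(axis_xy)) axis_xy <- colMeans(axyz[, 1:2, drop = FALSE])
  radius <- cx <- cy <- numeric(length(zs))
  status <- character(length(zs))
  seed <- axis_xy
  for (k in seq_along(zs)) {
    z <- zs[k]
    slab <- abs(axyz[, 3] - z) <= z_step
    if (!any(slab)) {
      radius[k] <- NA_real_; cx[k] <- seed[1]; cy[k] <- seed[2]
      status[k] <- "unbounded"
      next
    }
    res <- pore_maximise(seed, z, axyz[slab, , drop = FALSE], avdw[slab])
    cx[k] <- res[1]; cy[k] <- res[2]
    if (res[3] > unbounded_radius) {
      radius[k] <- NA_real_
      status[k] <- "unbounded"
    } else if (res[3] < 0) {
      radius[k] <- 0
      status[k] <- "occluded"
      seed <- res[1:2]
    } else {
      radius[k] <- res[3]
      status[k] <- "ok"
      seed <- res[1:2]
    }
  }
  out <- data.frame(z = zs, radius = radius, cx = cx, cy = cy,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "backbone_only") <- backbone_only
  attr(out, "z_step") <- z_step
  class(out) <- c("PoreProfile", "data.frame")
  out
}

#' Minimum pore radius near a z position
#'
#' @param profile a `PoreProfile`.
#' @param z_center window centre, Angstrom.
#' @param window half-width of the search window, Angstrom (the window is
#'   `z_center` plus/minus `window`).
#' @return list with `radius` (Angstrom) and `z` (location; ties resolve to
#'   the smaller z).
#' @export
min_radius_near <- function(profile, z_center, window) {
  inw <- which(abs(profile$z - z_center) <= window)
  if (length(inw) == 0L) stop("window does not intersect the profile z grid")
  vals <- profile$radius[inw]
  if (all(is.na(vals))) stop("no bounded slices inside the window")
  j <- inw[which.min(replace(vals, is.na(vals), Inf))]
  list(radius = profile$radius[j], z = profile$z[j])
}

#' Time-resolved pore profiles over a trajectory
#'
#' One [pore_profile()] per frame (identical arguments), suitable for
#' radius-versus-z-versus-time heat maps.
#'
#' @inheritParams pore_profile
#' @param traj a `Trajectory` with topology.
#' @param ... forwarded to [pore_profile()].
#' @return list of `PoreProfile`s (class `PoreProfileSeries`) with a
#'   `times` attribute.
#' @export
profile_series <- function(traj, sel = NULL, ...) {
  out <- lapply(seq_len(n_frames(traj)), function(i)
    pore_profile(frame_structure(traj, i), sel = sel, ...))
  attr(out, "times") <- traj$times
  class(out) <- "PoreProfileSeries"
  out
}

#' Minimum-radius time series of a profile series
#'
#' @param series a `PoreProfileSeries`.
#' @param z_center,window as in [min_radius_near()].
#' @return numeric vector of per-frame minimum radii, Angstrom.
#' @export
min_radius_series <- function(series, z_center, window) {
  vapply(series, function(p) min_radius_near(p, z_center, window)$radius,
         numeric(1))
}

#' Count water molecules in the gate cylinder
#'
#' Counts water oxygen atoms inside an axis-aligned cylinder centred at the
#' gate.
#'
#' @param x a `Structure`.
#' @param water_sel atom indices of water oxygens; by default, oxygen atoms
#'   of residues named HOH/WAT/SOL/TIP3/TIP4/SPC.
#' @param gate_center length-3 cylinder centre, Angstrom.
#' @param radius cylinder radius, Angstrom.
#' @param half_height cylinder half-height, Angstrom.
#' @return integer count (0 with a warning when no waters are present).
#' @export
count_waters_in_gate <- function(x, water_sel = NULL, gate_center,
                                 radius, half_height) {
  if (is.null(water_sel))
    water_sel <- which(x$atoms$resname %in%
                         c("HOH", "WAT", "SOL", "TIP3", "TIP4", "SPC") &
                       x$atoms$element == "O")
  if (length(water_sel) == 0L) {
    warning("no water oxygens in the structure")
    return(0L)
  }
  w <- x$xyz[water_sel, , drop = FALSE]
  inside <- abs(w[, 3] - gate_center[3]) <= half_height &
    sqrt((w[, 1] - gate_center[1])^2 + (w[, 2] - gate_center[2])^2) <= radius
  sum(inside)
}
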