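# Ion permeation: complete-crossing detection through the pore cylinder and
# conversion of event counts to current and conductance.

ELEMENTARY_CHARGE <- 1.602176634e-19  # C

default_ion_charges <- c(K = 1, NA. = 1, LI = 1, CL = -1, CA = 2, MG = 2)

#' Detect complete ion crossings through a bounded pore cylinder
#'
#' A crossing is recorded when an ion passes from beyond one boundary plane
#' (`z_lower`, `z_upper`) to beyond the other while its radial distance from
#' the cylinder axis stays below `radius` for every frame spent between the
#' planes. Re-entries without completion are not events; this is the
#' strictest convention, counting only full two-plane traversals. Periodic
#' z-jumps are unwrapped via the box before testing; a trajectory without
#' box information whose per-frame z displacement looks wrapped raises an
#' error.
#'
#' @param traj a `Trajectory` (topology identifies the ion species).
#' @param ion_sel atom indices of the ions (persistent across frames).
#' @param z_lower,z_upper boundary plane positions, Angstrom
#'   (`z_lower < z_upper`).
#' @param radius cylinder radius, Angstrom.
#' @param axis_xy cylinder axis in-plane position, Angstrom.
#' @param charges named charge table by element (units of e); defaults cover
#'   common ions.
#' @return data.frame of `CrossingEvent`s: `ion` (index within `ion_sel`),
#'   `species`, `charge`, `entry_time`, `exit_time` (ps), `direction`
#'   (`"+z"`/`"-z"`).
#' @export
detect_crossings <- function(traj, ion_sel, z_lower, z_upper, radius,
                             axis_xy = NULL, charges = default_ion_charges) {
  if (z_lower >= z_upper) stop("z_lower must be below z_upper")
  nf <- n_frames(traj)
  if (is.null(axis_xy)) {
    axis_xy <- if (!is.null(traj$box)) traj$box[1, 1:2] / 2 else c(0, 0)
  }
  lz <- if (!is.null(traj$box)) traj$box[, 3] else rep(NA_real_, nf)
  out <- list()
  for (j in seq_along(ion_sel)) {
    i <- ion_sel[j]
    z <- traj$xyz[, i, 3]
    r <- sqrt((traj$xyz[, i, 1] - axis_xy[1])^2 +
              (traj$xyz[, i, 2] - axis_xy[2])^2)
    dz <- diff(z)
    if (is.null(traj$box)) {
      span <- diff(range(z))
      if (any(abs(dz) > pmax(span / 2, z_upper - z_lower)))
        stop("per-frame z jumps look periodic-wrapped but the trajectory ",
             "has no box information")
      dzu <- dz
    } else {
      dzu <- dz - lz[-1] * round(dz / lz[-1])
    }
    region <- ifelse(z <= z_lower, "below",
                     ifelse(z >= z_upper, "above", "inside"))
    origin <- if (region[1] == "inside") NA_character_ else region[1]
    entry <- if (region[1] == "inside") traj$times[1] else NA_real_
    valid <- !(region[1] == "inside" && r[1] >= radius)
    for (f in 2:nf) {
      if (region[f] == "inside") {
        if (is.na(entry)) entry <- traj$times[f]
        if (r[f] >= radius) valid <- FALSE
      } else {
        crossed <- FALSE
        if (!is.na(origin) && origin != region[f] && valid) {
          if (region[f - 1] == "inside") crossed <- TRUE
          else crossed <- (region[f] == "above" && dzu[f - 1] > 0) ||
              (region[f] == "below" && dzu[f - 1] < 0)
        }
        if (crossed) {
          el <- traj$topology$atoms$element[i]
          q <- charges[element_key(el)]
          out[[length(out) + 1L]] <- data.frame(
            ion = j, species = el,
            charge = if (is.na(q)) NA_real_ else unname(q),
            entry_time = if (is.na(entry)) traj$times[f - 1] else entry,
            exit_time = traj$times[f],
            direction = if (region[f] == "above") "+z" else "-z",
            stringsAsFactors = FALSE)
        }
        origin <- region[f]
        entry <- NA_real_
        valid <- TRUE
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(ion = integer(0), species = character(0),
                      charge = numeric(0), entry_time = numeric(0),
                      exit_time = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  ev[order(ev$exit_time, ev$ion), , drop = FALSE]
}

#' Current from crossing events
#'
#' I = dq / dt: dq is the signed transferred charge (sum over events of
#' charge x direction sign x elementary charge), dt the full analysed
#' duration.
#'
#' @param events data.frame from [detect_crossings()] (columns `charge`,
#'   `direction`).
#' @param duration analysed duration, ps.
#' @return list with `I` (A), `dq` (C), `dt` (s), and event counts by
#'   direction.
#' @export
compute_current <- function(events, duration) {
  if (duration <= 0) stop("duration must be positive")
  sgn <- ifelse(events$direction == "+z", 1, -1)
  dq <- sum(events$charge * sgn) * ELEMENTARY_CHARGE
  dt <- duration * 1e-12
  list(I = dq / dt, dq = dq, dt = dt,
       n_up = sum(events$direction == "+z"),
       n_down = sum(events$direction == "-z"))
}

#' Conductance from current and transmembrane potential
#'
#' C = I / U.
#'
#' @param I current, A.
#' @param U transmembrane potential, V (nonzero).
#' @return conductance, S.
#' @export
compute_conductance <- function(I, U) {
  if (U == 0) stop("U must be nonzero")
  I / U
}

#' Full permeation bookkeeping
#'
#' Combines [compute_current()] and [compute_conductance()] into a
#' `ConductanceResult`.
#'
#' @param events crossing events.
#' @param duration analysed duration, ps.
#' @param U transmembrane potential, V.
#' @return list with `dq` (C), `dt` (s), `I` (A), `U` (V), `C` (S) and the
#'   event counts.
#' @export
conductance_result <- function(events, duration, U = 0.3) {
  cur <- compute_current(events, duration)
  res <- c(cur[c("dq", "dt", "I")], list(U = U,
           C = compute_conductance(cur$I, U),
           n_up = cur$n_up, n_down = cur$n_down))
  class(res) <- "ConductanceResult"
  res
}

#' @export
print.ConductanceResult <- function(x, ...) {
  cat(sprintf("ConductanceResult: I = %.3g pA at U = %g mV -> C = %.3g pS (%d up, %d down)\n",
              x$I * 1e12, x$U * 1e3, x$C * 1e12, x$n_up, x$n_down))
  invisible(x)
}
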