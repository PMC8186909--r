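# Synthetic systems with known ground truth: every analysis stage of the
# package can be exercised against these generators without any MD data.

BOLTZMANN_PN_NM <- 0.0138064852  # pN nm / K

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# ---- bead-spring supercoil --------------------------------------------------

#' Bead-spring model of a supercoiled ankyrin-repeat bundle
#'
#' Parameterises a reduced model of the AR spring: `n_chains` helical chains
#' of `n_beads` beads each (one bead per ankyrin repeat), arranged
#' C4-symmetrically about the z axis, plus a restrained head bead (bead 0,
#' the linker-helix anchor) per chain. Consecutive beads are joined by
#' springs that are harmonic in the displacement of the bond vector from
#' its relaxed reference (elastic-network form), with per-bond stiffness
#' `n_beads * k_chain`; series composition then makes the end-to-end
#' stiffness of each chain exactly `k_chain` in every direction, at any
#' temperature. The trade-off of the fully harmonic network is that its
#' force response is achiral: the supercoil twist shapes the geometry, not
#' the force field, so emergent torque under axial load is outside this
#' toy's scope.
#'
#' Defaults follow the studied system: 4 chains x 29 repeats, relaxed z-span
#' `n_beads * rise` = 15.0 nm, per-chain stiffness 3 pN/nm, a 5 pN-scale
#' force range, and a flat-bottom lateral confinement of radius 3 nm with
#' stiffness 166 pN/nm (100 kJ mol^-1 nm^-2) on the force-bearing terminal
#' bead.
#'
#' @param n_chains number of chains (default 4).
#' @param n_beads beads per chain excluding the head (default 29).
#' @param helix_radius helix radius, nm.
#' @param rise rise per bead, nm (default 15/29 so the relaxed span is 15 nm).
#' @param twist_per_bead helix twist per bead, degrees (sign = chirality).
#' @param k_chain end-to-end stiffness per chain, pN/nm.
#' @param k_head head (bead 0) restraint stiffness, pN/nm.
#' @param flat_radius,flat_k flat-bottom lateral confinement of the terminal
#'   bead: radius nm, stiffness pN/nm.
#' @param gamma friction coefficient, pN ps/nm, of the overdamped dynamics.
#' @return object of class `SpringModel`.
#' @export
spring_model <- function(n_chains = 4L, n_beads = 29L, helix_radius = 1.5,
                         rise = 15 / 29, twist_per_bead = 4,
                         k_chain = 3.0, k_head = 100,
                         flat_radius = 3.0, flat_k = 166.054, gamma = 1.0) {
  if (n_chains < 1 || n_beads < 1) stop("n_chains and n_beads must be >= 1")
  if (helix_radius <= 0 || rise <= 0) stop("helix dimensions must be positive")
  if (k_chain <= 0) stop("k_chain must be positive")
  obj <- list(n_chains = as.integer(n_chains), n_beads = as.integer(n_beads),
              helix_radius = helix_radius, rise = rise,
              twist_per_bead = twist_per_bead, k_chain = k_chain,
              k_head = k_head, flat_radius = flat_radius, flat_k = flat_k,
              gamma = gamma)
  class(obj) <- "SpringModel"
  obj
}

spring_bead_coords_nm <- function(model) {
  # rows: chain-major, bead 0..n_beads per chain; nm
  nc <- model$n_chains; nb <- model$n_beads
  out <- matrix(NA_real_, nrow = nc * (nb + 1L), ncol = 3L)
  for (c in seq_len(nc)) {
    phase <- 2 * pi * (c - 1) / nc
    b <- 0:nb
    ang <- phase + (model$twist_per_bead * pi / 180) * b
    rows <- (c - 1L) * (nb + 1L) + b + 1L
    out[rows, 1] <- model$helix_radius * cos(ang)
    out[rows, 2] <- model$helix_radius * sin(ang)
    out[rows, 3] <- b * model$rise
  }
  out
}

#' Generate the relaxed helical bead-spring structure
#'
#' Deterministic: chains are labelled A, B, C, ... with bead index as residue
#' number (bead 0 = restrained head). Coordinates are emitted in Angstrom
#' (the `Structure` convention); the relaxed z-span of each chain is
#' `n_beads * rise`.
#'
#' @param model a [spring_model()].
#' @return a `Structure` with one CA pseudo-atom per bead.
#' @export
make_helical_spring <- function(model) {
  stopifnot(inherits(model, "SpringModel"))
  nm <- spring_bead_coords_nm(model)
  nc <- model$n_chains; nb <- model$n_beads
  atoms <- data.frame(
    serial = seq_len(nrow(nm)),
    name = "CA",
    resname = "BEA",
    chain = rep(LETTERS[seq_len(nc)], each = nb + 1L),
    resno = rep(0:nb, times = nc),
    insert = "",
    occupancy = 1,
    element = "C",
    stringsAsFactors = FALSE)
  structure_new(atoms, nm * 10)
}

spring_topology <- function(model) {
  # bonds (0-based) with their relaxed reference vectors; series composition
  # of n_beads bonds of stiffness n_beads * k_chain gives exactly k_chain
  nc <- model$n_chains; nb <- model$n_beads
  ref <- spring_bead_coords_nm(model)
  bonds <- NULL
  for (c in seq_len(nc)) {
    off <- (c - 1L) * (nb + 1L)
    bonds <- rbind(bonds, cbind(off + 0:(nb - 1L), off + 1:nb))
  }
  d0 <- ref[bonds[, 2] + 1L, , drop = FALSE] - ref[bonds[, 1] + 1L, , drop = FALSE]
  list(bonds = bonds, k_bond = rep(nb * model$k_chain, nrow(bonds)),
       d0 = d0,
       head_idx = (seq_len(nc) - 1L) * (nb + 1L),
       tail_idx = (seq_len(nc) - 1L) * (nb + 1L) + nb)
}

#' Overdamped Brownian dynamics of the bead-spring model
#'
#' First-order (overdamped Langevin) integration of the bead-spring
#' network: elastic-network bonds, harmonic head restraints whose per-step
#' reaction forces are recorded, a flat-bottom lateral confinement on the
#' terminal beads, and a constant external force applied to the terminal
#' bead of each chain along z. Identical arguments and seed give identical
#' output. Aborts with a diagnostic if any bond extends beyond 10x its
#' reference length.
#'
#' @param model a [spring_model()].
#' @param force_per_chain signed force, pN, applied along z to the terminal
#'   bead of each chain (negative = pushing toward the head, i.e.
#'   compression).
#' @param n_steps number of integration steps.
#' @param dt time step, ps.
#' @param temperature Kelvin; 0 switches the noise off.
#' @param seed integer RNG seed.
#' @param start optional starting `Structure` (default: the relaxed helix).
#' @param save_every record every this-many steps.
#' @return a `ToyRunResult`: list with `trajectory` (a `Trajectory`,
#'   Angstrom/ps), `force_trace` (a [force_trace()] of head-restraint
#'   reaction forces, pN, application points at the head anchors), `model`,
#'   `force_per_chain` and `seed`.
#' @export
simulate_overdamped <- function(model, force_per_chain = 0, n_steps = 10000L,
                                dt = 0.004, temperature = 300, seed = 1L,
                                start = NULL, save_every = 50L) {
  stopifnot(inherits(model, "SpringModel"))
  if (dt <= 0 || n_steps <= 0) stop("dt and n_steps must be positive")
  topo <- spring_topology(model)
  ref_nm <- spring_bead_coords_nm(model)
  x0 <- if (is.null(start)) ref_nm else start$xyz / 10
  n <- nrow(x0)
  ext <- matrix(0, n, 3)
  ext[topo$tail_idx + 1L, 3] <- force_per_chain
  kBT <- BOLTZMANN_PN_NM * temperature
  res <- with_seed(seed, bd_integrate(
    x0, topo$bonds, topo$k_bond, topo$d0,
    topo$head_idx, ref_nm[topo$head_idx + 1L, , drop = FALSE], model$k_head,
    topo$tail_idx, model$flat_radius, model$flat_k,
    ext, model$gamma, dt, as.integer(n_steps), as.integer(save_every), kBT))
  topology <- make_helical_spring(model)
  traj <- trajectory_new(res$xyz * 10, res$times, topology = topology)
  trace <- force_trace(res$times, res$reaction,
                       points = ref_nm[topo$head_idx + 1L, , drop = FALSE] * 10,
                       meta = list(source = "simulate_overdamped",
                                   restrained = "head beads",
                                   force_per_chain = force_per_chain,
                                   seed = seed))
  out <- list(trajectory = traj, force_trace = trace, model = model,
              force_per_chain = force_per_chain, seed = seed)
  class(out) <- "ToyRunResult"
  out
}

#' Chain z-span series of a bead-spring run, nm
#'
#' The "length of the AR region" observable: per-frame difference between the
#' mean z of the terminal beads and the mean z of the head beads, in nm.
#'
#' @param run a `ToyRunResult` (or a `Trajectory` whose topology is a
#'   bead-spring structure plus `model`).
#' @param model the [spring_model()] (taken from `run` when omitted).
#' @return numeric vector, one value per frame, nm.
#' @export
spring_length_series <- function(run, model = NULL) {
  if (inherits(run, "ToyRunResult")) {
    model <- run$model
    traj <- run$trajectory
  } else traj <- run
  topo <- spring_topology(model)
  hz <- topo$head_idx + 1L
  tz <- topo$tail_idx + 1L
  (rowMeans(traj$xyz[, tz, 3, drop = FALSE]) -
     rowMeans(traj$xyz[, hz, 3, drop = FALSE])) / 10
}

# ---- cylindrical pore fixture -----------------------------------------------

#' Construct a pore of known radius profile
#'
#' Builds rings of carbon pseudo-atoms whose inner accessible radius at each
#' z equals `radius_profile(z)` by construction: ring radius =
#' `radius_profile(z) + atom_vdw`.
#'
#' @param radius_profile function z (Angstrom) -> accessible radius
#'   (Angstrom, >= 0).
#' @param atom_vdw van der Waals radius assigned to the ring atoms, Angstrom.
#' @param axial_extent length-2 vector `c(z_min, z_max)`, Angstrom.
#' @param ring_density atoms per ring.
#' @param z_spacing ring spacing, Angstrom.
#' @return a `Structure` (chain "P", one residue per ring).
#' @export
make_pore_cylinder <- function(radius_profile, atom_vdw = 1.70,
                               axial_extent = c(-15, 15), ring_density = 24L,
                               z_spacing = 1.0) {
  zs <- seq(axial_extent[1], axial_extent[2], by = z_spacing)
  coords <- NULL
  resno <- integer(0)
  name <- character(0)
  for (k in seq_along(zs)) {
    r_acc <- radius_profile(zs[k])
    if (r_acc < 0) stop("radius_profile must be >= 0")
    ring_r <- r_acc + atom_vdw
    ang <- 2 * pi * (seq_len(ring_density) - 1) / ring_density +
      (k %% 2) * pi / ring_density  # stagger alternate rings
    coords <- rbind(coords, cbind(ring_r * cos(ang), ring_r * sin(ang), zs[k]))
    resno <- c(resno, rep(k, ring_density))
    name <- c(name, sprintf("C%d", seq_len(ring_density)))
  }
  atoms <- data.frame(serial = seq_len(nrow(coords)), name = name,
                      resname = "CYL", chain = "P", resno = resno,
                      insert = "", occupancy = 1, element = "C",
                      stringsAsFactors = FALSE)
  structure_new(atoms, coords)
}

# ---- drifting ions ----------------------------------------------------------

#' Drifting-ion trajectory with a ground-truth crossing log
#'
#' Potassium-like ions performing drift-diffusion along z inside a periodic
#' box, with lateral diffusion. Coordinates are stored wrapped into the box;
#' the returned ground-truth crossing log is computed during generation from
#' the unwrapped path, with the same event definition the detector uses
#' (complete two-plane traversal with the radial excursion inside the
#' cylinder radius for all in-slab frames).
#'
#' @param n_ions number of ions.
#' @param drift drift velocity along z, nm/ns (signed).
#' @param diffusion diffusion coefficient, nm^2/ns.
#' @param box length-3 box edge lengths, Angstrom (z-periodic).
#' @param cylinder list with `z_lower`, `z_upper`, `radius` (Angstrom).
#' @param n_frames,dt frames and frame spacing (ps).
#' @param seed RNG seed.
#' @return list with `trajectory` (a `Trajectory` with box and ion topology)
#'   and `events` (data.frame: ion, entry_time, exit_time, direction).
#' @export
make_ion_drift_trajectory <- function(n_ions = 20L, drift = 0,
                                      diffusion = 0.5,
                                      box = c(40, 40, 80),
                                      cylinder = list(z_lower = 25,
                                                      z_upper = 55,
                                                      radius = 15),
                                      n_frames = 200L, dt = 10, seed = 1L) {
  dt_ns <- dt * 1e-3
  step_sd <- sqrt(2 * diffusion * dt_ns) * 10   # Angstrom
  drift_A <- drift * dt_ns * 10                 # Angstrom per frame
  with_seed(seed, {
    cx <- box[1] / 2; cy <- box[2] / 2
    times <- seq_len(n_frames) * dt
    # generate paths; the box is periodic along z only (xy stays unwrapped)
    x <- matrix(runif(n_ions, cx - 5, cx + 5), n_frames, n_ions,
                byrow = TRUE) +
      apply(matrix(rnorm(n_frames * n_ions, 0, step_sd), n_frames), 2, cumsum)
    y <- matrix(runif(n_ions, cy - 5, cy + 5), n_frames, n_ions,
                byrow = TRUE) +
      apply(matrix(rnorm(n_frames * n_ions, 0, step_sd), n_frames), 2, cumsum)
    zu <- matrix(runif(n_ions, 0, box[3]), n_frames, n_ions, byrow = TRUE) +
      apply(matrix(drift_A + rnorm(n_frames * n_ions, 0, step_sd),
                   n_frames), 2, cumsum)
    xyz <- array(NA_real_, dim = c(n_frames, n_ions, 3L))
    xyz[, , 1] <- x
    xyz[, , 2] <- y
    xyz[, , 3] <- zu %% box[3]
    # ground-truth crossing log from the generated (unwrapped-z) paths
    region_of <- function(zw)
      ifelse(zw <= cylinder$z_lower, "below",
             ifelse(zw >= cylinder$z_upper, "above", "inside"))
    ev_ion <- integer(0); ev_entry <- numeric(0); ev_exit <- numeric(0)
    ev_dir <- character(0)
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    zw <- zu %% box[3]
    for (i in seq_len(n_ions)) {
      reg <- region_of(zw[, i])
      origin <- if (reg[1] == "inside") NA_character_ else reg[1]
      entry <- if (reg[1] == "inside") times[1] else NA_real_
      valid <- !(reg[1] == "inside" && r[1, i] >= cylinder$radius)
      for (f in 2:n_frames) {
        if (reg[f] == "inside") {
          if (is.na(entry)) entry <- times[f]
          if (r[f, i] >= cylinder$radius) valid <- FALSE
        } else {
          crossed <- FALSE
          if (!is.na(origin) && origin != reg[f] && valid) {
            if (reg[f - 1] == "inside") crossed <- TRUE
            else {
              # slab skipped in one step: through the slab only if the
              # unwrapped displacement points through it (not a periodic
              # boundary jump)
              dzu <- zu[f, i] - zu[f - 1, i]
              crossed <- (reg[f] == "above" && dzu > 0) ||
                (reg[f] == "below" && dzu < 0)
            }
          }
          if (crossed) {
            ev_ion <- c(ev_ion, i)
            ev_entry <- c(ev_entry, if (is.na(entry)) times[f - 1] else entry)
            ev_exit <- c(ev_exit, times[f])
            ev_dir <- c(ev_dir, if (reg[f] == "above") "+z" else "-z")
          }
          if (reg[f] != "inside") {
            origin <- reg[f]
            entry <- NA_real_
            valid <- TRUE
          }
        }
      }
    }
    atoms <- data.frame(serial = seq_len(n_ions), name = "K",
                        resname = "K", chain = "I", resno = seq_len(n_ions),
                        insert = "", occupancy = 1, element = "K",
                        stringsAsFactors = FALSE)
    topo <- structure_new(atoms, matrix(xyz[1, , ], ncol = 3))
    traj <- trajectory_new(xyz, times, topology = topo,
                           box = matrix(box, 1))
    events <- data.frame(ion = ev_ion, entry_time = ev_entry,
                         exit_time = ev_exit, direction = ev_dir,
                         stringsAsFactors = FALSE)
    list(trajectory = traj, events = events)
  })
}

# ---- rigid tilt/rotation fixture --------------------------------------------

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Rigid tilt/rotation trajectory of a domain
#'
#' Frame i is the reference structure with the selected atoms rigidly rotated
#' about their centroid so that the domain axis gains exactly
#' `tilt_series[i]` degrees of polar angle (tilt away from z) and
#' `rotation_series[i]` degrees of azimuth (positive = clockwise viewed from
#' -z, the intracellular side). All other atoms are untouched, so they can
#' serve as the immobile superposition reference.
#'
#' @param structure reference `Structure`.
#' @param selection atom indices of the mobile domain.
#' @param tilt_series,rotation_series equal-length vectors of angles, degrees.
#' @param dt frame spacing, ps.
#' @return a `Trajectory`.
#' @export
make_rigid_rotation_trajectory <- function(structure, selection, tilt_series,
                                           rotation_series, dt = 10) {
  stopifnot(length(tilt_series) == length(rotation_series))
  a0 <- domain_axis(structure$xyz[selection, , drop = FALSE])
  th0 <- acos(pmin(pmax(a0[3], -1), 1))
  ph0 <- atan2(a0[2], a0[1])
  cen <- colMeans(structure$xyz[selection, , drop = FALSE])
  nf <- length(tilt_series)
  xyz <- array(rep(structure$xyz, each = nf),
               dim = c(nf, nrow(structure$xyz), 3L))
  for (f in seq_len(nf)) {
    tau <- tilt_series[f] * pi / 180
    rho <- rotation_series[f] * pi / 180
    R <- rot_z(ph0 + rho) %*% rot_y(th0 + tau) %*% t(rot_y(th0)) %*%
      t(rot_z(ph0))
    moved <- sweep(structure$xyz[selection, , drop = FALSE], 2, cen) %*% t(R)
    xyz[f, selection, ] <- sweep(moved, 2, cen, "+")
  }
  trajectory_new(xyz, seq_len(nf) * dt, topology = structure)
}

# ---- distance trace with jump -----------------------------------------------

#' Distance trace with an optional injected sharp jump
#'
#' Gaussian noise about a constant baseline; if `jump_at_frame` is given,
#' all frames strictly after it are shifted by `jump_amplitude`.
#'
#' @param n_frames series length.
#' @param baseline baseline value (nm).
#' @param noise_sd Gaussian noise SD.
#' @param jump_at_frame last unshifted frame index, or `NULL` for no jump.
#' @param jump_amplitude step height.
#' @param seed RNG seed.
#' @return numeric vector of length `n_frames`.
#' @export
make_distance_trace_with_jump <- function(n_frames, baseline = 10,
                                          noise_sd = 0.1,
                                          jump_at_frame = NULL,
                                          jump_amplitude = 0, seed = 1L) {
  with_seed(seed, {
    x <- baseline + rnorm(n_frames, 0, noise_sd)
    if (!is.null(jump_at_frame) && jump_at_frame < n_frames)
      x[(jump_at_frame + 1L):n_frames] <- x[(jump_at_frame + 1L):n_frames] +
        jump_amplitude
    x
  })
}

# ---- delayed-response force traces ------------------------------------------

#' Paired force traces with an imposed response delay
#'
#' Emulates the force-transfer experiment: a free trace (noise about zero)
#' and a perturbed trace identical in distribution until `delay` ps, after
#' which a step of `amplitude` pN is added. The imposed delay is the ground
#' truth for onset detection; an imposed transfer speed v over a region of
#' length L corresponds to `delay = L / v`.
#'
#' @param n_samples samples per trace.
#' @param dt sampling interval, ps (default 0.01 ps = 10 fs).
#' @param delay imposed response delay, ps.
#' @param amplitude response step, pN.
#' @param noise_sd Gaussian noise SD, pN.
#' @param seed RNG seed.
#' @return list with `times`, `free`, `perturbed`, `delay`.
#' @export
make_delayed_force_traces <- function(n_samples = 2000L, dt = 0.01,
                                      delay = 8.0, amplitude = 5,
                                      noise_sd = 0.25, seed = 1L) {
  with_seed(seed, {
    times <- seq_len(n_samples) * dt
    free <- rnorm(n_samples, 0, noise_sd)
    pert <- rnorm(n_samples, 0, noise_sd)
    pert[times >= delay] <- pert[times >= delay] + amplitude
    list(times = times, free = free, perturbed = pert, delay = delay)
  })
}

# ---- hydrogen-bond toy ------------------------------------------------------

#' Donor-H-acceptor toy geometry
#'
#' One nitrogen donor with an attached hydrogen and one oxygen acceptor,
#' placed so the donor-acceptor heavy-atom distance is exactly `d_DA` and the
#' donor-hydrogen-acceptor angle exactly `angle_DHA` (N-H bond length 1.0
#' Angstrom).
#'
#' @param d_DA donor-acceptor distance, Angstrom.
#' @param angle_DHA donor-hydrogen-acceptor angle, degrees.
#' @return a `Structure` with residues DON (N, H) and ACC (O).
#' @export
make_hbond_toy <- function(d_DA = 2.9, angle_DHA = 170) {
  a <- angle_DHA * pi / 180
  disc <- cos(a)^2 - 1 + d_DA^2
  if (disc < 0) stop("no geometry with this distance/angle combination")
  x_HA <- cos(a) + sqrt(disc)
  if (x_HA <= 0) stop("no geometry with this distance/angle combination")
  D <- c(0, 0, 0)
  H <- c(1, 0, 0)
  A <- H + x_HA * c(cos(pi - a), sin(pi - a), 0)
  atoms <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                      resname = c("DON", "DON", "ACC"), chain = "A",
                      resno = c(1L, 1L, 2L), insert = "", occupancy = 1,
                      element = c("N", "H", "O"), stringsAsFactors = FALSE)
  structure_new(atoms, rbind(D, H, A))
}
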