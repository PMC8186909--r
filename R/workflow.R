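# Programmatic stage dispatcher: every analysis stage and generator behind
# one entry point with validated configuration, reproducible seeds and a
# machine-readable provenance record per run.

stage_params <- list(
  simulate = c("force_per_chain", "n_steps", "dt", "temperature",
               "save_every", "model"),
  pore = c("structure", "map", "selection", "z_range", "z_step",
           "backbone_only"),
  pca = c("trajectory", "topology", "map", "selection", "n_components"),
  angles = c("trajectory", "topology", "map", "selection", "fit_selection"),
  spring = c("free_lengths", "forced_lengths", "force"),
  torque = c("forces", "points", "symmetrize"),
  transfer = c("traces", "length_nm", "baseline_window", "threshold_sd",
               "min_persist", "dt"),
  permeation = c("trajectory", "topology", "z_lower", "z_upper", "radius",
                 "potential"),
  hbonds = c("structure", "pairs", "max_distance", "min_angle"))

validate_config <- function(stage, config) {
  allowed <- c(stage_params[[stage]], "output_dir", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s) for stage '", stage, "': ",
         paste(unknown, collapse = ", "))
  if (is.null(config$output_dir)) stop("config requires output_dir")
  config$seed <- config$seed %||% 1L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_provenance <- function(stage, config, outputs, dir) {
  rec <- list(stage = stage,
              package = "mechanotraj",
              version = as.character(utils::packageVersion("mechanotraj")),
              seed = config$seed,
              parameters = config[setdiff(names(config),
                                          c("output_dir", "seed"))],
              outputs = outputs)
  jsonlite::write_json(rec, file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  path
}

#' Run one analysis stage from a configuration
#'
#' Dispatches to the package's generators and analyses:
#' `simulate`, `pore`, `pca`, `angles`, `spring`, `torque`, `transfer`,
#' `permeation`, `hbonds`. The configuration (an R list, or a YAML file
#' path) is validated against the stage's known keys - unknown keys are
#' rejected - and each run writes its outputs plus a provenance record
#' (stage, parameters, package version, seed) into `output_dir`. On error,
#' files created by the failed run are removed. Output columns carry
#' explicit units in their headers.
#'
#' @param stage stage name.
#' @param config named list or YAML path; always contains `output_dir`,
#'   optionally `seed` (default 1), plus stage parameters.
#' @return named list of output file paths, invisibly.
#' @export
run_stage <- function(stage, config) {
  if (!stage %in% names(stage_params))
    stop("unknown stage '", stage, "'; stages: ",
         paste(names(stage_params), collapse = ", "))
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- validate_config(stage, config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- list.files(config$output_dir, full.names = TRUE)
  outputs <- tryCatch(
    do.call(paste0("stage_", stage), list(config)),
    error = function(e) {
      created <- setdiff(list.files(config$output_dir, full.names = TRUE), pre)
      unlink(created)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  write_provenance(stage, config, outputs, config$output_dir)
  invisible(outputs)
}

out_path <- function(config, name) file.path(config$output_dir, name)

stage_simulate <- function(config) {
  model <- do.call(spring_model, config$model %||% list())
  run <- simulate_overdamped(model,
                             force_per_chain = config$force_per_chain %||% 0,
                             n_steps = config$n_steps %||% 10000L,
                             dt = config$dt %||% 0.004,
                             temperature = config$temperature %||% 300,
                             seed = config$seed,
                             save_every = config$save_every %||% 50L)
  traj_path <- out_path(config, "trajectory.tsv")
  write_frame_store(run$trajectory, traj_path)
  pdb_path <- out_path(config, "structure.pdb")
  write_structure(make_helical_spring(model), pdb_path)
  ft <- run$force_trace
  nc <- dim(ft$forces)[2]
  tab <- data.frame(time_ps = ft$times)
  for (c in seq_len(nc))
    for (d in 1:3)
      tab[[paste0("chain", c, "_f", c("x", "y", "z")[d], "_pN")]] <-
        ft$forces[, c, d]
  forces_path <- write_tsv(tab, out_path(config, "reaction_forces.tsv"))
  list(trajectory = traj_path, structure = pdb_path, forces = forces_path)
}

stage_pore <- function(config) {
  x <- read_structure(config$structure)
  sel <- if (!is.null(config$map)) {
    map <- read_domain_map(config$map)
    select_domain(x, map, config$selection)
  } else NULL
  prof <- pore_profile(x, sel = sel,
                       z_range = config$z_range,
                       z_step = config$z_step %||% 0.5,
                       backbone_only = isTRUE(config$backbone_only))
  tab <- data.frame(z_A = prof$z, radius_A = prof$radius, cx_A = prof$cx,
                    cy_A = prof$cy, status = prof$status)
  list(profile = write_tsv(tab, out_path(config, "pore_profile.tsv")))
}

load_stage_trajectory <- function(config) {
  topo <- if (!is.null(config$topology)) read_structure(config$topology)
  read_frame_store(config$trajectory, topology = topo)
}

stage_pca <- function(config) {
  traj <- load_stage_trajectory(config)
  sel <- if (!is.null(config$map))
    select_domain(traj$topology, read_domain_map(config$map),
                  config$selection)
  model <- fit_pca(traj, sel = sel)
  k <- min(config$n_components %||% 5L, length(model$values))
  proj <- data.frame(time_ps = traj$times)
  for (j in seq_len(k))
    proj[[paste0("pc", j, "_A")]] <- model$projections[, j]
  evs <- data.frame(component = seq_along(model$values),
                    variance_A2 = model$values)
  list(projections = write_tsv(proj, out_path(config, "pca_projections.tsv")),
       eigenvalues = write_tsv(evs, out_path(config, "pca_eigenvalues.tsv")))
}

stage_angles <- function(config) {
  traj <- load_stage_trajectory(config)
  map <- read_domain_map(config$map)
  sel <- select_domain(traj$topology, map, config$selection)
  fit_sel <- if (!is.null(config$fit_selection))
    select_domain(traj$topology, map, config$fit_selection)
  ang <- tilt_rotation_series(traj, sel, fit_sel = fit_sel)
  tab <- data.frame(time_ps = ang$time, tilt_deg = ang$tilt,
                    rotation_deg = ang$rotation)
  list(angles = write_tsv(tab, out_path(config, "angles.tsv")))
}

read_series <- function(path) as.matrix(data.table::fread(path))[, 1]

stage_spring <- function(config) {
  fit <- spring_constant(read_series(config$free_lengths),
                         read_series(config$forced_lengths),
                         config$force)
  p <- out_path(config, "spring.json")
  jsonlite::write_json(unclass(fit), p, auto_unbox = TRUE, digits = NA)
  list(spring = p)
}

stage_torque <- function(config) {
  trace <- read_force_trace(config$forces,
                            points = as.matrix(
                              data.table::fread(config$points)))
  ts <- planar_torque(trace, symmetrize = !isFALSE(config$symmetrize))
  p <- out_path(config, "torque.json")
  jsonlite::write_json(list(torque_z_pN_nm = ts$torque_z,
                            net_planar_force_pN = ts$net_planar_force,
                            symmetrized = ts$symmetrized),
                       p, auto_unbox = TRUE, digits = NA)
  list(torque = p)
}

stage_transfer <- function(config) {
  dat <- data.table::fread(config$traces)
  onset <- arrival_onset(dat[[2]], dat[[3]], times = dat[[1]],
                         baseline_window = config$baseline_window %||% 2,
                         threshold_sd = config$threshold_sd %||% 3,
                         min_persist = config$min_persist %||% 5L)
  est <- transfer_speed(onset, config$length_nm)
  p <- out_path(config, "transfer.json")
  jsonlite::write_json(list(onset_ps = est$onsets, L_nm = est$L,
                            v_nm_per_ps = est$v), p, auto_unbox = TRUE,
                       digits = NA)
  list(transfer = p)
}

stage_permeation <- function(config) {
  traj <- load_stage_trajectory(config)
  ev <- detect_crossings(traj, seq_len(dim(traj$xyz)[2]),
                         z_lower = config$z_lower, z_upper = config$z_upper,
                         radius = config$radius)
  res <- conductance_result(ev, duration = diff(range(traj$times)),
                            U = config$potential %||% 0.3)
  ev_path <- write_tsv(ev, out_path(config, "crossings.tsv"))
  p <- out_path(config, "permeation.json")
  jsonlite::write_json(list(n_events = nrow(ev), dq_C = res$dq,
                            dt_s = res$dt, I_A = res$I, U_V = res$U,
                            C_S = res$C), p, auto_unbox = TRUE, digits = NA)
  list(events = ev_path, summary = p)
}

stage_hbonds <- function(config) {
  x <- read_structure(config$structure)
  pairs <- lapply(config$pairs, function(p)
    list(resA = list(chain = p$chainA, resno = p$resnoA),
         resB = list(chain = p$chainB, resno = p$resnoB)))
  crit <- hbond_criterion(max_distance = config$max_distance %||% 3.5,
                          min_angle = config$min_angle %||% 120)
  rep <- interface_pairs_report(x, pairs, criterion = crit)
  list(report = write_tsv(rep, out_path(config, "hbond_report.tsv")))
}
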