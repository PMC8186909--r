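# Geometric hydrogen-bond detection, per-pair occupancy over trajectories,
# and stable-bond classification.

#' Geometric hydrogen-bond criterion
#'
#' Default: donor-acceptor heavy-atom distance <= 3.5 Angstrom and
#' donor-hydrogen-acceptor angle >= 120 degrees (the common geometric
#' standard); both boundaries inclusive. For structures without hydrogens
#' (e.g. cryo-EM models) the angle condition is dropped, either explicitly
#' via `heavy_only` or automatically per donor without attached hydrogens.
#'
#' @param max_distance maximum donor-acceptor distance, Angstrom (> 0).
#' @param min_angle minimum D-H-A angle, degrees, in (0, 180].
#' @param heavy_only drop the angle condition entirely.
#' @return object of class `HBondCriterion`.
#' @export
hbond_criterion <- function(max_distance = 3.5, min_angle = 120,
                            heavy_only = FALSE) {
  if (max_distance <= 0) stop("max_distance must be positive")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  obj <- list(max_distance = max_distance, min_angle = min_angle,
              heavy_only = heavy_only)
  class(obj) <- "HBondCriterion"
  obj
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert)

#' Donor and acceptor candidates of a structure
#'
#' Donors: N/O atoms; an attached hydrogen is any H of the same residue
#' within `h_cutoff` of the heavy atom. Acceptors: N/O atoms.
#'
#' @param x a `Structure`.
#' @param sel atom indices to consider (default all).
#' @param h_cutoff covalent D-H distance cutoff, Angstrom.
#' @return list with `donors` (data.frame: index, hydrogens list-column) and
#'   `acceptors` (index vector).
#' @export
find_hbond_candidates <- function(x, sel = NULL, h_cutoff = 1.25) {
  if (is.null(sel)) sel <- seq_len(n_atoms(x))
  el <- x$atoms$element[sel]
  heavy <- sel[el %in% c("N", "O")]
  hyd <- sel[el == "H"]
  rkey <- residue_key(x$atoms)
  hyd_by_res <- split(hyd, rkey[hyd])
  dons <- lapply(heavy, function(i) {
    hs <- hyd_by_res[[rkey[i]]]
    if (is.null(hs)) return(integer(0))
    d <- sqrt(rowSums((x$xyz[hs, , drop = FALSE] -
                         matrix(x$xyz[i, ], length(hs), 3, byrow = TRUE))^2))
    hs[d <= h_cutoff]
  })
  donors <- data.frame(index = heavy)
  donors$hydrogens <- dons
  # when the structure carries hydrogens, only H-bearing heavy atoms donate;
  # hydrogen-free structures (cryo-EM) keep all N/O as potential donors and
  # the angle condition is dropped per donor
  if (length(hyd) > 0L)
    donors <- donors[vapply(dons, length, integer(1)) > 0L, , drop = FALSE]
  list(donors = donors, acceptors = heavy)
}

dha_angle <- function(xyz, d, h, a) {
  u <- xyz[d, ] - xyz[h, ]
  v <- xyz[a, ] - xyz[h, ]
  c0 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(c0, -1), 1)) * 180 / pi
}

hbond_pair_ok <- function(x, d_idx, d_hyds, a_idx, criterion) {
  eps <- 1e-9  # boundaries are inclusive, within numerical tolerance
  dist <- sqrt(sum((x$xyz[d_idx, ] - x$xyz[a_idx, ])^2))
  if (dist > criterion$max_distance + eps) return(list(ok = FALSE))
  if (criterion$heavy_only || length(d_hyds) == 0L)
    return(list(ok = TRUE, dist = dist, angle = NA_real_))
  angs <- vapply(d_hyds, function(h) dha_angle(x$xyz, d_idx, h, a_idx),
                 numeric(1))
  if (max(angs) >= criterion$min_angle - eps)
    list(ok = TRUE, dist = dist, angle = max(angs))
  else list(ok = FALSE)
}

#' Hydrogen bonds of one frame
#'
#' Reports every donor/acceptor pair (different residues) satisfying the
#' criterion: distance condition always; angle condition when the donor has
#' attached hydrogens and the criterion is not heavy-only.
#'
#' @param x a `Structure`.
#' @param donors,acceptors candidates as produced by
#'   [find_hbond_candidates()] (defaults: all N/O of the structure).
#' @param criterion an [hbond_criterion()].
#' @return data.frame: donor/acceptor indices, chains, residues, atom
#'   names, `dist`, `angle`, and backbone flags (backbone = atom named
#'   N/CA/C/O/OXT or an H bound to backbone N).
#' @export
detect_hbonds_frame <- function(x, donors = NULL, acceptors = NULL,
                                criterion = hbond_criterion()) {
  if (is.null(donors) || is.null(acceptors)) {
    cand <- find_hbond_candidates(x)
    if (is.null(donors)) donors <- cand$donors
    if (is.null(acceptors)) acceptors <- cand$acceptors
  }
  rkey <- residue_key(x$atoms)
  rows <- list()
  bb_names <- c(BACKBONE_NAMES, "OXT")
  for (k in seq_len(nrow(donors))) {
    d <- donors$index[k]
    hs <- donors$hydrogens[[k]]
    for (a in acceptors) {
      if (rkey[d] == rkey[a]) next
      hit <- hbond_pair_ok(x, d, hs, a, criterion)
      if (!hit$ok) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d, acceptor = a,
        donor_chain = x$atoms$chain[d], donor_resno = x$atoms$resno[d],
        donor_resname = x$atoms$resname[d], donor_atom = x$atoms$name[d],
        acceptor_chain = x$atoms$chain[a], acceptor_resno = x$atoms$resno[a],
        acceptor_resname = x$atoms$resname[a], acceptor_atom = x$atoms$name[a],
        dist = hit$dist, angle = hit$angle,
        donor_backbone = x$atoms$name[d] %in% bb_names,
        acceptor_backbone = x$atoms$name[a] %in% bb_names,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      donor_chain = character(0), donor_resno = integer(0),
                      donor_resname = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resname = character(0),
                      acceptor_atom = character(0), dist = numeric(0),
                      angle = numeric(0), donor_backbone = logical(0),
                      acceptor_backbone = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

residue_atoms <- function(x, res) {
  hit <- x$atoms$chain == res$chain & x$atoms$resno == res$resno
  if (!is.null(res$insert)) hit <- hit & x$atoms$insert == res$insert
  which(hit)
}

pair_present_frame <- function(x, atomsA, atomsB, cand, criterion) {
  # any donor/acceptor atom combination between the two residues, both ways
  don_idx <- cand$donors$index
  for (k in seq_len(nrow(cand$donors))) {
    d <- don_idx[k]
    inA <- d %in% atomsA
    inB <- d %in% atomsB
    if (!inA && !inB) next
    targets <- if (inA) intersect(cand$acceptors, atomsB)
               else intersect(cand$acceptors, atomsA)
    for (a in targets) {
      if (hbond_pair_ok(x, d, cand$donors$hydrogens[[k]], a, criterion)$ok)
        return(TRUE)
    }
  }
  FALSE
}

#' Hydrogen-bond occupancy of a residue pair over a trajectory
#'
#' Evaluates, per frame, whether any donor/acceptor atom combination between
#' the two residues satisfies the criterion (residue-level "any combination"
#' rule, both donor directions), and reports the fraction of bonded frames.
#'
#' @param traj a `Trajectory` with topology.
#' @param resA,resB residue specs: `list(chain =, resno =, insert = )`.
#' @param criterion an [hbond_criterion()].
#' @return an `HBondObservation`: list with `pair`, `present` (per-frame
#'   logical) and `occupancy` in [0, 1].
#' @export
hbond_occupancy <- function(traj, resA, resB, criterion = hbond_criterion()) {
  if (n_frames(traj) == 0L) stop("empty trajectory")
  topo <- traj$topology
  if (is.null(topo)) stop("trajectory has no topology")
  atomsA <- residue_atoms(topo, resA)
  atomsB <- residue_atoms(topo, resB)
  if (length(atomsA) == 0L || length(atomsB) == 0L)
    stop("residue not found in topology")
  cand <- find_hbond_candidates(topo, sel = c(atomsA, atomsB))
  present <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- structure_new(topo$atoms, frame_xyz(traj, i))
    pair_present_frame(fr, atomsA, atomsB, cand, criterion)
  }, logical(1))
  obj <- list(pair = list(resA = resA, resB = resB), present = present,
              occupancy = mean(present))
  class(obj) <- "HBondObservation"
  obj
}

#' Classify stable hydrogen bonds by occupancy
#'
#' @param observations list of `HBondObservation`s.
#' @param threshold stability threshold on occupancy (default 0.7).
#' @return data.frame sorted by decreasing occupancy with a `stable` flag.
#' @export
stable_bonds <- function(observations, threshold = 0.7) {
  tab <- data.frame(
    pair = vapply(observations, function(o)
      paste0(o$pair$resA$chain, o$pair$resA$resno, "-",
             o$pair$resB$chain, o$pair$resB$resno), character(1)),
    occupancy = vapply(observations, `[[`, numeric(1), "occupancy"))
  tab$stable <- tab$occupancy >= threshold
  tab[order(-tab$occupancy), , drop = FALSE]
}

#' Evaluate named residue pairs on a single structure
#'
#' Checks each residue pair for a hydrogen bond on one frame (e.g. a
#' deposited cryo-EM model). When the structure carries no hydrogens the
#' heavy-atom fallback applies automatically. The report preserves the input
#' pair order and includes the backbone/side-chain attribution of the bonded
#' atoms.
#'
#' @param x a `Structure`.
#' @param pairs list of `list(resA =, resB =)` residue specs.
#' @param criterion an [hbond_criterion()].
#' @return data.frame: pair label, `bonded`, bonded atom names (or `NA`),
#'   backbone flags.
#' @export
interface_pairs_report <- function(x, pairs,
                                   criterion = hbond_criterion()) {
  bb_names <- c(BACKBONE_NAMES, "OXT")
  rows <- lapply(pairs, function(p) {
    atomsA <- residue_atoms(x, p$resA)
    atomsB <- residue_atoms(x, p$resB)
    lab <- paste0(p$resA$chain, p$resA$resno, "-", p$resB$chain, p$resB$resno)
    if (length(atomsA) == 0L || length(atomsB) == 0L)
      stop("residue not found for pair ", lab)
    cand <- find_hbond_candidates(x, sel = c(atomsA, atomsB))
    best <- NULL
    don_idx <- cand$donors$index
    for (k in seq_len(nrow(cand$donors))) {
      d <- don_idx[k]
      inA <- d %in% atomsA
      if (!inA && !(d %in% atomsB)) next
      targets <- if (inA) intersect(cand$acceptors, atomsB)
                 else intersect(cand$acceptors, atomsA)
      for (a in targets) {
        hit <- hbond_pair_ok(x, d, cand$donors$hydrogens[[k]], a, criterion)
        if (hit$ok && (is.null(best) || hit$dist < best$dist))
          best <- list(d = d, a = a, dist = hit$dist)
      }
    }
    if (is.null(best))
      data.frame(pair = lab, bonded = FALSE, donor_atom = NA_character_,
                 acceptor_atom = NA_character_, dist = NA_real_,
                 donor_backbone = NA, acceptor_backbone = NA,
                 stringsAsFactors = FALSE)
    else
      data.frame(pair = lab, bonded = TRUE,
                 donor_atom = x$atoms$name[best$d],
                 acceptor_atom = x$atoms$name[best$a], dist = best$dist,
                 donor_backbone = x$atoms$name[best$d] %in% bb_names,
                 acceptor_backbone = x$atoms$name[best$a] %in% bb_names,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
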