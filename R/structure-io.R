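#' @useDynLib mechanotraj, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd rnorm runif setNames
#' @importFrom utils head tail
NULL

# ---- element tables ---------------------------------------------------------

#' Atomic masses and van der Waals radii
#'
#' Named vectors of atomic masses (unified atomic mass units) and Bondi-style
#' van der Waals radii (Angstrom) for the elements that occur in protein,
#' water, lipid and common ion records. The vdW table is the default used by
#' [pore_profile()] and can be overridden there.
#'
#' @return Named numeric vector keyed by upper-case element symbol.
#' @export
atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    NA. = 22.98977, K = 39.098, CL = 35.45, MG = 24.305, CA = 40.078,
    F = 18.998, BR = 79.904, I = 126.904, FE = 55.845, ZN = 65.38,
    MN = 54.938, CU = 63.546)
}

#' @rdname atomic_masses
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75,
    MG = 1.73, CA = 2.31, ZN = 1.39, FE = 2.00, MN = 2.00, CU = 1.40)
}

element_key <- function(el) {
  el <- toupper(el)
  ifelse(el == "NA", "NA.", el)
}

mass_of <- function(elements) {
  m <- atomic_masses()[element_key(elements)]
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

vdw_of <- function(elements, table = vdw_radii(), default = 1.70) {
  r <- table[element_key(elements)]
  r[is.na(r)] <- default
  unname(r)
}

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element column of a PDB record is blank. Digits and primes
#' are stripped; a leading "H" anywhere in names like "1HG1" means hydrogen;
#' two-letter ion symbols (NA, CL, MG, ...) are recognised when the full
#' stripped name matches.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name) {
  two_letter <- c("NA", "CL", "MG", "FE", "ZN", "BR", "MN", "CU")
  vapply(name, function(nm) {
    s <- gsub("[0-9']", "", toupper(nm))
    if (s == "") stop("cannot infer element from atom name '", nm, "'")
    if (s %in% two_letter) return(s)
    if (grepl("^[0-9]", nm) && substr(s, 1, 1) == "H") return("H")
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# ---- Structure --------------------------------------------------------------

#' Construct a Structure
#'
#' A `Structure` holds an atom table and an n-by-3 coordinate matrix in
#' Angstrom. Invariants checked: finite coordinates, matching row counts, an
#' element symbol for every atom.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `insert`, `occupancy`, `element` (missing `insert`/`occupancy`
#'   are filled with `""`/`1`).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return object of class `Structure`.
#' @export
structure_new <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (nrow(atoms) != nrow(xyz)) stop("atoms and xyz row counts differ")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  need <- c("name", "resname", "chain", "resno", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(atoms$element) | atoms$element == "")) {
    idx <- which(is.na(atoms$element) | atoms$element == "")
    atoms$element[idx] <- infer_element(atoms$name[idx])
  }
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  obj <- list(atoms = atoms, xyz = xyz)
  class(obj) <- "Structure"
  obj
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

scan_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  at <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(at) == 0L) stop("no ATOM/HETATM records in ", path)
  for (i in at) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, " of ", path,
           " (record shorter than coordinate fields)")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed coordinates at line ", i, " of ", path)
  }
  invisible(TRUE)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records (via the bio3d reader after a strict record
#' scan). Alternate locations are resolved by keeping, per
#' (chain, residue, insertion code, atom name), the record with the highest
#' occupancy; ties keep the first encountered. Insertion codes are preserved.
#' A blank element column is inferred from the atom name.
#'
#' @param path file path.
#' @param format only `"pdb"` is supported.
#' @return [structure_new()] object. For multi-model files only the first
#'   model's coordinates are used; see [read_trajectory()] for trajectories.
#' @export
read_structure <- function(path, format = "pdb") {
  if (!identical(format, "pdb")) stop("unsupported format: ", format)
  if (!file.exists(path)) stop("file not found: ", path)
  scan_pdb_records(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- at$o
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ, seq_len(nrow(at)))
    keep_first <- !duplicated(key[ord])
    keep <- sort(ord[keep_first])
    at <- at[keep, , drop = FALSE]
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  el <- at$elesy
  el[is.na(el)] <- ""
  atoms <- data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      resno = at$resno, insert = ins,
                      occupancy = ifelse(is.na(at$o), 1, at$o),
                      element = el, stringsAsFactors = FALSE)
  structure_new(atoms, cbind(at$x, at$y, at$z))
}

format_pdb_atom <- function(serial, name, resname, chain, resno, insert,
                            x, y, z, occupancy, element) {
  nm <- ifelse(nchar(name) >= 4, name, paste0(" ", name))
  sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, resname, substr(chain, 1, 1), resno %% 10000L,
          substr(paste0(insert, " "), 1, 1), x, y, z, occupancy, 0, element)
}

#' Write a structure (or trajectory) as PDB
#'
#' Single structures are written as a flat list of ATOM records; trajectories
#' as multi-model PDB (MODEL/ENDMDL per frame). Coordinates are printed at the
#' PDB fixed precision of 0.001 Angstrom.
#'
#' @param x a `Structure` or `Trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "Trajectory")) return(write_trajectory_pdb(x, path))
  if (!inherits(x, "Structure")) stop("x must be a Structure or Trajectory")
  a <- x$atoms
  lines <- format_pdb_atom(a$serial, a$name, a$resname, a$chain, a$resno,
                           a$insert, x$xyz[, 1], x$xyz[, 2], x$xyz[, 3],
                           a$occupancy, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  out <- vector("list", n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    fr <- frame_xyz(traj, i)
    out[[i]] <- c(sprintf("MODEL     %4d", i),
                  format_pdb_atom(a$serial, a$name, a$resname, a$chain,
                                  a$resno, a$insert, fr[, 1], fr[, 2],
                                  fr[, 3], a$occupancy, a$element),
                  "ENDMDL")
  }
  writeLines(c(unlist(out), "END"), path)
  invisible(path)
}

# ---- Trajectory -------------------------------------------------------------

#' Construct a Trajectory
#'
#' Ordered coordinate frames (Angstrom) over a fixed atom list, with frame
#' times in picoseconds (strictly increasing) and an optional per-frame
#' orthorhombic box.
#'
#' @param xyz array `n_frames x n_atoms x 3` (Angstrom).
#' @param times numeric vector of frame times, ps, strictly increasing.
#' @param topology `Structure` describing the atom list (optional but needed
#'   by mass-weighted and selection-based operations).
#' @param box optional `n_frames x 3` matrix of box edge lengths, Angstrom.
#' @return object of class `Trajectory`.
#' @export
trajectory_new <- function(xyz, times, topology = NULL, box = NULL) {
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("xyz must be an n_frames x n_atoms x 3 array")
  storage.mode(xyz) <- "double"
  if (length(times) != dim(xyz)[1]) stop("times length must equal frame count")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(topology)) {
    if (!inherits(topology, "Structure")) stop("topology must be a Structure")
    if (n_atoms(topology) != dim(xyz)[2])
      stop("atom count mismatch: topology has ", n_atoms(topology),
           " atoms, frames have ", dim(xyz)[2])
  }
  if (!is.null(box)) {
    box <- as.matrix(box)
    if (nrow(box) == 1L) box <- box[rep(1L, dim(xyz)[1]), , drop = FALSE]
    if (nrow(box) != dim(xyz)[1] || ncol(box) != 3L)
      stop("box must be n_frames x 3")
  }
  obj <- list(xyz = xyz, times = as.numeric(times), topology = topology,
              box = box)
  class(obj) <- "Trajectory"
  obj
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", dim(x$xyz)[2], "atoms,",
      "t =", x$times[1], "..", x$times[n_frames(x)], "ps\n")
  invisible(x)
}

#' Frame count and single-frame access
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @return `n_frames()` an integer; `frame_xyz()` an n_atoms-by-3 matrix (Angstrom).
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' @rdname n_frames
#' @export
frame_xyz <- function(traj, i) {
  m <- traj$xyz[i, , , drop = FALSE]
  dim(m) <- dim(traj$xyz)[2:3]
  m
}

#' Extract one frame as a Structure
#' @param traj a `Trajectory` with a topology.
#' @param i frame index.
#' @return a `Structure` with frame `i` coordinates.
#' @export
frame_structure <- function(traj, i) {
  if (is.null(traj$topology)) stop("trajectory has no topology")
  structure_new(traj$topology$atoms, frame_xyz(traj, i))
}

#' Read a trajectory from multi-model PDB files
#'
#' Each file contributes its models in order; files are concatenated in the
#' order given. Frame times are assigned on a uniform grid of `dt` ps unless
#' `times` is supplied explicitly.
#'
#' @param paths character vector of multi-model PDB paths.
#' @param topology `Structure` giving the atom list; every model must match
#'   its atom count.
#' @param dt frame spacing, ps, for the default time grid.
#' @param times optional explicit frame times, ps, strictly increasing.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(paths, topology, dt = 10, times = NULL) {
  stopifnot(length(paths) >= 1L)
  mats <- lapply(paths, function(p) {
    scan_pdb_records(p)
    pdb <- suppressWarnings(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE))
    m <- pdb$xyz
    if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
    if (ncol(m) != 3L * n_atoms(topology))
      stop("atom count mismatch in ", p, ": frames have ", ncol(m) / 3,
           " atoms, topology has ", n_atoms(topology))
    m
  })
  flat <- do.call(rbind, mats)
  nf <- nrow(flat)
  xyz <- array(NA_real_, dim = c(nf, n_atoms(topology), 3L))
  for (i in seq_len(nf)) xyz[i, , ] <- matrix(flat[i, ], ncol = 3L, byrow = TRUE)
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf) stop("times length must equal total frame count")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  trajectory_new(xyz, times, topology = topology)
}

# ---- columnar frame store ---------------------------------------------------

#' Read and write the internal columnar frame store
#'
#' A plain-text tab-separated container for trajectories: comment header
#' (atom count, box flag), then one row per frame holding the time in ps,
#' optionally the box edge lengths, and the flattened x/y/z coordinates in
#' Angstrom. Round-trips coordinates well within 1e-3 Angstrom.
#'
#' @param traj a `Trajectory`.
#' @param path file path (`.tsv` recommended).
#' @param topology optional `Structure` to attach on read.
#' @return `write_frame_store()` returns `path` invisibly;
#'   `read_frame_store()` returns a `Trajectory`.
#' @export
write_frame_store <- function(traj, path) {
  na <- dim(traj$xyz)[2]
  has_box <- !is.null(traj$box)
  con <- file(path, "w")
  writeLines(c("# mechanotraj frame store v1",
               paste0("# n_atoms: ", na),
               paste0("# box: ", if (has_box) "yes" else "no")), con)
  close(con)
  # row layout: x1 y1 z1 x2 y2 z2 ...
  flat <- t(apply(traj$xyz, 1, function(fr) as.vector(t(fr))))
  if (n_frames(traj) == 1L) flat <- matrix(flat, nrow = 1L)
  dat <- if (has_box) cbind(traj$times, traj$box, flat) else cbind(traj$times, flat)
  data.table::fwrite(data.table::as.data.table(dat), path, sep = "\t",
                     append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_store
#' @export
read_frame_store <- function(path, topology = NULL) {
  hdr <- readLines(path, n = 3L)
  if (!identical(hdr[1], "# mechanotraj frame store v1"))
    stop("not a mechanotraj frame store: ", path)
  na <- as.integer(sub("# n_atoms: ", "", hdr[2]))
  has_box <- identical(sub("# box: ", "", hdr[3]), "yes")
  dat <- as.matrix(data.table::fread(path, sep = "\t", skip = 3L))
  times <- dat[, 1]
  box <- NULL
  off <- 1L
  if (has_box) {
    box <- dat[, 2:4, drop = FALSE]
    off <- 4L
  }
  coords <- dat[, (off + 1L):(off + 3L * na), drop = FALSE]
  nf <- nrow(dat)
  xyz <- array(NA_real_, dim = c(nf, na, 3L))
  for (i in seq_len(nf)) xyz[i, , ] <- matrix(coords[i, ], ncol = 3L, byrow = TRUE)
  trajectory_new(xyz, times, topology = topology, box = box)
}

# ---- DomainMap and selections ----------------------------------------------

#' Named domain selections
#'
#' A `DomainMap` maps region names (TM, LH, TRP, S6, AR1..AR29, gate_residue,
#' ...) to lists of chain + residue-range entries, optionally flagged
#' backbone-only. Residue ranges follow the deposited PDB numbering; the map
#' is user-supplied configuration, not hard-coded.
#'
#' @param x named list; each element is a list of entries
#'   `list(chain =, from =, to =, backbone = FALSE)` (`to` defaults to
#'   `from`).
#' @return object of class `DomainMap`.
#' @export
domain_map <- function(x) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("every DomainMap entry must be named")
  x <- lapply(x, function(entries) {
    lapply(entries, function(e) {
      if (is.null(e$chain)) stop("DomainMap entry without chain")
      if (is.null(e$from)) stop("DomainMap entry without residue range")
      if (is.null(e$to)) e$to <- e$from
      if (is.null(e$backbone)) e$backbone <- FALSE
      if (e$to < e$from) stop("DomainMap entry with to < from")
      e[c("chain", "from", "to", "backbone")]
    })
  })
  class(x) <- "DomainMap"
  x
}

#' @rdname domain_map
#' @param path YAML file path with the same shape as `x`.
#' @export
read_domain_map <- function(path) domain_map(yaml::read_yaml(path))

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Resolve a named domain selection to atom indices
#'
#' Pure function of (structure, map, name): returns the sorted, deduplicated
#' indices of all atoms matched by the entries of `name`. Entries flagged
#' `backbone` restrict to N/CA/C/O.
#'
#' @param structure a `Structure`.
#' @param map a `DomainMap`.
#' @param name selection name defined in `map`.
#' @return sorted integer vector of atom indices; error if the name is
#'   undefined or resolves to no atoms.
#' @export
select_domain <- function(structure, map, name) {
  if (!inherits(map, "DomainMap")) stop("map must be a DomainMap")
  if (!name %in% names(map)) stop("selection name not in map: ", name)
  a <- structure$atoms
  idx <- integer(0)
  for (e in map[[name]]) {
    hit <- a$chain == e$chain & a$resno >= e$from & a$resno <= e$to
    if (isTRUE(e$backbone)) hit <- hit & a$name %in% BACKBONE_NAMES
    idx <- c(idx, which(hit))
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L) stop("selection '", name, "' resolves to no atoms")
  idx
}

# ---- centre of mass ---------------------------------------------------------

#' Mass-weighted centre of mass
#'
#' @param structure a `Structure`, or an n-by-3 coordinate matrix if `masses`
#'   is given.
#' @param sel optional atom indices (default: all atoms).
#' @param masses optional explicit masses (otherwise looked up from the
#'   element table; unknown elements error).
#' @return length-3 numeric vector, Angstrom.
#' @export
center_of_mass <- function(structure, sel = NULL, masses = NULL) {
  if (inherits(structure, "Structure")) {
    xyz <- structure$xyz
    if (is.null(masses)) masses <- mass_of(structure$atoms$element)
  } else {
    xyz <- as.matrix(structure)
    if (is.null(masses)) stop("masses required when passing raw coordinates")
  }
  if (is.null(sel)) sel <- seq_len(nrow(xyz))
  if (length(sel) == 0L) stop("empty selection")
  m <- masses[sel]
  colSums(xyz[sel, , drop = FALSE] * m) / sum(m)
}

com_of_frame <- function(traj, i, sel, masses) {
  xyz <- frame_xyz(traj, i)
  m <- masses[sel]
  colSums(xyz[sel, , drop = FALSE] * m) / sum(m)
}
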