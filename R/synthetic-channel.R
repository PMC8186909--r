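# A synthetic stand-in for a closed-state tetrameric mechanosensitive
# channel model. Entirely geometric and deterministic: it encodes, by
# construction, the hallmark features of the closed state that the analyses
# target - a sub-Angstrom gate constriction at residue 1554, a ~15 nm
# ankyrin-repeat span, and a TRP-LH interface in which three of four named
# hydrogen-bond pairs are in bonding geometry while Q1253-S1577 is not. It
# is a synthetic validation fixture for the analysis machinery, not a model
# of the deposited structure's coordinates.

deg <- function(a) a * pi / 180

rotate_z_xyz <- function(xyz, ang) {
  ca <- cos(ang); sa <- sin(ang)
  cbind(ca * xyz[, 1] - sa * xyz[, 2],
        sa * xyz[, 1] + ca * xyz[, 2],
        xyz[, 3])
}

# backbone cluster laid along direction u (unit, in-plane) at centre c
backbone_atoms <- function(c, u) {
  v <- c(-u[2], u[1], 0)
  rbind(N = c,
        CA = c + 1.5 * u,
        C = c + 3.0 * u,
        O = c + 3.0 * u + 1.2 * v)
}

#' Synthetic closed-state channel model
#'
#' Deterministic generator of a C4-symmetric tetramer (chains A-D) used as a
#' synthetic stand-in where a deposited closed-state structure would
#' otherwise be analysed. Per chain it contains: an S6-like pore-lining
#' helix (residues 1540-1570) whose side-chain atoms form an hourglass wall
#' with its narrowest accessible radius (0.6 Angstrom) at residue 1554
#' (ILE, atoms CG1/CD1 pointing into the pore); a TRP-LH/S4-S5 interface
#' with residues S1421, W1572, K1244, E1571, D1236, R1581, Q1253 and S1577
#' placed so that W1572(NE1)-S1421(backbone O), K1244(NZ)-E1571(OE1) and
#' R1581(NH1)-D1236(OD1) satisfy the heavy-atom hydrogen-bond criterion
#' while Q1253(NE2)-S1577(OG) is 5.5 Angstrom apart; and a 29-repeat
#' ankyrin trace (one CA per repeat, residues 101-129) spanning 15 nm along
#' z. No hydrogens are present, as in a typical cryo-EM deposition.
#'
#' @return a `Structure`.
#' @seealso [synthetic_channel_map()] for the matching domain map.
#' @export
synthetic_channel_model <- function() {
  z_gate <- (1554 - 1540) * 1.2
  r_acc <- function(z) 0.6 + 0.25 * abs(z - z_gate)
  name <- resname <- character(0)
  resno <- integer(0)
  xyz <- NULL
  add <- function(nm, rn, rs, coords) {
    name <<- c(name, nm)
    resname <<- c(resname, rep(rs, length(nm)))
    resno <<- c(resno, rep(rn, length(nm)))
    xyz <<- rbind(xyz, coords)
  }
  # S6-like pore lining: per residue, CB on the accessible wall, CA outside
  for (r in 1540:1570) {
    z <- (r - 1540) * 1.2
    phi <- deg(-100 * (r - 1540))
    ring <- r_acc(z) + 1.70
    cb <- c(ring * cos(phi), ring * sin(phi), z)
    ca <- c((ring + 2.5) * cos(phi), (ring + 2.5) * sin(phi), z)
    if (r == 1554) {
      cg <- c(ring * cos(phi + deg(12)), ring * sin(phi + deg(12)), z)
      cd <- c(ring * cos(phi - deg(12)), ring * sin(phi - deg(12)), z)
      add(c("CA", "CB", "CG1", "CD1"), r, "ILE", rbind(ca, cb, cg, cd))
    } else {
      add(c("CA", "CB"), r, "VAL", rbind(ca, cb))
    }
  }
  # TRP-LH / S4-S5 interface pairs, one contact point per pair
  iface <- function(res_d, rs_d, atom_d, res_a, rs_a, atom_a, gap,
                    azim, z) {
    P <- c(40 * cos(deg(azim)), 40 * sin(deg(azim)), z)
    u <- c(-sin(deg(azim)), cos(deg(azim)), 0)  # tangent
    # acceptor side: backbone + named acceptor atom
    ca_c <- P - 5.5 * u
    acc_bb <- backbone_atoms(ca_c, -u)
    acc_at <- P - (gap / 2) * u
    add(c(rownames(acc_bb), atom_a), res_a, rs_a, rbind(acc_bb, acc_at))
    # donor side
    cd_c <- P + 5.5 * u
    don_bb <- backbone_atoms(cd_c, u)
    don_at <- P + (gap / 2) * u
    add(c(rownames(don_bb), atom_d), res_d, rs_d, rbind(don_bb, don_at))
  }
  # W1572 NE1 donates to the backbone O of S1421 (side chain of S1421 not
  # involved): the acceptor "atom_a" here is a second O placed on the
  # backbone oxygen position of S1421
  P <- c(40 * cos(deg(5)), 40 * sin(deg(5)), 42)
  u <- c(-sin(deg(5)), cos(deg(5)), 0)
  v <- c(-u[2], u[1], 0)
  # S1421 cluster laid along +u but positioned so its backbone O sits at the
  # contact point P - 1.45 u; the serine OG points away (bond is
  # backbone-mediated)
  s1421_bb <- sweep(backbone_atoms(c(0, 0, 0), u), 2,
                    P - 1.45 * u - 3.0 * u - 1.2 * v, "+")
  add(c(rownames(s1421_bb), "OG"), 1421, "SER",
      rbind(s1421_bb, s1421_bb["CA", ] + c(0, 0, 3.0)))
  w_bb <- backbone_atoms(P + 5.5 * u, u)
  add(c(rownames(w_bb), "NE1"), 1572, "TRP",
      rbind(w_bb, P + 1.45 * u))
  iface(1244, "LYS", "NZ", 1571, "GLU", "OE1", 2.8, 95, 52)
  iface(1581, "ARG", "NH1", 1236, "ASP", "OD1", 2.9, 185, 62)
  iface(1253, "GLN", "NE2", 1577, "SER", "OG", 5.5, 275, 72)
  # ankyrin-repeat trace: 29 repeats spanning 15 nm below the pore
  for (i in 1:29) {
    phi <- deg(15 * (i - 1))
    z <- -180 + (i - 1) * (150 / 28)
    add("CA", 100L + i, "ALA",
        matrix(c(12 * cos(phi), 12 * sin(phi), z), 1))
  }
  # C4 copies
  n1 <- length(name)
  chains <- c("A", "B", "C", "D")
  all_xyz <- NULL
  for (c in 1:4) all_xyz <- rbind(all_xyz, rotate_z_xyz(xyz, deg(90 * (c - 1))))
  atoms <- data.frame(serial = seq_len(4L * n1),
                      name = rep(name, 4),
                      resname = rep(resname, 4),
                      chain = rep(chains, each = n1),
                      resno = rep(resno, 4),
                      insert = "", occupancy = 1,
                      element = rep(infer_element(name), 4),
                      stringsAsFactors = FALSE)
  structure_new(atoms, all_xyz)
}

#' Domain map matching [synthetic_channel_model()]
#'
#' @return a `DomainMap` with `gate_residue`, `S6` (= the pore lining),
#'   `TRP`, `LH`, `S4S5_linker`, `AR` and `AR1`..`AR29` selections over the
#'   four chains.
#' @export
synthetic_channel_map <- function() {
  chains <- c("A", "B", "C", "D")
  per_chain <- function(from, to = from, backbone = FALSE)
    lapply(chains, function(ch)
      list(chain = ch, from = from, to = to, backbone = backbone))
  m <- list(
    gate_residue = per_chain(1554),
    S6 = per_chain(1540, 1570),
    TRP = per_chain(1571, 1585),
    LH = per_chain(1236, 1260),
    S4S5_linker = per_chain(1415, 1430),
    AR = per_chain(101, 129))
  for (i in 1:29) m[[paste0("AR", i)]] <- per_chain(100L + i)
  domain_map(m)
}

#' The four named TRP-LH interface pairs
#'
#' Default residue pairing used by the interface census: W1572-S1421
#' (backbone acceptor), Q1253-S1577, K1244-E1571, D1236-R1581, instantiated
#' on one chain. Override freely; pairings beyond the first two follow the
#' residue memberships reported for the interface, and exact atom pairings
#' are configuration.
#'
#' @param chain chain identifier (default "A").
#' @return list of residue-pair specs for [interface_pairs_report()].
#' @export
trp_lh_interface_pairs <- function(chain = "A") {
  mk <- function(a, b) list(resA = list(chain = chain, resno = a),
                            resB = list(chain = chain, resno = b))
  list(W1572_S1421 = mk(1572, 1421),
       Q1253_S1577 = mk(1253, 1577),
       K1244_E1571 = mk(1244, 1571),
       D1236_R1581 = mk(1236, 1581))
}
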