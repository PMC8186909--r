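# Shared fixture builders; everything is generated in code at test time.

# minimal PDB text for hand-built structures
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element, occ = 1.00) {
  nm <- if (nchar(name) >= 4) name else paste0(" ", name)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resname, chain, resno, x, y, z, occ, 0, element)
}

write_tiny_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# a 10-atom two-residue structure used across io tests
tiny_structure <- function() {
  atoms <- data.frame(
    serial = 1:6,
    name = c("N", "CA", "C", "O", "CB", "OG"),
    resname = c(rep("ALA", 4), "SER", "SER"),
    chain = c(rep("A", 4), "B", "B"),
    resno = c(rep(1L, 4), 5L, 5L),
    insert = "",
    occupancy = 1,
    element = c("N", "C", "C", "O", "C", "O"),
    stringsAsFactors = FALSE)
  xyz <- matrix(c(0, 0, 0,   1.5, 0, 0,   2.2, 1.2, 0,  2.2, 2.4, 0.4,
                  4, 4, 4,   5.1, 4.2, 4.4), ncol = 3, byrow = TRUE)
  structure_new(atoms, xyz)
}

# trajectory with linear drift of one atom, for series tests
drift_trajectory <- function(n_frames = 5) {
  s <- tiny_structure()
  xyz <- array(rep(s$xyz, each = n_frames), dim = c(n_frames, nrow(s$xyz), 3))
  for (i in seq_len(n_frames)) xyz[i, 1, 3] <- (i - 1) * 2
  trajectory_new(xyz, seq_len(n_frames) * 10, topology = s)
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = paste0(deparse(substitute(object)), " = ",
                             paste(signif(object, 6), collapse = ", "),
                             " vs expected ",
                             paste(signif(expected, 6), collapse = ", ")))
}
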