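test_that("a single-atom PDB parses to its printed coordinates", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(p, pdb_line(1, "CA", "GLY", "A", 7, 1.234, -5.678, 9.012, "C"))
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$resno, 7L)
  expect_equal(unname(s$xyz[1, ]), c(1.234, -5.678, 9.012))
})

test_that("write/read round-trip preserves coordinates and identifiers", {
  s <- tiny_structure()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, p)
  s2 <- read_structure(p)
  expect_equal(s2$xyz, s$xyz, tolerance = 1e-9)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$chain, s$atoms$chain)
  expect_equal(s2$atoms$resno, s$atoms$resno)
  # idempotence: a second round-trip is byte-identical
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("malformed and empty PDB files are rejected with line info", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
               "ATOM      2  CB BAD"), p)
  expect_error(read_structure(p), "line 2")
  writeLines(character(0), p)
  expect_error(read_structure(p), "empty")
})

test_that("altloc resolution keeps the highest-occupancy record", {
  p <- withr::local_tempfile(fileext = ".pdb")
  l1 <- "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.40  0.00           C"
  l2 <- "ATOM      2  CA BGLY A   1       2.000   0.000   0.000  0.60  0.00           C"
  write_tiny_pdb(p, c(l1, l2))
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$xyz[1, 1], 2.0)
})

test_that("multi-model PDB reads as a trajectory and files concatenate", {
  topo <- tiny_structure()
  t1 <- withr::local_tempfile(fileext = ".pdb")
  t2 <- withr::local_tempfile(fileext = ".pdb")
  xyz <- array(rep(topo$xyz, each = 5), dim = c(5, 6, 3))
  xyz[, 1, 1] <- 1:5
  write_structure(trajectory_new(xyz[1:2, , , drop = FALSE], c(10, 20),
                                 topology = topo), t1)
  write_structure(trajectory_new(xyz[3:5, , , drop = FALSE], c(10, 20, 30),
                                 topology = topo), t2)
  tr <- read_trajectory(c(t1, t2), topo, dt = 10)
  expect_equal(n_frames(tr), 5L)
  expect_equal(tr$xyz[, 1, 1], as.numeric(1:5))
  expect_true(all(diff(tr$times) > 0))
  # atom-count mismatch rejected
  small <- structure_new(topo$atoms[1:3, ], topo$xyz[1:3, ])
  expect_error(read_trajectory(t1, small), "mismatch")
})

test_that("frame store round-trips coordinates, times and box", {
  topo <- tiny_structure()
  xyz <- array(rnorm(4 * 6 * 3, sd = 5), dim = c(4, 6, 3))
  tr <- trajectory_new(xyz, c(1, 2, 4, 8), topology = topo,
                       box = matrix(rep(c(40, 40, 80), 4), 4, byrow = TRUE))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_frame_store(tr, p)
  tr2 <- read_frame_store(p, topology = topo)
  expect_equal(tr2$xyz, tr$xyz, tolerance = 1e-3)
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$box, tr$box, ignore_attr = TRUE)
})

test_that("trajectory invariants are enforced", {
  topo <- tiny_structure()
  xyz <- array(0, dim = c(2, 6, 3))
  expect_error(trajectory_new(xyz, c(2, 1), topology = topo), "increasing")
  expect_error(trajectory_new(xyz, c(1, 2),
                              topology = structure_new(topo$atoms[1:2, ],
                                                       topo$xyz[1:2, ])),
               "mismatch")
})

test_that("domain selections resolve deterministically with backbone flag", {
  s <- tiny_structure()
  map <- domain_map(list(
    ala = list(list(chain = "A", from = 1, to = 1)),
    ala_bb = list(list(chain = "A", from = 1, to = 1, backbone = TRUE)),
    ser = list(list(chain = "B", from = 5)),
    both = list(list(chain = "A", from = 1), list(chain = "B", from = 5)),
    nothing = list(list(chain = "Z", from = 99))))
  expect_equal(select_domain(s, map, "ala"), 1:4)
  expect_equal(select_domain(s, map, "ala_bb"), 1:4)  # all four are backbone
  expect_equal(select_domain(s, map, "ser"), 5:6)
  # union equals combination of parts
  expect_equal(select_domain(s, map, "both"),
               sort(union(select_domain(s, map, "ala"),
                          select_domain(s, map, "ser"))))
  expect_error(select_domain(s, map, "missing"), "not in map")
  expect_error(select_domain(s, map, "nothing"), "no atoms")
  # pure function: repeated calls identical
  expect_identical(select_domain(s, map, "both"),
                   select_domain(s, map, "both"))
})

test_that("domain map reads from YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gate_residue:",
               "  - {chain: A, from: 1, to: 1}",
               "ser_bb:",
               "  - {chain: B, from: 5, backbone: true}"), p)
  map <- read_domain_map(p)
  s <- tiny_structure()
  expect_equal(select_domain(s, map, "gate_residue"), 1:4)
  expect_error(select_domain(s, map, "ser_bb"), "no atoms")  # SER OG/CB not backbone
})

test_that("center of mass matches brute force and is translation-equivariant", {
  # two equal-mass atoms
  atoms <- data.frame(serial = 1:2, name = "CA", resname = "GLY",
                      chain = "A", resno = 1:2, insert = "", occupancy = 1,
                      element = "C", stringsAsFactors = FALSE)
  s <- structure_new(atoms, rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_equal(unname(center_of_mass(s)), c(0, 0, 1))

  set.seed(42)
  n <- 50
  els <- sample(c("C", "N", "O", "S", "H"), n, replace = TRUE)
  atoms <- data.frame(serial = 1:n, name = "X", resname = "UNK", chain = "A",
                      resno = 1:n, insert = "", occupancy = 1, element = els,
                      stringsAsFactors = FALSE)
  xyz <- matrix(rnorm(3 * n, sd = 10), ncol = 3)
  s <- structure_new(atoms, xyz)
  masses <- atomic_masses()[ifelse(els == "NA", "NA.", els)]
  brute <- colSums(xyz * masses) / sum(masses)
  expect_close(center_of_mass(s), brute, 1e-12)
  # translation equivariance
  t <- c(3.2, -1.1, 7.7)
  s2 <- structure_new(atoms, sweep(xyz, 2, t, "+"))
  expect_close(center_of_mass(s2), brute + t, 1e-10)
  # COM of union = mass-weighted combination of disjoint parts
  a <- 1:20; b <- 21:50
  ma <- sum(masses[a]); mb <- sum(masses[b])
  comb <- (center_of_mass(s, a) * ma + center_of_mass(s, b) * mb) / (ma + mb)
  expect_close(center_of_mass(s, c(a, b)), comb, 1e-10)
  expect_error(center_of_mass(s, integer(0)), "empty")
})

test_that("unknown elements error in mass lookup", {
  atoms <- data.frame(serial = 1, name = "XX", resname = "UNK", chain = "A",
                      resno = 1, insert = "", occupancy = 1, element = "XQ",
                      stringsAsFactors = FALSE)
  s <- structure_new(atoms, matrix(0, 1, 3))
  expect_error(center_of_mass(s), "unknown element")
})
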