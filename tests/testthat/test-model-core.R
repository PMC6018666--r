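# Atomic-model layer: PDB I/O, chain roles, ring centroids, RMSD, moves.

make_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.685   7.148  -4.897  1.00  0.00           C",
    "END"
  ), path)
  path
}

test_that("PDB round-trips with coordinates preserved to 3 decimals", {
  p1 <- make_mini_pdb(tempfile(fileext = ".pdb"))
  m <- read_pdb(p1)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$name, c("N", "CA", "C"))
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(m, p2)
  m2 <- read_pdb(p2)
  expect_equal(coords(m2), coords(m), tolerance = 5e-4)
  expect_equal(m2$atoms$resname, m$atoms$resname)
  expect_equal(m2$atoms$chain, m$atoms$chain)
})

test_that("chain roles are inferred from residue names", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C1'   U B   1       5.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), p)
  m <- read_pdb(p)
  expect_equal(unname(m$roles[c("A", "B")]), c("protein", "rna"))
})

test_that("malformed, inserted and empty PDB inputs are rejected", {
  p <- tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  ALA A   1      xx.xxx   0.000   0.000", p)
  expect_error(read_pdb(p), "line 1")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A      1.000   0.000   0.000  1.00  0.00           C"
  ), p)
  expect_error(read_pdb(p), "insertion")
  writeLines(character(0), p)
  expect_error(read_pdb(p), "no ATOM")
  expect_error(read_pdb(tempfile()), "not found")
})

test_that("generated toy model matches its own manifest counts", {
  toy <- toy_fixture()
  expect_equal(nrow(toy$truth$atoms), toy$manifest$n_atoms)
  counts <- table(toy$truth$atoms$chain)
  expect_equal(as.vector(counts),
               as.vector(toy$manifest$n_atoms_per_chain))
  p <- tempfile(fileext = ".pdb")
  write_pdb(toy$truth, p)
  back <- read_pdb(p)
  expect_equal(nrow(back$atoms), toy$manifest$n_atoms)
  expect_equal(backbone_rmsd(back, toy$truth), 0, tolerance = 1e-3)
})

test_that("ring_center is the centroid of the ring atoms", {
  # regular hexagon at the origin and translated
  hex <- data.frame(
    serial = 1:6, name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    elem = "C", resno = 1, resname = "PHE", chain = "A",
    x = cos(seq(0, 5) * pi / 3), y = sin(seq(0, 5) * pi / 3), z = 0
  )
  m <- atomic_model(hex, roles = c(A = "protein"))
  expect_equal(ring_center(m, "A", 1), c(x = 0, y = 0, z = 0),
               ignore_attr = TRUE, tolerance = 1e-12)
  hex2 <- hex
  hex2$x <- hex2$x + 1; hex2$y <- hex2$y + 2; hex2$z <- hex2$z + 3
  m2 <- atomic_model(hex2, roles = c(A = "protein"))
  expect_equal(ring_center(m2, "A", 1), c(1, 2, 3), ignore_attr = TRUE)

  # toy Phe ring equals the plain mean of its six ring atoms
  toy <- toy_fixture()
  idx <- with(toy$truth$atoms,
              which(chain == "A" & resno == 10 &
                      name %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")))
  expect_equal(ring_center(toy$truth, "A", 10),
               colMeans(coords(toy$truth, idx)), ignore_attr = TRUE)

  # missing ring atoms are named
  m3 <- atomic_model(hex[-1, ], roles = c(A = "protein"))
  expect_error(ring_center(m3, "A", 1), "CG")
  expect_error(ring_center(toy$truth, "A", 1), "ring definition")
})

test_that("backbone RMSD behaves as a superposition metric", {
  toy <- toy_fixture()
  truth <- toy$truth
  expect_equal(backbone_rmsd(truth, truth), 0, tolerance = 1e-9)

  shifted <- truth
  shifted$atoms[c("x", "y", "z")] <- shifted$atoms[c("x", "y", "z")] + 5 / sqrt(3)
  expect_equal(backbone_rmsd(truth, shifted, superpose = TRUE), 0,
               tolerance = 1e-6)
  expect_equal(backbone_rmsd(truth, shifted, superpose = FALSE), 5,
               tolerance = 1e-6)

  # brute-force pairwise formula on a small selection, no superposition
  sel <- "A:1-5"
  a <- truth$atoms
  keep <- a$chain == "A" & a$resno <= 5 & a$name %in% c("N", "CA", "C", "O")
  d2 <- rowSums((coords(truth)[keep, ] - coords(toy$start)[keep, ])^2)
  expect_equal(backbone_rmsd(truth, toy$start, selection = sel,
                             superpose = FALSE),
               sqrt(mean(d2)), tolerance = 1e-9)
  # symmetry
  expect_equal(backbone_rmsd(truth, toy$start), backbone_rmsd(toy$start, truth),
               tolerance = 1e-6)
  expect_error(backbone_rmsd(truth, truth, selection = "A:300-301"),
               "empty")
})

test_that("rigid moves preserve intra-group geometry and torsion moves are local", {
  toy <- toy_fixture()
  m <- toy$truth
  part <- toy$partition

  # identity move changes nothing
  m_id <- apply_move(m, part, group = "dom2")
  expect_equal(coords(m_id), coords(m))

  # 180-degree rotation twice returns the original coordinates
  R180 <- rotation_about_axis(c(0, 0, 1), pi)
  m_two <- apply_move(apply_move(m, part, group = "dom2", rotation = R180),
                      part, group = "dom2", rotation = R180)
  expect_equal(coords(m_two), coords(m), tolerance = 1e-6)

  # random rigid move: intra-group distances conserved, inter-group change
  set.seed(42)
  Rr <- rotation_about_axis(rnorm(3), runif(1, 0.2, 1))
  mv <- apply_move(m, part, group = "dom2", rotation = Rr,
                   translation = runif(3, -2, 2))
  g2 <- part$groups$dom2
  idx <- unlist(lapply(seq_len(nrow(g2)), function(i) {
    which(m$atoms$chain == g2$chain[i] & m$atoms$resno == g2$resno[i])
  }))
  expect_equal(as.vector(dist(coords(mv, idx))),
               as.vector(dist(coords(m, idx))), tolerance = 1e-6)
  other <- setdiff(seq_len(nrow(m$atoms)), idx)
  d_before <- sqrt(sum((colMeans(coords(m, idx)) -
                          colMeans(coords(m, other)))^2))
  d_after <- sqrt(sum((colMeans(coords(mv, idx)) -
                         colMeans(coords(mv, other)))^2))
  expect_gt(abs(d_after - d_before), 1e-4)

  # improper rotation rejected; unknown group rejected
  expect_error(apply_move(m, part, group = "dom2", rotation = diag(c(1, 1, -1))),
               "proper")
  expect_error(apply_move(m, part, group = "nope"), "unknown")

  # torsion move leaves upstream atoms fixed
  mt <- apply_move(m, part, torsions = data.frame(resno = 20,
                                                  dihedral = "phi",
                                                  delta_deg = 25))
  up <- which(m$atoms$chain == "A" & m$atoms$resno < 20)
  expect_equal(coords(mt, up), coords(m, up))
  down <- which(m$atoms$chain == "A" & m$atoms$resno > 20)
  expect_gt(max(abs(coords(mt, down) - coords(m, down))), 0.1)
})

test_that("selection mini-language parses and rejects malformed input", {
  sel <- parse_selection("A:3-5:CA,N")
  expect_equal(nrow(sel), 6)
  expect_setequal(unique(sel$name), c("CA", "N"))
  expect_error(parse_selection("A"), "malformed")
  expect_error(parse_selection("A:x-y"), "malformed")
})

test_that("model validation catches duplicates and bad coordinates", {
  at <- data.frame(serial = 1:2, name = "CA", elem = "C", resno = 1,
                   resname = "ALA", chain = "A", x = 0, y = 0, z = 0)
  expect_error(atomic_model(at, roles = c(A = "protein")), "duplicate")
  at$name <- c("CA", "CB")
  at$x[2] <- NA
  expect_error(atomic_model(at, roles = c(A = "protein")), "finite")
})
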