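# Coordinate I/O, altloc policy, Kabsch superposition and RMSD.

test_that("a minimal hand-written PDB fixture parses with author numbering", {
  atoms <- fixture_atoms(resno = c(10, 10, 11, 11, 12, 12),
                         resid = rep(c("SER", "GLU", "ARG"), each = 2),
                         elety = c("CA", "OG", "CA", "OE1", "CA", "NH1"),
                         element = c("C", "O", "C", "O", "C", "N"),
                         x = c(0, 1, 4, 5, 8, 9), y = 0, z = 0)
  tmp <- tempfile(fileext = ".pdb")
  write_fixture_pdb(tmp, atoms)
  m <- read_structure(tmp)
  expect_equal(nrow(m$atoms), 6L)
  expect_equal(sort(unique(m$atoms$resno)), c(10L, 11L, 12L))
  expect_equal(m$atoms$x[m$atoms$elety == "NH1"], 9)
  expect_equal(m$atoms$resid[m$atoms$resno == 11][1], "GLU")
})

test_that("the same content read as PDB and as mmCIF gives identical models", {
  atoms <- fixture_atoms(resno = c(1, 1, 1, 2), resid = c(rep("GLY", 3), "HOH"),
                         elety = c("N", "CA", "C", "O"),
                         element = c("N", "C", "C", "O"),
                         x = c(1.5, 2.25, 3.125, 10), y = c(0, 1, 0, 5),
                         z = c(0, 0.5, 1, 2), het = c(FALSE, FALSE, FALSE, TRUE))
  pdb <- tempfile(fileext = ".pdb")
  write_fixture_pdb(pdb, atoms)
  cif <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_fixture", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    vapply(seq_len(nrow(atoms)), function(i) {
      a <- atoms[i, ]
      sprintf("%s %d %s %s . %s %s %d ? %.3f %.3f %.3f 1.00",
              ifelse(a$het, "HETATM", "ATOM"), i, a$element, a$elety,
              a$resid, a$chain, a$resno, a$x, a$y, a$z)
    }, character(1)), "#"), cif)
  mp <- read_structure(pdb)
  mc <- read_structure(cif)
  cols <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z",
            "het")
  expect_equal(mp$atoms[, cols], mc$atoms[, cols])
  suppressWarnings(
    expect_error(read_structure(tempfile(fileext = ".cif")),
                 "cannot open|parse"))
})

test_that("altloc resolution keeps the highest occupancy, ties prefer A", {
  atoms <- fixture_atoms(resno = c(1, 1, 2, 2), resid = "SER",
                         elety = c("OG", "OG", "OG", "OG"),
                         element = "O", x = c(1, 2, 3, 4), y = 0, z = 0,
                         occ = c(0.4, 0.6, 0.5, 0.5),
                         altloc = c("A", "B", "B", "A"))
  tmp <- tempfile(fileext = ".pdb")
  write_fixture_pdb(tmp, atoms)
  m <- read_structure(tmp)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 2)  # occupancy 0.6 wins
  expect_equal(m$atoms$altloc[m$atoms$resno == 2], "A")  # tie -> A
})

test_that("superposing a model onto itself gives zero RMSD", {
  sim <- simulate_structures(simulation_spec(seed = 1, structure_sigma = 0))
  sup <- superpose(sim$reference, sim$reference)
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)
})

test_that("a rigidly transformed copy superposes to zero and inverts the transform", {
  sim <- simulate_structures(simulation_spec(seed = 2, structure_sigma = 0))
  sup <- superpose(sim$reference, sim$mobile)
  expect_lt(sup$rmsd, 1e-9)
  # moving the mobile model back onto the reference inverts the applied
  # rotation
  expect_lt(max(abs(sup$rotation %*% sim$rotation - diag(3))), 1e-8)
  moved <- transform_model(sim$mobile, sup)
  expect_equal(moved$atoms$x, sim$reference$atoms$x, tolerance = 1e-6)
})

test_that("RMSD is invariant under random proper rigid transforms", {
  set.seed(111)
  sim <- simulate_structures(simulation_spec(seed = 3, structure_sigma = 0.2))
  base <- superpose(sim$reference, sim$mobile)$rmsd
  for (rep in 1:5) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rot <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                  3, 3, byrow = TRUE)
    spun <- transform_model(sim$mobile,
                            list(rotation = rot,
                                 translation = runif(3, -30, 30)))
    expect_equal(superpose(sim$reference, spun)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("noisy-copy RMSD matches the sqrt(3)*sigma expectation and the quaternion oracle", {
  spec <- simulation_spec(seed = 4, structure_sigma = 0.3,
                          structure_n_residues = 125)  # 500 atoms
  sim <- simulate_structures(spec)
  sup <- superpose(sim$reference, sim$mobile)
  expect_equal(sup$n_atoms, 500L)
  expect_equal(sup$rmsd, sqrt(3) * 0.3, tolerance = 0.1)
  # quaternion (Horn) oracle on the same paired coordinates
  p <- as.matrix(sim$mobile$atoms[, c("x", "y", "z")])
  q <- as.matrix(sim$reference$atoms[, c("x", "y", "z")])
  oracle <- horn_superpose(p, q)
  expect_equal(sup$rmsd, oracle$rmsd, tolerance = 1e-9)
  expect_lt(max(abs(sup$rotation - oracle$rotation)), 1e-6)
  # and against bio3d's fitter as a second independent route
  b3 <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(q)), mobile = as.numeric(t(p))))
  expect_equal(sup$rmsd,
               sqrt(mean(colSums(matrix((b3 - as.numeric(t(q)))^2, nrow = 3)))),
               tolerance = 1e-6)
})

test_that("kabsch agrees with the quaternion oracle on random point sets", {
  set.seed(121)
  for (rep in 1:10) {
    n <- sample(4:40, 1)
    p <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    q <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    k <- kabsch(p, q)
    h <- horn_superpose(p, q)
    expect_equal(k$rmsd, h$rmsd, tolerance = 1e-9)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition over a residue range pairs by residue and atom name", {
  sim <- simulate_structures(simulation_spec(seed = 6, structure_sigma = 0.1))
  sup <- superpose(sim$reference, sim$mobile, residue_range = c(11, 110),
                   atom_names = c("N", "CA", "C", "O"))
  expect_equal(sup$n_atoms, 400L)
  ca_only <- superpose(sim$reference, sim$mobile, residue_range = c(11, 110),
                       atom_names = "CA")
  expect_equal(ca_only$n_atoms, 100L)
  # residues missing from one model are reported, not silently dropped
  chopped <- sim$mobile
  chopped$atoms <- chopped$atoms[chopped$atoms$resno > 20, ]
  sup2 <- superpose(sim$reference, chopped, residue_range = c(11, 110))
  expect_true(all(11:20 %in% sup2$unpaired$resno))
  expect_error(superpose(sim$reference, chopped, residue_range = c(12, 14)),
               "paired atoms")
})

test_that("PDB write/read round-trips coordinates to format precision", {
  sim <- simulate_structures(simulation_spec(seed = 7,
                                             structure_n_residues = 20))
  tmp <- tempfile(fileext = ".pdb")
  write_structure_pdb(sim$reference, tmp)
  back <- read_structure(tmp)
  expect_equal(nrow(back$atoms), nrow(sim$reference$atoms))
  expect_equal(back$atoms$x, sim$reference$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$resno, sim$reference$atoms$resno)
  expect_equal(back$atoms$elety, sim$reference$atoms$elety)
})

test_that("measure_distance resolves references and reports candidates", {
  atoms <- rbind(
    fixture_atoms(resno = 147, resid = "SER", elety = c("CA", "OG"),
                  element = c("C", "O"), x = c(0, 0), y = c(0, 0),
                  z = c(0, 1)),
    fixture_atoms(resno = 7, resid = "UCN", elety = "O7", element = "O",
                  x = 0, y = 0, z = 3.86, het = TRUE))
  tmp <- tempfile(fileext = ".pdb")
  write_fixture_pdb(tmp, atoms)
  m <- read_structure(tmp)
  expect_equal(measure_distance(m, "147:OG", "7:O7"), 2.86, tolerance = 1e-6)
  expect_equal(measure_distance(m, "A:147:CA", "147:CA"), 0)
  expect_error(measure_distance(m, "147:OXT", "7:O7"), "CA, OG")
})
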