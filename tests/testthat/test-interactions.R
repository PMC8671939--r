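# Geometric interaction detectors on constructed fixtures with known
# geometry: hydrogen bonds, salt bridges, cation-pi classes, CH-pi,
# water bridges and pocket contacts.

make_model <- function(atoms) {
  tmp <- tempfile(fileext = ".pdb")
  write_fixture_pdb(tmp, atoms)
  read_structure(tmp)
}

test_that("hydrogen bonds respect the heavy-atom distance cutoff", {
  near <- make_model(rbind(
    fixture_atoms(resno = 1, resid = "SER", elety = "OG", element = "O",
                  x = 0, y = 0, z = 0),
    fixture_atoms(resno = 2, resid = "GLN", elety = "NE2", element = "N",
                  x = 2.8, y = 0, z = 0)))
  hb <- detect_hbonds(near)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.8, tolerance = 1e-3)
  far <- make_model(rbind(
    fixture_atoms(resno = 1, resid = "SER", elety = "OG", element = "O",
                  x = 0, y = 0, z = 0),
    fixture_atoms(resno = 2, resid = "GLN", elety = "NE2", element = "N",
                  x = 4.2, y = 0, z = 0)))
  expect_equal(nrow(detect_hbonds(far)), 0L)
  # ligand donors come from the chemistry table (UCN O7 hydroxyl)
  lig <- make_model(rbind(
    fixture_atoms(resno = 64, resid = "GLU", elety = "OE1", element = "O",
                  x = 0, y = 0, z = 0),
    fixture_atoms(resno = 500, resid = "UCN", elety = "O7", element = "O",
                  x = 2.7, y = 0, z = 0, het = TRUE)))
  hb2 <- detect_hbonds(lig)
  expect_equal(nrow(hb2), 1L)
  expect_true(any(grepl("UCN", c(hb2$partner_a, hb2$partner_b))))
})

test_that("detectors are idempotent and symmetric in partner order", {
  m <- make_model(rbind(
    fixture_atoms(resno = 1, resid = "SER", elety = "OG", element = "O",
                  x = 0, y = 0, z = 0),
    fixture_atoms(resno = 2, resid = "THR", elety = "OG1", element = "O",
                  x = 2.9, y = 0, z = 0)))
  a <- detect_hbonds(m); b <- detect_hbonds(m)
  expect_identical(a, b)
  expect_equal(nrow(a), 1L)  # one row per unordered pair
  expect_true(all(a$distance <= 3.5))
})

test_that("salt bridges pair cationic nitrogens with anionic oxygens", {
  close_pair <- rbind(
    fixture_atoms(resno = 90, resid = "ARG",
                  elety = c("NE", "NH1", "NH2"), element = "N",
                  x = c(0, -1.1, -0.4), y = c(0, 0.7, 1.2), z = 0),
    fixture_atoms(resno = 64, resid = "GLU", elety = c("OE1", "OE2"),
                  element = "O", x = c(2.9, 3.4), y = 0, z = 0))
  sb <- detect_salt_bridges(make_model(close_pair))
  expect_equal(nrow(sb), 1L)  # one interaction per residue pair, min dist
  expect_equal(sb$distance, 2.9, tolerance = 0.05)
  far_pair <- close_pair
  far_pair$x[far_pair$resid == "GLU"] <- c(6, 6.5)
  expect_equal(nrow(detect_salt_bridges(make_model(far_pair))), 0L)
})

test_that("cation-pi geometry classes follow the normal angle", {
  ring <- benzene_atoms()
  axial <- rbind(ring,
                 fixture_atoms(resno = 90, resid = "LYS", elety = "NZ",
                               element = "N", x = 0, y = 0, z = 4))
  m1 <- make_model(axial)
  r1 <- ligand_rings(m1, "BNZ")
  expect_length(r1, 1L)
  cp1 <- detect_cation_pi(m1, r1)
  expect_equal(nrow(cp1), 1L)
  expect_equal(cp1$geometry_class, "stacked")
  expect_equal(cp1$distance, 4, tolerance = 1e-3)

  inplane <- rbind(ring,
                   fixture_atoms(resno = 90, resid = "LYS", elety = "NZ",
                                 element = "N", x = 4.5, y = 0, z = 0))
  m2 <- make_model(inplane)
  cp2 <- detect_cation_pi(m2, ligand_rings(m2, "BNZ"))
  expect_equal(cp2$geometry_class, "T-shaped")
  # beyond 6 A: nothing
  distant <- rbind(ring,
                   fixture_atoms(resno = 90, resid = "LYS", elety = "NZ",
                                 element = "N", x = 0, y = 0, z = 7))
  m3 <- make_model(distant)
  expect_equal(nrow(detect_cation_pi(m3, ligand_rings(m3, "BNZ"))), 0L)
})

test_that("an arginine guanidinium group is treated as one cation centroid", {
  ring <- benzene_atoms()
  arg <- rbind(ring,
               fixture_atoms(resno = 90, resid = "ARG",
                             elety = c("NE", "NH1", "NH2"), element = "N",
                             x = c(-0.6, 0.6, 0), y = c(0.4, 0.4, -0.8),
                             z = 4.2))
  m <- make_model(arg)
  cp <- detect_cation_pi(m, ligand_rings(m, "BNZ"))
  expect_equal(nrow(cp), 1L)
  expect_match(cp$partner_a, "ARG90")
  expect_equal(cp$geometry_class, "stacked")
})

test_that("CH-pi requires both proximity and out-of-plane elevation", {
  ring <- benzene_atoms()
  above <- rbind(ring,
                 fixture_atoms(resno = 112, resid = "PHE", elety = "CD1",
                               element = "C", x = 0.3, y = 0, z = 3.58))
  m1 <- make_model(above)
  ch1 <- detect_ch_pi(m1, ligand_rings(m1, "BNZ"))
  expect_equal(nrow(ch1), 1L)
  expect_gt(ch1$angle, 30)
  inplane <- rbind(ring,
                   fixture_atoms(resno = 112, resid = "PHE", elety = "CD1",
                                 element = "C", x = 3.6, y = 0, z = 0))
  m2 <- make_model(inplane)
  expect_equal(nrow(detect_ch_pi(m2, ligand_rings(m2, "BNZ"))), 0L)
})

test_that("non-planar rings are rejected with a warning", {
  bent <- benzene_atoms()
  bent$z <- c(0, 0.8, 0, -0.8, 0, 0.8)
  m <- make_model(bent)
  expect_warning(r <- ligand_rings(m, "BNZ"), "planarity")
  expect_length(r, 0L)
})

test_that("ring centroid and normal are as constructed", {
  m <- make_model(benzene_atoms(z = 2))
  r <- ligand_rings(m, "BNZ")[[1]]
  expect_equal(r$centroid, c(0, 0, 2), tolerance = 1e-3)
  expect_equal(sqrt(sum(r$normal^2)), 1, tolerance = 1e-10)
  expect_equal(abs(r$normal[3]), 1, tolerance = 1e-6)
})

test_that("bridging waters need two legs; spread and extra distances report", {
  bridge <- rbind(
    fixture_atoms(resno = 114, resid = "SER", elety = "OG", element = "O",
                  x = -2.8, y = 0, z = 0),
    fixture_atoms(resno = 125, resid = "SER", elety = "OG", element = "O",
                  x = 2.8, y = 0, z = 0),
    fixture_atoms(resno = 700, resid = "HOH", elety = "O", element = "O",
                  x = 0, y = 0, z = 0, het = TRUE),
    fixture_atoms(resno = 500, resid = "UCN", elety = "O6", element = "O",
                  x = 0, y = 3.8, z = 0, het = TRUE))
  m <- make_model(bridge)
  wb <- detect_water_bridges(m, extra_refs = "500:O6")
  expect_equal(nrow(wb), 1L)
  expect_equal(wb$n_legs, 2L)
  expect_equal(wb$spread, 0, tolerance = 1e-6)  # equidistant legs
  expect_equal(wb$dist_500_O6, 3.8, tolerance = 1e-3)
  # one partner only: not a bridge
  single <- bridge[bridge$resno != 125, ]
  expect_equal(nrow(detect_water_bridges(make_model(single))), 0L)
})

test_that("pocket residues are found within the cutoff and sorted", {
  atoms <- rbind(
    fixture_atoms(resno = 49, resid = "PHE", elety = "CZ", element = "C",
                  x = 3, y = 0, z = 0),
    fixture_atoms(resno = 37, resid = "TYR", elety = "OH", element = "O",
                  x = 4.2, y = 0, z = 0),
    fixture_atoms(resno = 101, resid = "LEU", elety = "CD1", element = "C",
                  x = 9, y = 0, z = 0),
    fixture_atoms(resno = 500, resid = "UCN", elety = "C1", element = "C",
                  x = 0, y = 0, z = 0, het = TRUE))
  m <- make_model(atoms)
  pk <- ligand_pocket_residues(m, "UCN", cutoff = 4.5)
  expect_equal(pk$resno, c(49L, 37L))  # sorted by min distance
  expect_equal(pk$min_distance, c(3, 4.2), tolerance = 1e-3)
  expect_equal(nrow(ligand_pocket_residues(m, "UCN", cutoff = 0.1)), 0L)
  expect_error(ligand_pocket_residues(m, "XYZ"), "UCN")
})

test_that("every reported interaction metric respects its own cutoff", {
  set.seed(131)
  ring <- benzene_atoms()
  scatter <- fixture_atoms(
    resno = 200 + 1:30, resid = sample(c("SER", "GLU", "ARG", "LYS", "THR"),
                                       30, replace = TRUE),
    elety = "CA", element = "C",
    x = runif(30, -8, 8), y = runif(30, -8, 8), z = runif(30, -8, 8))
  polar <- fixture_atoms(
    resno = 300 + 1:20, resid = sample(c("SER", "THR"), 20, replace = TRUE),
    elety = rep(c("OG", "OG1"), 10), element = "O",
    x = runif(20, -8, 8), y = runif(20, -8, 8), z = runif(20, -8, 8))
  polar$elety <- ifelse(polar$resid == "SER", "OG", "OG1")
  m <- make_model(rbind(ring, scatter, polar))
  rings <- ligand_rings(m, "BNZ")
  expect_true(all(detect_hbonds(m)$distance <= 3.5))
  expect_true(all(detect_salt_bridges(m)$distance <= 4.0))
  expect_true(all(detect_cation_pi(m, rings)$distance <= 6.0))
  ch <- detect_ch_pi(m, rings)
  expect_true(all(ch$distance <= 4.5) && all(ch$angle >= 30))
})
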