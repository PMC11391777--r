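test_that("PDB parsing drops waters and resolves alternate locations", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB AALA A   1      12.000   7.000  -4.000  0.60  0.00           C",
    "ATOM      4  CB BALA A   1      13.000   8.000  -3.000  0.40  0.00           C",
    "ATOM      5  CA  GLY A   2      14.000   6.000  -5.000  1.00  0.00           C",
    "HETATM    6  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 4L)
  expect_false(any(s$atoms$resname == "HOH"))
  # highest-occupancy CB kept
  cb <- s$atoms[s$atoms$atom == "CB", ]
  expect_equal(cb$x, 12.0)
  expect_true(all(s$atoms$radius > 0))
})

test_that("structure writing round-trips through the reader", {
  toy <- generate_toy_structure(12, "helix", seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$structure, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), 12L)
  expect_equal(back$atoms$x, toy$structure$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$resname, toy$structure$atoms$resname)
})

test_that("superposition is exact under rigid motion and symmetric", {
  set.seed(23)
  m <- matrix(stats::rnorm(30), 10, 3)
  sup0 <- superpose(m, m)
  expect_equal(sup0$rmsd, 0, tolerance = 1e-12)

  th <- pi / 2
  rot_z <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                  3, 3)
  target <- m %*% rot_z + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  sup <- superpose(m, target)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_equal(sup$fitted, target, tolerance = 1e-9,
               ignore_attr = TRUE)

  # RMSD is symmetric in mobile/target swap
  set.seed(24)
  a <- matrix(stats::rnorm(18), 6, 3)
  b <- a + matrix(stats::rnorm(18, 0, 0.4), 6, 3)
  expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd,
               tolerance = 1e-9)

  expect_error(superpose(m[1:2, ], m[1:2, ]), ">= 3 pairs")
  expect_error(superpose(m[1:4, ], m[1:5, ]), "unequal")
  line <- cbind(1:5, 0, 0)
  expect_warning(superpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches a rotation-grid oracle on 4-point toys", {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  target <- pts
  target[2, ] <- target[2, ] + c(1, 0, 0)  # one point displaced 1 A
  sup <- superpose(pts, target)
  oracle <- rotation_grid_rmsd(pts, target)
  expect_equal(sup$rmsd, oracle, tolerance = 1e-3)

  set.seed(25)
  pts2 <- matrix(stats::rnorm(12), 4, 3)
  target2 <- pts2 + matrix(stats::rnorm(12, 0, 0.3), 4, 3)
  expect_equal(superpose(pts2, target2)$rmsd,
               rotation_grid_rmsd(pts2, target2), tolerance = 1e-3)
})

test_that("sequence-paired superposition agrees with an independent
           implementation", {
  toy <- generate_toy_structure(25, "helix", seed = 6)
  xyz <- as.matrix(toy$structure$atoms[, c("x", "y", "z")])
  set.seed(26)
  th <- 1.1
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)),
                3, 3)
  moved <- xyz %*% rot + matrix(c(5, 5, 5), 25, 3, byrow = TRUE) +
    matrix(stats::rnorm(75, 0, 0.2), 25, 3)
  target <- toy$structure
  target$atoms[, c("x", "y", "z")] <- moved
  sup <- superpose_structures(toy$structure, target)
  expect_equal(nrow(sup$pairs), 25L)
  # independent route: bio3d's least-squares fit on the same pairing
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(moved)),
                   mobile = as.vector(t(xyz))))
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(ref, ncol = 3, byrow = TRUE) - moved)^2)))
  expect_equal(sup$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("the 2 A threshold separates aligned from unaligned pairs", {
  d <- c(0.4, 1.9, 2.0, 3.0)
  out <- unaligned_residues(d, ids = c("r1", "r2", "r3", "r4"))
  expect_equal(out$aligned, c("r1", "r2", "r3"))  # exactly 2.0 aligned
  expect_equal(out$unaligned$id, "r4")
  expect_equal(out$unaligned$distance, 3.0)
  expect_equal(nrow(unaligned_residues(c(0.1, 0.5))$unaligned), 0L)
})

test_that("Shrake-Rupley matches analytic sphere areas", {
  one <- structure_model(make_toy_structure_df(matrix(0, 1, 3)))
  sasa <- shrake_rupley_sasa(one)
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(sasa$sasa, analytic, tolerance = 0.01)

  # no occlusion at 100 A separation
  two_far <- structure_model(
    make_toy_structure_df(rbind(c(0, 0, 0), c(100, 0, 0))))
  expect_equal(sum(shrake_rupley_sasa(two_far)$sasa), 2 * analytic,
               tolerance = 0.01)

  # overlapping equal spheres: spherical-cap closed form within 2%
  for (gap in c(2.0, 3.5, 5.0)) {
    two <- structure_model(
      make_toy_structure_df(rbind(c(0, 0, 0), c(gap, 0, 0))))
    got <- sum(shrake_rupley_sasa(two)$sasa)
    expect_equal(got, two_sphere_area(1.7 + 1.4, gap), tolerance = 0.02)
  }
})

test_that("SASA is invariant under rigid motion and monotone in probe", {
  toy <- generate_toy_structure(15, "helix", seed = 9)
  base <- shrake_rupley_sasa(toy$structure)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                3, 3)
  moved <- toy$structure
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")])
  moved$atoms[, c("x", "y", "z")] <- xyz %*% rot +
    matrix(c(10, -4, 2), 15, 3, byrow = TRUE)
  rotated <- shrake_rupley_sasa(moved)
  expect_lt(max(abs(rotated$sasa - base$sasa)) / max(base$sasa), 1e-6)

  # probe monotonicity on the two-sphere system, where the closed form
  # 2 * 2 pi r (r + d/2) is strictly increasing in r = radius + probe
  two <- structure_model(
    make_toy_structure_df(rbind(c(0, 0, 0), c(3, 0, 0))))
  areas <- vapply(c(1.0, 1.4, 2.0),
                  function(p) sum(shrake_rupley_sasa(two, probe = p)$sasa),
                  0.0)
  expect_true(all(diff(areas) > 0))

  # random-point mode agrees with the spiral lattice
  rand <- shrake_rupley_sasa(toy$structure, mode = "random",
                             n_points = 2000, seed = 4)
  expect_equal(rand$sasa, base$sasa, tolerance = 0.05)
})

test_that("surface selection and group composition follow the cutoff", {
  sasa <- data.frame(resno = 1:4, resname = c("ASP", "GLU", "LYS", "GLY"),
                     sasa = c(45, 31, 29.9, 0))
  expect_equal(surface_residues(sasa), c(1L, 2L))
  expect_equal(surface_residues(sasa, cutoff = 0), 1:4)

  atoms <- data.frame(resno = 1:3, resname = c("ASP", "GLU", "LYS"),
                      atom = "CA", element = "C",
                      x = c(0, 10, 20), y = 0, z = 0)
  s <- structure_model(atoms)
  comp <- surface_group_composition(s, 1:3)
  expect_equal(unname(comp["negative"]), 2L)
  expect_equal(unname(comp["positive"]), 1L)
  expect_equal(sum(surface_group_composition(s, integer(0))), 0L)

  # mixed 8-residue fixture checked by exhaustive table walk
  resn <- c("PHE", "SER", "LEU", "ARG", "TRP", "ASP", "HIS", "GLY")
  atoms8 <- data.frame(resno = 1:8, resname = resn, atom = "CA",
                       element = "C", x = seq(0, 70, by = 10), y = 0,
                       z = 0)
  s8 <- structure_model(atoms8)
  comp8 <- surface_group_composition(s8, 1:8)
  tab <- aa_dichotomy_table()
  one <- phoptima:::AA_THREE_TO_ONE[resn]
  for (g in names(tab)) {
    expect_equal(unname(comp8[g]), sum(one %in% tab[[g]]))
  }
  expect_error(surface_group_composition(s8, 99), "absent")
})
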