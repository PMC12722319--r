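# Unit cells, CIF round trips, symmetry expansion, density.

test_that("cell volume matches closed forms and the determinant oracle", {
  expect_equal(cell_volume(unit_cell(10, 10, 10)), 1000)

  # monoclinic reduces to a*b*c*sin(beta)
  mono <- unit_cell(14.13, 5.16, 26.47, beta = 96.67)
  expect_equal(cell_volume(mono),
               14.13 * 5.16 * 26.47 * sin(96.67 * pi / 180))

  # random triclinic cells: volume equals det of the lattice-vector matrix
  set.seed(11)
  n_ok <- 0
  while (n_ok < 100) {
    cell <- tryCatch(
      unit_cell(runif(1, 3, 30), runif(1, 3, 30), runif(1, 3, 30),
                runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120)),
      error = function(e) NULL
    )
    if (is.null(cell)) next
    expect_equal(cell_volume(cell), det(lattice_matrix(cell)),
                 tolerance = 1e-9)
    n_ok <- n_ok + 1
  }
})

test_that("degenerate cells are rejected", {
  expect_error(unit_cell(-1, 5, 5), "positive")
  expect_error(unit_cell(5, 5, 5, alpha = 0), "between 0 and 180")
  # angle triple with a negative volume discriminant (gamma > alpha + beta)
  expect_error(unit_cell(5, 5, 5, alpha = 10, beta = 10, gamma = 170),
               "discriminant")
})

test_that("parse_cif handles minimal blocks, defaults and operator loops", {
  minimal <- c(
    "data_min",
    "_cell_length_a 5.0",
    "_cell_length_b 6.0",
    "_cell_length_c 7.0",
    "loop_",
    "_space_group_symop_operation_xyz",
    "'x,y,z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "C1 0.1 0.2 0.3"
  )
  s <- parse_cif(minimal)
  expect_equal(nrow(s$sites), 1)
  expect_equal(s$sites$occupancy, 1.0)
  expect_equal(s$sites$element, "C")
  expect_equal(length(s$ops), 1)

  screw <- c(
    "data_p21",
    "_cell_length_a 5", "_cell_length_b 6", "_cell_length_c 7",
    "_cell_angle_beta 95",
    "loop_",
    "_space_group_symop_operation_xyz",
    "'x,y,z'",
    "'-x,y+1/2,-z'",
    "loop_",
    "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "N1 N 0.1 0.2 0.3"
  )
  s2 <- parse_cif(screw)
  expect_equal(length(s2$ops), 2)
  op2 <- s2$ops[[2]]
  expect_equal(op2$rot, matrix(c(-1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, -1L), 3, 3,
                               byrow = TRUE))
  expect_equal(op2$trans, c(0, 0.5, 0))
  # consistent with the built-in P21 operators
  p21 <- spacegroup_ops("P21")
  expect_equal(lapply(s2$ops, `[[`, "rot"), lapply(p21, `[[`, "rot"))
})

test_that("parse_cif reports missing tags and malformed operators", {
  expect_error(parse_cif(c("data_x", "_cell_length_a 5")), "_cell_length_b")
  no_atoms <- c("data_x", "_cell_length_a 5", "_cell_length_b 5",
                "_cell_length_c 5",
                "_symmetry_space_group_name_H-M 'P 1'")
  expect_error(parse_cif(no_atoms), "_atom_site_fract_x")
  expect_error(parse_symop("x,y"), "malformed")
  expect_error(parse_symop("x,y,q+1/2"), "malformed")
})

test_that("space-group symbols resolve via the built-in table", {
  expect_equal(length(spacegroup_ops("P1")), 1)
  expect_equal(length(spacegroup_ops("P 21")), 2)
  expect_equal(length(spacegroup_ops("C2")), 4)
  expect_equal(length(spacegroup_ops("P212121")), 4)
  expect_equal(spacegroup_number("P 21 21 21"), 19L)
  expect_error(spacegroup_ops("Fddd"), "not in built-in table")
})

test_that("CIF write/parse round trip preserves the structure to 1e-6", {
  s <- fixture_structure()
  path <- tempfile(fileext = ".cif")
  write_cif(s, path)
  s2 <- parse_cif(path)
  for (p in c("a", "b", "c", "alpha", "beta", "gamma")) {
    expect_equal(s2$cell[[p]], s$cell[[p]], tolerance = 1e-6)
  }
  expect_equal(length(s2$ops), length(s$ops))
  expect_equal(lapply(s2$ops, `[[`, "rot"), lapply(s$ops, `[[`, "rot"))
  expect_equal(lapply(s2$ops, `[[`, "trans"), lapply(s$ops, `[[`, "trans"),
               tolerance = 1e-9)
  expect_equal(as.matrix(s2$sites[, c("x", "y", "z")]),
               as.matrix(s$sites[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(s2$sites$occupancy, s$sites$occupancy, tolerance = 1e-6)
  expect_equal(s2$sites$disorder_group, s$sites$disorder_group)
  expect_equal(s2$z_formula, s$z_formula)
})

test_that("disorder-group occupancies must sum to one", {
  cell <- unit_cell(10, 10, 10)
  bad <- data.frame(label = c("O1A", "O1B"), element = "O",
                    x = c(0.1, 0.4), y = 0.2, z = 0.3,
                    occupancy = c(0.58, 0.58), disorder_group = "1")
  expect_error(crystal_structure(cell, "P1", bad), "sum")
})

test_that("crystal density follows Z M / (N_A V)", {
  # constants cancel: Z = 1, M = 100 g/mol, V = 166.054 A^3 -> exactly 1 g/cm^3
  a <- 166.054^(1 / 3)
  s <- crystal_structure(unit_cell(a, a, a), "P1",
                         data.frame(label = "C1", element = "C",
                                    x = 0, y = 0, z = 0))
  expect_equal(crystal_density(s, molar_mass = 100),
               100 / (6.02214076e23 * 166.054e-24), tolerance = 1e-12)
  expect_equal(crystal_density(s, molar_mass = 100), 1.0, tolerance = 1e-4)

  # doubling Z at fixed cell doubles the density
  s2 <- crystal_structure(s$cell, "P1", s$sites, z_formula = 2)
  expect_equal(crystal_density(s2, 100), 2 * crystal_density(s, 100))

  # ritonavir form 4: Z = 2, C37H48N6O5S2 in the published monoclinic cell
  m <- molar_mass_from_formula("C37H48N6O5S2")
  expect_equal(m, 720.95, tolerance = 1e-4)
  cell4 <- unit_cell(14.13, 5.16, 26.47, beta = 96.67)
  f4 <- crystal_structure(cell4, "P21",
                          data.frame(label = "C1", element = "C",
                                     x = 0.1, y = 0.1, z = 0.1),
                          z_formula = 2, formula = "C37H48N6O5S2")
  rho_hand <- 2 * m / (6.02214076e23 * cell_volume(cell4) * 1e-24)
  expect_equal(crystal_density(f4), rho_hand, tolerance = 1e-12)
  expect_equal(crystal_density(f4), 1.249, tolerance = 1e-3)
})

test_that("symmetry expansion matches orbit sizes and the brute-force oracle", {
  # general position in P21: full orbit of 2
  s <- crystal_structure(unit_cell(8, 9, 10, beta = 95), "P21",
                         data.frame(label = "C1", element = "C",
                                    x = 0.13, y = 0.27, z = 0.41))
  expect_equal(nrow(expand_symmetry(s)), 2)

  # special position on the C2 axis (x = 0, z = 0): orbit halves to 2
  sp <- crystal_structure(unit_cell(9, 9, 11, beta = 102), "C2",
                          data.frame(label = "O1", element = "O",
                                     x = 0, y = 0.3, z = 0))
  expect_equal(nrow(expand_symmetry(sp)), 2)

  # 3-atom asymmetric unit in P212121: 3 x 4 = 12 sites
  s3 <- crystal_structure(unit_cell(10, 11, 12), "P212121",
                          data.frame(label = c("C1", "N1", "O1"),
                                     element = c("C", "N", "O"),
                                     x = c(0.11, 0.31, 0.57),
                                     y = c(0.23, 0.47, 0.71),
                                     z = c(0.37, 0.59, 0.83)))
  expect_equal(nrow(expand_symmetry(s3)), 12)
  expect_equal(nrow(expand_symmetry(s3)), oracle_expand_count(s3))

  # randomized structures agree with the brute-force count
  for (seed in 1:20) {
    st <- make_toy_structure(seed, c("P21", "P1", "P212121")[1 + seed %% 3],
                             n_atoms = 5)
    expanded <- expand_symmetry(st)
    expect_equal(nrow(expanded), oracle_expand_count(st))
    expect_true(all(expanded$x >= 0 & expanded$x < 1))
    expect_true(all(expanded$y >= 0 & expanded$y < 1))
    expect_true(all(expanded$z >= 0 & expanded$z < 1))
  }
})
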