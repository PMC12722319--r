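# Diffraction geometry, structure factors, pattern simulation.

test_that("d-spacings follow the reciprocal metric tensor", {
  cubic <- unit_cell(10, 10, 10)
  expect_equal(d_spacing(cubic, c(1, 0, 0)), 10)
  expect_equal(d_spacing(cubic, c(1, 1, 0)), 10 / sqrt(2))

  # monoclinic closed form for (0,0,l): d = c sin(beta) / l
  mono <- unit_cell(14.13, 5.16, 26.47, beta = 96.67)
  expect_equal(d_spacing(mono, c(0, 0, 1)), 26.47 * sin(96.67 * pi / 180),
               tolerance = 1e-9)
  expect_equal(d_spacing(mono, c(0, 0, 1)), 26.29, tolerance = 1e-3)

  # Friedel symmetry on a random triclinic cell
  tric <- unit_cell(7.3, 9.1, 11.7, 83, 99, 104)
  for (hkl in list(c(1, 2, 3), c(-2, 1, 4), c(3, 0, -1))) {
    expect_equal(d_spacing(tric, hkl), d_spacing(tric, -hkl))
  }
  expect_error(d_spacing(cubic, c(0, 0, 0)), "no d-spacing")
})

test_that("Bragg angles follow 2 asin(lambda / 2d) and drop unobservables", {
  expect_equal(bragg_two_theta(1.5406, 1.5406), 60)
  expect_equal(bragg_two_theta(26.29, 1.5406),
               2 * asin(1.5406 / (2 * 26.29)) * 180 / pi)
  expect_equal(bragg_two_theta(26.29, 1.5406), 3.359, tolerance = 2e-3)
  expect_true(is.na(bragg_two_theta(0.7, 1.5406))) # lambda/2d > 1
})

test_that("structure factors match trivial closed forms", {
  cell <- unit_cell(5, 5, 5)
  one <- data.frame(label = "C1", element = "C", x = 0, y = 0, z = 0,
                    occupancy = 1, disorder_group = NA)
  # constant form factor = atomic number (C: 6) -> |F|^2 = 36 for any hkl
  for (hkl in list(c(1, 0, 0), c(2, 1, 3), c(-1, 4, 2))) {
    expect_equal(structure_factor_sq(one, hkl, cell, form_factor = "constant"),
                 36, tolerance = 1e-12)
  }
  # body-centered pair: h+k+l odd extinguishes
  bc <- data.frame(label = c("C1", "C2"), element = "C",
                   x = c(0, 0.5), y = c(0, 0.5), z = c(0, 0.5),
                   occupancy = 1, disorder_group = NA)
  f2_odd <- structure_factor_sq(bc, c(1, 0, 0), cell, form_factor = "constant")
  f2_even <- structure_factor_sq(bc, c(1, 1, 0), cell, form_factor = "constant")
  expect_lt(f2_odd, 1e-25)
  expect_equal(f2_even, 4 * 36, tolerance = 1e-12)
  expect_error(
    structure_factor_sq(data.frame(label = "Xx1", element = "Xx", x = 0, y = 0,
                                   z = 0, occupancy = 1, disorder_group = NA),
                        c(1, 0, 0), cell),
    "Xx"
  )
})

test_that("structure factors agree with the complex-sum oracle to 1e-10", {
  set.seed(31)
  for (rep in 1:5) {
    cell <- unit_cell(runif(1, 5, 12), runif(1, 5, 12), runif(1, 5, 12),
                      runif(1, 80, 100), runif(1, 80, 100), runif(1, 80, 100))
    sites <- data.frame(
      label = paste0("A", 1:6),
      element = sample(c("H", "C", "N", "O", "S"), 6, replace = TRUE),
      x = runif(6), y = runif(6), z = runif(6),
      occupancy = runif(6, 0.4, 1), disorder_group = NA,
      stringsAsFactors = FALSE
    )
    for (k in 1:5) {
      hkl <- sample(-4:4, 3, replace = TRUE)
      if (all(hkl == 0)) hkl <- c(1, 0, 0)
      got <- structure_factor_sq(sites, hkl, cell)
      want <- oracle_f2(sites, hkl, cell)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("screw-axis systematic absences are exact", {
  # P21: (0,k,0) with k odd carries zero intensity
  s21 <- make_toy_structure(101, "P21", n_atoms = 6)
  refl <- reflection_list(s21, two_theta_range = c(3, 40))
  expect_gt(nrow(refl), 10)
  odd_0k0 <- refl$h == 0 & refl$l == 0 & refl$k %% 2 != 0
  if (any(odd_0k0)) {
    expect_lt(max(refl$intensity[odd_0k0]), 1e-9 * max(refl$intensity))
  }
  even_0k0 <- refl$h == 0 & refl$l == 0 & refl$k %% 2 == 0
  expect_true(any(even_0k0)) # the allowed class is present

  # P212121: h00 (h odd), 0k0 (k odd), 00l (l odd) all extinguished
  s19 <- make_toy_structure(202, "P212121", n_atoms = 6)
  r19 <- reflection_list(s19, two_theta_range = c(3, 40))
  axial_odd <- (r19$k == 0 & r19$l == 0 & r19$h %% 2 != 0) |
    (r19$h == 0 & r19$l == 0 & r19$k %% 2 != 0) |
    (r19$h == 0 & r19$k == 0 & r19$l %% 2 != 0)
  if (any(axial_odd)) {
    expect_lt(max(r19$intensity[axial_odd]), 1e-9 * max(r19$intensity))
  }
})

test_that("pattern peaks land at the Bragg closed form", {
  # single atom, P1, cubic 5 A: lowest-angle reflection at d = 5
  s <- crystal_structure(unit_cell(5, 5, 5), "P1",
                         data.frame(label = "C1", element = "C",
                                    x = 0.2, y = 0.4, z = 0.6))
  pat <- simulate_pattern(s, two_theta_range = c(3, 40))
  refl <- attr(pat, "reflections")
  tt_expect <- 2 * asin(1.5406 / 10) * 180 / pi
  expect_equal(min(refl$two_theta), tt_expect, tolerance = 1e-6)
  # the profile maximum near that angle
  near <- abs(pat$two_theta - tt_expect) < 0.5
  peak_at <- pat$two_theta[near][which.max(pat$intensity[near])]
  expect_equal(peak_at, tt_expect, tolerance = 0.02 + 1e-9)
})

test_that("intensities scale as occupancy squared before normalization", {
  cell <- unit_cell(8, 9, 10, beta = 97)
  half <- data.frame(label = c("C1", "N1"), element = c("C", "N"),
                     x = c(0.15, 0.62), y = c(0.33, 0.71),
                     z = c(0.48, 0.09), occupancy = 0.5, disorder_group = NA)
  full <- transform(half, occupancy = 1.0)
  r_half <- reflection_list(crystal_structure(cell, "P21", half))
  r_full <- reflection_list(crystal_structure(cell, "P21", full))
  expect_equal(r_full$intensity, 4 * r_half$intensity, tolerance = 1e-12)
})

test_that("simulated patterns are finite, non-negative and label-invariant", {
  sgs <- c("P21", "P1", "P212121")
  for (seed in 1:50) {
    st <- make_toy_structure(seed, sgs[1 + seed %% 3], n_atoms = 4)
    pat <- simulate_pattern(st)
    expect_true(all(is.finite(pat$intensity)))
    expect_true(all(pat$intensity >= 0))
  }

  # shuffling / relabeling atom sites leaves the pattern unchanged
  st <- make_toy_structure(77, "P21", n_atoms = 8)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  shuffled <- st
  shuffled$sites <- st$sites[perm, ]
  shuffled$sites$label <- paste0("Q", seq_len(8))
  p1 <- simulate_pattern(st)
  p2 <- simulate_pattern(shuffled)
  expect_equal(p1$intensity, p2$intensity, tolerance = 1e-9)
})

test_that("a structure with no observable reflection warns and returns zeros", {
  s <- crystal_structure(unit_cell(4, 4, 4), "P1",
                         data.frame(label = "C1", element = "C",
                                    x = 0, y = 0, z = 0))
  # 3..5 degrees needs d > 17.6 A; a 4 A cell has none
  expect_warning(pat <- simulate_pattern(s, two_theta_range = c(3, 5)),
                 "no observable reflection")
  expect_true(all(pat$intensity == 0))
})

test_that("xy pattern files round trip", {
  st <- make_toy_structure(5, "P21", n_atoms = 4)
  pat <- simulate_pattern(st)
  path <- tempfile(fileext = ".xy")
  write_pattern_xy(pat, path)
  back <- read_pattern_xy(path)
  expect_equal(back$wavelength, pat$wavelength, tolerance = 1e-6)
  expect_equal(back$two_theta, pat$two_theta, tolerance = 1e-6)
  expect_equal(back$intensity, pat$intensity, tolerance = 1e-6)
})
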