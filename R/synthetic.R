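# Synthetic fixtures: toy molecular crystals, candidate energy landscapes
# with ground truth, noisy powder patterns, and disorder ensembles. Every
# generator is a pure function of (seed, parameters); a single root seed
# fans out to per-fixture substreams via a counter so adding a fixture never
# perturbs existing ones.

#' Derive a substream seed from a root seed and a counter
#'
#' @param seed root seed (integer).
#' @param counter non-negative integer fixture index.
#' @return integer seed below 2^31.
#' @export
substream_seed <- function(seed, counter = 0L) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  as.integer(((s * 69069) + as.numeric(counter) * 9973) %% 2147483647)
}

#' Generate a toy molecular crystal
#'
#' Random cell (edges 4-30 Angstrom, angles 80-120 degrees, constrained to
#' the crystal system of the space group), random elements from C, N, O, S
#' on random general positions, full occupancy.
#'
#' @param seed integer seed (determinism: same seed, same structure).
#' @param spacegroup one of `"P1"`, `"P21"`, `"P212121"`.
#' @param n_atoms asymmetric-unit size, 1..20.
#' @return a [crystal_structure].
#' @export
make_toy_structure <- function(seed, spacegroup = c("P21", "P1", "P212121"),
                               n_atoms = 8) {
  spacegroup <- match.arg(spacegroup)
  stopifnot(n_atoms >= 1, n_atoms <= 20)
  set.seed(seed)
  edges <- stats::runif(3, 4, 30)
  repeat {
    angles <- switch(spacegroup,
      P1 = stats::runif(3, 80, 120),
      P21 = c(90, stats::runif(1, 80, 120), 90),
      P212121 = c(90, 90, 90)
    )
    cell <- tryCatch(
      unit_cell(edges[1], edges[2], edges[3], angles[1], angles[2], angles[3]),
      error = function(e) NULL
    )
    if (!is.null(cell)) break
  }
  elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
  counts <- stats::ave(seq_along(elements), elements, FUN = seq_along)
  sites <- data.frame(
    label = paste0(elements, counts), element = elements,
    x = stats::runif(n_atoms), y = stats::runif(n_atoms),
    z = stats::runif(n_atoms), occupancy = 1,
    disorder_group = NA_character_, stringsAsFactors = FALSE
  )
  crystal_structure(cell, spacegroup = spacegroup, sites = sites)
}

#' Generate a candidate energy landscape with ground truth
#'
#' True relative free energies follow an exponential-spacing model (gaps
#' above the global minimum drawn Exp(1/`spacing_scale`)), emulating the
#' dense-above-minimum shape of predicted-polymorph landscapes. Each
#' candidate has a true vibrational term `fvib ~ N(fvib_mean, fvib_sd)`; the
#' observed lattice energy is `F_true - fvib + N(0, noise_sigma)` so each
#' observed total free energy carries exactly `noise_sigma` of Gaussian
#' error, and the `n_explicit_fvib` most stable candidates report their fvib
#' explicitly (the remainder get the uniform-shift treatment downstream).
#'
#' @param seed integer seed.
#' @param n_candidates number of candidates (>= 2).
#' @param spacing_scale mean true gap between consecutive candidates, kJ/mol
#'   (default 2).
#' @param n_explicit_fvib how many (most stable) candidates carry explicit
#'   fvib (>= 2).
#' @param noise_sigma sd of the Gaussian energy noise, kJ/mol.
#' @param fvib_mean,fvib_sd distribution of the true vibrational terms,
#'   kJ/mol. With `fvib_sd = 0` and `noise_sigma = 0` the assembled landscape
#'   reproduces the true ranking exactly.
#' @param gaps optional explicit true gaps (length `n_candidates - 1`,
#'   kJ/mol) overriding the exponential draw -- used to pin a landscape to a
#'   known configuration, e.g. a single 1.62 kJ/mol gap.
#' @param with_structures also generate a toy structure per candidate (for
#'   densities and pattern matching).
#' @return list: `entries` (data.frame id, spacegroup, elatt, fvib, density),
#'   `structures` (named list or NULL), `truth` (list with seed, parameters,
#'   true_free_energies, true_fvib).
#' @export
make_candidate_landscape <- function(seed, n_candidates = 20,
                                     spacing_scale = 2, n_explicit_fvib = 5,
                                     noise_sigma = 0, fvib_mean = -2,
                                     fvib_sd = 0.5, gaps = NULL,
                                     with_structures = TRUE) {
  stopifnot(n_candidates >= 2, n_explicit_fvib >= 2,
            n_explicit_fvib <= n_candidates, spacing_scale >= 0,
            noise_sigma >= 0, fvib_sd >= 0)
  set.seed(substream_seed(seed, 0L))
  if (is.null(gaps)) {
    gaps <- stats::rexp(n_candidates - 1, rate = 1 / max(spacing_scale, 1e-12))
  } else {
    gaps <- rep_len(as.numeric(gaps), n_candidates - 1)
  }
  f_true <- c(0, cumsum(gaps))
  fvib <- fvib_mean + fvib_sd * stats::rnorm(n_candidates)
  elatt_obs <- (f_true - fvib) + noise_sigma * stats::rnorm(n_candidates)
  ids <- sprintf("cand_%02d", seq_len(n_candidates))
  explicit <- seq_len(n_candidates) <= n_explicit_fvib
  structures <- NULL
  sg_pool <- c("P21", "P1", "P212121")
  sg <- sample(sg_pool, n_candidates, replace = TRUE)
  density <- rep(NA_real_, n_candidates)
  if (with_structures) {
    structures <- lapply(seq_len(n_candidates), function(i) {
      make_toy_structure(substream_seed(seed, i), spacegroup = sg[i])
    })
    names(structures) <- ids
    density <- vapply(structures, crystal_density, numeric(1))
  }
  entries <- data.frame(
    id = ids, spacegroup = sg, elatt = elatt_obs,
    fvib = ifelse(explicit, fvib, NA_real_), density = density,
    stringsAsFactors = FALSE
  )
  truth <- list(seed = seed, n_candidates = n_candidates,
                spacing_scale = spacing_scale,
                n_explicit_fvib = n_explicit_fvib, noise_sigma = noise_sigma,
                fvib_mean = fvib_mean, fvib_sd = fvib_sd,
                true_free_energies = f_true, true_fvib = fvib,
                true_order = ids)
  list(entries = entries, structures = structures, truth = truth)
}

#' Generate a noisy "experimental" powder pattern
#'
#' Simulates the structure's pattern, shifts it by a zero-point error, adds a
#' polynomial background, applies multiplicative Gaussian noise and clips at
#' zero -- emulating a digitized laboratory pattern.
#'
#' @param structure a [crystal_structure].
#' @param seed integer seed for the noise.
#' @param noise_level sd of the multiplicative noise (default 0.05).
#' @param background_coeffs polynomial coefficients (intensity units,
#'   ascending powers of 2-theta) on the normalized 0-100 intensity scale;
#'   default a gentle quadratic amorphous hump.
#' @param zero_shift zero-point error in degrees 2-theta (default 0.02).
#' @param pattern_params list of arguments for [simulate_pattern()].
#' @return a [powder_pattern].
#' @export
make_noisy_pattern <- function(structure, seed, noise_level = 0.05,
                               background_coeffs = c(15, -0.5, 0.006),
                               zero_shift = 0.02, pattern_params = list()) {
  clean <- do.call(simulate_pattern, c(list(structure), pattern_params))
  tt <- clean$two_theta
  # shifting the pattern by +zero_shift: evaluate the clean curve at tt - shift
  y <- stats::approx(tt, clean$intensity, xout = tt - zero_shift, rule = 2)$y
  bg <- numeric(length(tt))
  for (k in seq_along(background_coeffs)) {
    bg <- bg + background_coeffs[k] * tt^(k - 1)
  }
  set.seed(seed)
  y <- (y + bg) * (1 + noise_level * stats::rnorm(length(y)))
  powder_pattern(tt, pmax(y, 0), clean$wavelength)
}

#' Generate an ensemble of independent disorder sites
#'
#' Each site gets 2-3 configurations; the ground configuration is at 0 and
#' the others have gaps drawn uniformly in \[0, `gap_scale`\] kJ/mol, all with
#' degeneracy 1.
#'
#' @param seed integer seed.
#' @param n_sites number of sites (>= 1).
#' @param gap_scale upper bound of the configuration gaps, kJ/mol.
#' @return list of [disorder_site].
#' @export
make_disorder_ensemble <- function(seed, n_sites = 1, gap_scale = 1) {
  stopifnot(n_sites >= 1, gap_scale >= 0)
  set.seed(seed)
  lapply(seq_len(n_sites), function(i) {
    n_conf <- sample(2:3, 1)
    disorder_site(sprintf("site_%02d", i),
                  c(0, stats::runif(n_conf - 1, 0, gap_scale)))
  })
}

#' Write a complete synthetic study directory
#'
#' End-to-end fixture set: candidate CIFs, the energy table, a noisy
#' "experimental" pattern generated from one designated candidate, and the
#' ground truth as JSON.
#'
#' @param seed integer root seed.
#' @param dir output directory (created if needed).
#' @param n_candidates,n_explicit_fvib,spacing_scale,noise_sigma,fvib_sd see
#'   [make_candidate_landscape()].
#' @param target_index which candidate (in true stability order) generates
#'   the experimental pattern; default 1, the global minimum -- the
#'   unfound-polymorph scenario uses a known form instead.
#' @param pattern_noise,zero_shift,background_coeffs see
#'   [make_noisy_pattern()].
#' @return invisibly, a list with `entries`, `structures`, `truth` and the
#'   file paths written.
#' @export
make_synthetic_study <- function(seed, dir, n_candidates = 20,
                                 n_explicit_fvib = 5, spacing_scale = 2,
                                 noise_sigma = 0.5, fvib_sd = 0.5,
                                 target_index = 2, pattern_noise = 0.05,
                                 zero_shift = 0.02,
                                 background_coeffs = c(15, -0.5, 0.006)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  land <- make_candidate_landscape(seed, n_candidates = n_candidates,
                                   spacing_scale = spacing_scale,
                                   n_explicit_fvib = n_explicit_fvib,
                                   noise_sigma = noise_sigma,
                                   fvib_sd = fvib_sd, with_structures = TRUE)
  cif_dir <- file.path(dir, "cif")
  dir.create(cif_dir, showWarnings = FALSE)
  cif_paths <- character(0)
  for (id in names(land$structures)) {
    p <- file.path(cif_dir, paste0(id, ".cif"))
    write_cif(land$structures[[id]], p)
    cif_paths <- c(cif_paths, p)
  }
  target_id <- land$entries$id[target_index]
  pat <- make_noisy_pattern(land$structures[[target_id]],
                            seed = substream_seed(seed, 1000L),
                            noise_level = pattern_noise,
                            background_coeffs = background_coeffs,
                            zero_shift = zero_shift)
  xy_path <- file.path(dir, "experimental.xy")
  write_pattern_xy(pat, xy_path)
  energies <- land$entries
  names(energies)[names(energies) == "elatt"] <- "elatt_kjmol"
  names(energies)[names(energies) == "fvib"] <- "fvib_kjmol"
  energy_path <- file.path(dir, "energies.csv")
  utils::write.csv(energies, energy_path, row.names = FALSE, na = "")
  truth <- c(land$truth, list(true_target_id = target_id,
                              pattern_noise = pattern_noise,
                              zero_shift = zero_shift,
                              background_coeffs = background_coeffs))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(entries = land$entries, structures = land$structures,
                 truth = truth,
                 paths = list(cif = cif_paths, pattern = xy_path,
                              energies = energy_path, truth = truth_path)))
}
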