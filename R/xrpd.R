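# Kinematic powder X-ray diffraction simulation: d-spacings, Bragg angles,
# structure factors with Cromer-Mann form factors, pseudo-Voigt profiles.

#' d-spacing of a reflection
#'
#' \eqn{1/d^2 = h^T G^* h} with \eqn{G^*} the reciprocal metric tensor of the
#' cell.
#'
#' @param cell a [unit_cell].
#' @param hkl integer triple (vector of length 3) or an n x 3 matrix.
#' @return d in Angstrom (vector for matrix input).
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, nrow = 1)
  if (ncol(h) != 3) stop("hkl must have 3 components")
  if (any(rowSums(h != 0) == 0)) stop("hkl = (0,0,0) has no d-spacing")
  lm <- lattice_matrix(cell)
  gstar <- solve(lm %*% t(lm)) # reciprocal metric tensor
  invd2 <- rowSums((h %*% gstar) * h)
  d <- 1 / sqrt(invd2)
  if (!is.matrix(hkl)) d[1] else d
}

#' Bragg angle 2-theta for a d-spacing
#'
#' \eqn{2\theta = 2\arcsin(\lambda / 2d)} in degrees. Reflections outside the
#' sphere (\eqn{\lambda/2d > 1}) are unobservable and return `NA` rather than
#' erroring, so callers can drop them.
#'
#' @param d d-spacing in Angstrom (> 0), vectorized.
#' @param wavelength radiation wavelength in Angstrom (> 0).
#' @return 2-theta in degrees, `NA` where unobservable.
#' @export
bragg_two_theta <- function(d, wavelength) {
  stopifnot(all(d > 0), wavelength > 0)
  s <- wavelength / (2 * d)
  out <- rep(NA_real_, length(s))
  ok <- s <= 1
  out[ok] <- 2 * asin(s[ok]) * 180 / pi
  out
}

# Atomic scattering factor f(s) for one element at s = sin(theta)/lambda.
# Cromer-Mann 4-Gaussian where tabulated, constant atomic number otherwise.
.form_factor <- function(element, s, model = c("cromer-mann", "constant")) {
  model <- match.arg(model)
  if (model == "cromer-mann" && element %in% names(.CROMER_MANN)) {
    cm <- .CROMER_MANN[[element]]
    f <- rep(cm$c, length(s))
    for (k in 1:4) f <- f + cm$a[k] * exp(-cm$b[k] * s^2)
    return(f)
  }
  if (!element %in% names(.ATOMIC_NUMBER)) {
    stop("no scattering factor for element: ", element)
  }
  rep(as.numeric(.ATOMIC_NUMBER[[element]]), length(s))
}

#' Squared structure factor |F(hkl)|^2
#'
#' Kinematic sum over the expanded unit-cell contents:
#' \eqn{F = \sum_j o_j f_j(s) e^{-B_j s^2} e^{2\pi i\, hkl \cdot x_j}},
#' with \eqn{s = \sin\theta/\lambda = 1/(2d)}.
#'
#' @param expanded_sites data.frame from [expand_symmetry()] (columns element,
#'   x, y, z, occupancy).
#' @param hkl integer triple or n x 3 matrix.
#' @param cell a [unit_cell] (needed for s).
#' @param form_factor `"cromer-mann"` (4-term table for H, C, N, O, S, with
#'   constant-Z fallback for other elements) or `"constant"`.
#' @param b_iso global isotropic displacement parameter in Angstrom^2
#'   (default 0, i.e. no Debye-Waller damping).
#' @return |F|^2 (vector for matrix input), in electrons^2.
#' @export
structure_factor_sq <- function(expanded_sites, hkl, cell,
                                form_factor = c("cromer-mann", "constant"),
                                b_iso = 0) {
  form_factor <- match.arg(form_factor)
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, nrow = 1)
  d <- d_spacing(cell, h)
  s <- 1 / (2 * d)
  xyz <- as.matrix(expanded_sites[, c("x", "y", "z")])
  occ <- expanded_sites$occupancy
  elems <- expanded_sites$element
  # per-hkl form factor for each distinct element, with optional B damping
  f_by_elem <- lapply(unique(elems), function(el) {
    .form_factor(el, s, form_factor) * exp(-b_iso * s^2)
  })
  names(f_by_elem) <- unique(elems)
  fmat <- do.call(cbind, f_by_elem)[, match(elems, unique(elems)), drop = FALSE]
  phase <- 2 * pi * (h %*% t(xyz))
  occ_m <- matrix(occ, nrow = nrow(h), ncol = length(occ), byrow = TRUE)
  f_re <- rowSums(fmat * occ_m * cos(phase))
  f_im <- rowSums(fmat * occ_m * sin(phase))
  out <- f_re^2 + f_im^2
  if (!is.matrix(hkl)) out[1] else out
}

#' Reflection list for a structure
#'
#' Enumerates all hkl inside the observable d-spacing sphere of the 2-theta
#' range, computes |F|^2, and merges reflections coincident in 2-theta
#' (tolerance 1e-4 degrees) accumulating multiplicity; intensity is
#' multiplicity x LP x |F|^2 with the Lorentz-polarization factor
#' \eqn{LP = (1+\cos^2 2\theta)/(\sin^2\theta \cos\theta)}.
#'
#' @inheritParams structure_factor_sq
#' @param structure a [crystal_structure].
#' @param wavelength Angstrom (default Cu K-alpha1, 1.5406).
#' @param two_theta_range length-2 numeric, degrees.
#' @return data.frame: h, k, l (representative), d, two_theta, multiplicity,
#'   f2 (mean |F|^2 over the merged group), intensity.
#' @export
reflection_list <- function(structure, wavelength = 1.5406,
                            two_theta_range = c(3, 40),
                            form_factor = "cromer-mann", b_iso = 0) {
  stopifnot(inherits(structure, "crystal_structure"),
            length(two_theta_range) == 2,
            two_theta_range[1] > 0, two_theta_range[2] <= 180)
  cell <- structure$cell
  dmin <- wavelength / (2 * sin(two_theta_range[2] / 2 * pi / 180))
  dmax <- wavelength / (2 * sin(two_theta_range[1] / 2 * pi / 180))
  # |h_i| <= |a_i| / d  bounds the index range exactly
  lm <- lattice_matrix(cell)
  hmax <- floor(sqrt(rowSums(lm^2)) / dmin)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  d <- d_spacing(cell, grid)
  keep <- d >= dmin & d <= dmax
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  if (!nrow(grid)) {
    return(data.frame(h = integer(0), k = integer(0), l = integer(0),
                      d = numeric(0), two_theta = numeric(0),
                      multiplicity = integer(0), f2 = numeric(0),
                      intensity = numeric(0)))
  }
  tt <- bragg_two_theta(d, wavelength)
  exp_sites <- expand_symmetry(structure)
  f2 <- structure_factor_sq(exp_sites, grid, cell,
                            form_factor = form_factor, b_iso = b_iso)
  # merge by 2-theta coincidence (symmetry equivalents land on one angle)
  key <- round(tt / 1e-4)
  ord <- order(key, -abs(grid[, 1]), -abs(grid[, 2]), -abs(grid[, 3]))
  grid <- grid[ord, , drop = FALSE]
  d <- d[ord]; tt <- tt[ord]; f2 <- f2[ord]; key <- key[ord]
  grp <- cumsum(!duplicated(key))
  mult <- as.integer(tapply(grp, grp, length))
  f2_sum <- as.numeric(tapply(f2, grp, sum))
  first <- !duplicated(grp)
  theta <- tt[first] / 2 * pi / 180
  lp <- (1 + cos(2 * theta)^2) / (sin(theta)^2 * cos(theta))
  data.frame(
    h = grid[first, 1], k = grid[first, 2], l = grid[first, 3],
    d = d[first], two_theta = tt[first], multiplicity = mult,
    f2 = f2_sum / mult,
    intensity = lp * f2_sum,
    row.names = NULL
  )
}

#' Construct a powder pattern object
#'
#' @param two_theta strictly increasing grid, degrees.
#' @param intensity non-negative intensities, same length.
#' @param wavelength Angstrom.
#' @return object of class `powder_pattern`.
#' @export
powder_pattern <- function(two_theta, intensity, wavelength = 1.5406) {
  stopifnot(length(two_theta) == length(intensity), length(two_theta) >= 1)
  if (any(diff(two_theta) <= 0)) stop("two_theta grid must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative")
  }
  structure(list(wavelength = wavelength, two_theta = two_theta,
                 intensity = intensity), class = "powder_pattern")
}

#' @export
print.powder_pattern <- function(x, ...) {
  cat(sprintf("<powder_pattern> lambda=%.4f A, %d points, 2theta %.2f..%.2f deg, max I %.3g\n",
              x$wavelength, length(x$two_theta), min(x$two_theta),
              max(x$two_theta), max(x$intensity)))
  invisible(x)
}

#' Simulate a powder diffraction pattern
#'
#' Peaks from [reflection_list()] are convolved with a pseudo-Voigt profile
#' (Gaussian/Lorentzian mixing `eta`, common `fwhm`) and the pattern maximum
#' is normalized to 100. A structure with no observable reflection in range
#' yields a flat zero pattern with a warning.
#'
#' @inheritParams reflection_list
#' @param step grid step in degrees 2-theta.
#' @param fwhm full width at half maximum of the peak profile, degrees.
#' @param eta Lorentzian fraction of the pseudo-Voigt, in \[0, 1\].
#' @param window profile evaluation half-window in degrees (peak tails beyond
#'   it are truncated).
#' @return a [powder_pattern] with the reflection table in
#'   `attr(, "reflections")`.
#' @export
simulate_pattern <- function(structure, wavelength = 1.5406,
                             two_theta_range = c(3, 40), step = 0.02,
                             fwhm = 0.1, eta = 0.5,
                             form_factor = "cromer-mann", b_iso = 0,
                             window = 4) {
  stopifnot(step > 0, fwhm > 0, eta >= 0, eta <= 1,
            two_theta_range[1] > 0, two_theta_range[2] <= 90)
  refl <- reflection_list(structure, wavelength, two_theta_range,
                          form_factor = form_factor, b_iso = b_iso)
  tt <- seq(two_theta_range[1], two_theta_range[2], by = step)
  y <- numeric(length(tt))
  if (!nrow(refl) || max(refl$intensity) <= 0) {
    warning("no observable reflection in range; returning flat zero pattern")
    pat <- powder_pattern(tt, y, wavelength)
    attr(pat, "reflections") <- refl
    return(pat)
  }
  # pseudo-Voigt, unit area: eta * Lorentzian + (1 - eta) * Gaussian
  hw <- fwhm / 2
  cg <- 2 * sqrt(log(2) / pi) / fwhm
  kg <- 4 * log(2) / fwhm^2
  cl <- 2 / (pi * fwhm)
  for (i in seq_len(nrow(refl))) {
    if (refl$intensity[i] <= 0) next
    lo <- max(1L, ceiling((refl$two_theta[i] - window - tt[1]) / step) + 1L)
    hi <- min(length(tt), floor((refl$two_theta[i] + window - tt[1]) / step) + 1L)
    if (lo > hi) next
    dx <- tt[lo:hi] - refl$two_theta[i]
    prof <- eta * cl / (1 + (dx / hw)^2) + (1 - eta) * cg * exp(-kg * dx^2)
    y[lo:hi] <- y[lo:hi] + refl$intensity[i] * prof
  }
  if (max(y) > 0) y <- y / max(y) * 100
  pat <- powder_pattern(tt, y, wavelength)
  attr(pat, "reflections") <- refl
  pat
}

#' Read / write powder patterns as two-column xy text
#'
#' The dialect is two whitespace-separated columns (2-theta in degrees,
#' intensity) with an optional `# wavelength= <A>` header comment.
#'
#' @param pattern a [powder_pattern].
#' @param path file path.
#' @return `write_pattern_xy` returns the path invisibly; `read_pattern_xy`
#'   returns a [powder_pattern].
#' @export
write_pattern_xy <- function(pattern, path) {
  stopifnot(inherits(pattern, "powder_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wavelength= %.6f", pattern$wavelength), con)
  writeLines(sprintf("%.6f %.10g", pattern$two_theta, pattern$intensity), con)
  invisible(path)
}

#' @rdname write_pattern_xy
#' @export
read_pattern_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  wl <- 1.5406
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("wavelength=\\s*[0-9.eE+-]+", hdr))
  if (length(m)) wl <- as.numeric(sub("wavelength=\\s*", "", m[1]))
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  xy <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                              function(p) as.numeric(p[1:2])))
  powder_pattern(xy[, 1], pmax(xy[, 2], 0), wl)
}
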