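# Weighted cross-correlation (de Gelder-type) powder pattern similarity
# and ranking of predicted candidates against an experimental pattern.

#' Similarity scoring parameters
#'
#' @param weight_width_l triangular weight half-width in degrees 2-theta; the
#'   score tolerates peak offsets up to `l` (default 1.5, the conventional
#'   choice, which also absorbs small cell-parameter and zero-point errors).
#' @param background_degree degree of the polynomial baseline removed during
#'   preprocessing (default 2).
#' @param grid_step resampling step in degrees (default 0.02).
#' @return list of class `similarity_params`.
#' @export
similarity_params <- function(weight_width_l = 1.5, background_degree = 2,
                              grid_step = 0.02) {
  stopifnot(weight_width_l > 0, grid_step > 0,
            background_degree >= 0, background_degree == round(background_degree))
  structure(list(weight_width_l = weight_width_l,
                 background_degree = as.integer(background_degree),
                 grid_step = grid_step), class = "similarity_params")
}

# Iterative clipped-polynomial baseline: least-squares fit, clip the signal
# to the fit, refit until stable. Commutes exactly with adding a polynomial
# of the same degree, and tends to the low envelope of a peaked pattern.
.poly_baseline <- function(x, y, degree, max_iter = 50L, rtol = 1e-10) {
  if (degree >= length(y)) degree <- length(y) - 1L
  xs <- (x - mean(x)) / max(diff(range(x)) / 2, 1) # scale for conditioning
  basis <- outer(xs, 0:degree, `^`)
  ycur <- y
  fit <- rep(0, length(y))
  scale <- max(abs(y), 1e-300)
  for (it in seq_len(max_iter)) {
    coef <- qr.solve(basis, ycur)
    newfit <- as.vector(basis %*% coef)
    if (max(abs(newfit - fit)) < rtol * scale) {
      fit <- newfit
      break
    }
    fit <- newfit
    ycur <- pmin(ycur, fit)
  }
  fit
}

#' Preprocess a powder pattern for similarity scoring
#'
#' Resamples by linear interpolation onto `grid` (default: a uniform grid of
#' step `params$grid_step` spanning the pattern), removes a polynomial
#' baseline of degree `params$background_degree` (iterative clipped
#' least-squares fit, so a pattern differing only by an added polynomial of
#' that degree preprocesses identically), clips negatives to zero, and scales
#' to unit area.
#'
#' @param pattern a [powder_pattern].
#' @param params a [similarity_params].
#' @param grid optional explicit target grid in degrees; points outside the
#'   pattern's range are dropped.
#' @return preprocessed [powder_pattern] on the (possibly trimmed) grid.
#' @export
preprocess_pattern <- function(pattern, params = similarity_params(),
                               grid = NULL) {
  stopifnot(inherits(pattern, "powder_pattern"),
            inherits(params, "similarity_params"))
  if (length(pattern$two_theta) < 10) stop("pattern needs at least 10 points")
  if (is.null(grid)) {
    grid <- seq(min(pattern$two_theta), max(pattern$two_theta),
                by = params$grid_step)
  }
  grid <- grid[grid >= min(pattern$two_theta) & grid <= max(pattern$two_theta)]
  if (length(grid) < 2) {
    stop("empty overlap between pattern range and target grid")
  }
  y <- stats::approx(pattern$two_theta, pattern$intensity, xout = grid)$y
  base <- .poly_baseline(grid, y, params$background_degree)
  y <- pmax(y - base, 0)
  area <- sum(y) * mean(diff(grid))
  if (area > 0) y <- y / area
  powder_pattern(grid, y, pattern$wavelength)
}

# Weighted cross-correlation integral sum_m w(m) c_ab(m) on a uniform grid.
.wcc <- function(a, b, n_off, w) {
  total <- w[1] * sum(a * b)
  n <- length(a)
  if (n_off >= 1) {
    for (m in seq_len(n_off)) {
      if (m >= n) break
      i1 <- 1:(n - m)
      i2 <- (m + 1):n
      total <- total + w[m + 1] * (sum(a[i1] * b[i2]) + sum(a[i2] * b[i1]))
    }
  }
  total
}

#' Weighted cross-correlation similarity of two powder patterns
#'
#' The de Gelder-type score
#' \deqn{S = \frac{\int w\, c_{pq}}{\sqrt{\int w\, c_{pp} \int w\, c_{qq}}}}
#' with triangular weight \eqn{w(r) = \max(0, 1 - |r|/l)} over the shift
#' \eqn{r}, discretized as shifted dot products on the common uniform grid.
#' The score is symmetric, invariant to positive scaling of either pattern,
#' equals 1 for identical shapes, and lies in \[0, 1\] for non-negative
#' patterns.
#'
#' @param p,q preprocessed [powder_pattern]s on the same grid.
#' @param params a [similarity_params] (only `weight_width_l` is used here).
#' @return similarity score.
#' @export
cross_correlation_similarity <- function(p, q, params = similarity_params()) {
  stopifnot(inherits(p, "powder_pattern"), inherits(q, "powder_pattern"))
  if (length(p$two_theta) != length(q$two_theta) ||
      max(abs(p$two_theta - q$two_theta)) > 1e-9) {
    stop("patterns must be preprocessed to the same grid")
  }
  step <- mean(diff(p$two_theta))
  l <- params$weight_width_l
  n_off <- floor(l / step + 1e-9)
  w <- pmax(0, 1 - (0:n_off) * step / l)
  spq <- .wcc(p$intensity, q$intensity, n_off, w)
  spp <- .wcc(p$intensity, p$intensity, n_off, w)
  sqq <- .wcc(q$intensity, q$intensity, n_off, w)
  if (spp <= 0 || sqq <= 0) {
    stop("undefined similarity: all-zero pattern")
  }
  spq / sqrt(spp * sqq)
}

#' Rank candidate structures against an experimental pattern
#'
#' Simulates each candidate's pattern (candidates may also be supplied as
#' ready-made [powder_pattern]s), preprocesses both sides identically onto
#' the experimental pattern's grid, scores with
#' [cross_correlation_similarity()], and sorts by descending score (ties
#' broken by candidate id). A candidate whose simulation fails is recorded
#' with score `NA` and ranked last, with a warning.
#'
#' @param experimental a [powder_pattern].
#' @param candidates named list of [crystal_structure] or [powder_pattern]
#'   objects (names are the candidate ids).
#' @param sim_params a [similarity_params].
#' @param pattern_params list of arguments forwarded to [simulate_pattern()]
#'   (e.g. `wavelength`, `two_theta_range`, `step`, `fwhm`, `eta`).
#' @return data.frame with columns candidate_id, score, rank.
#' @export
rank_candidates <- function(experimental, candidates,
                            sim_params = similarity_params(),
                            pattern_params = list()) {
  stopifnot(inherits(experimental, "powder_pattern"), length(candidates) >= 1)
  ids <- names(candidates)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- sprintf("candidate_%03d", seq_along(candidates))
  }
  exp_pp <- preprocess_pattern(experimental, sim_params)
  grid <- exp_pp$two_theta
  scores <- vapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    tryCatch({
      pat <- if (inherits(cand, "powder_pattern")) cand
             else do.call(simulate_pattern, c(list(cand), pattern_params))
      cand_pp <- preprocess_pattern(pat, sim_params, grid = grid)
      exp_cut <- preprocess_pattern(experimental, sim_params,
                                    grid = cand_pp$two_theta)
      cross_correlation_similarity(exp_cut, cand_pp, sim_params)
    }, error = function(e) {
      warning("candidate '", ids[i], "' failed: ", conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  ord <- order(-ifelse(is.na(scores), -Inf, scores), ids)
  res <- data.frame(candidate_id = ids[ord], score = scores[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
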