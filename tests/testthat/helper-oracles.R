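# Independent oracles used across the suite. These deliberately avoid the
# package's computation paths: complex-number structure-factor sums, direct
# reciprocal-vector geometry, brute-force symmetry expansion and joint
# partition functions.

# Cromer-Mann coefficients (International Tables C), local copy for the oracle.
.orc_cm <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

# |F|^2 by direct complex summation, with s from explicit reciprocal vectors.
oracle_f2 <- function(sites, hkl, cell) {
  deg <- pi / 180
  ca <- cos(cell$alpha * deg); cb <- cos(cell$beta * deg)
  cg <- cos(cell$gamma * deg); sg <- sin(cell$gamma * deg)
  v <- cell$a * cell$b * cell$c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  av <- c(cell$a, 0, 0)
  bv <- c(cell$b * cg, cell$b * sg, 0)
  cv <- c(cell$c * cb, cell$c * (ca - cb * cg) / sg,
          v / (cell$a * cell$b * sg))
  cross <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                            u[3] * w[1] - u[1] * w[3],
                            u[1] * w[2] - u[2] * w[1])
  astar <- cross(bv, cv) / v
  bstar <- cross(cv, av) / v
  cstar <- cross(av, bv) / v
  g <- hkl[1] * astar + hkl[2] * bstar + hkl[3] * cstar
  s <- sqrt(sum(g^2)) / 2
  f_tot <- 0 + 0i
  for (j in seq_len(nrow(sites))) {
    cm <- .orc_cm[[sites$element[j]]]
    f <- cm$c + sum(cm$a * exp(-cm$b * s^2))
    phase <- 2 * pi * sum(hkl * as.numeric(sites[j, c("x", "y", "z")]))
    f_tot <- f_tot + sites$occupancy[j] * f * exp(1i * phase)
  }
  Mod(f_tot)^2
}

# Brute-force symmetry expansion count with O(n^2) minimum-image dedup.
oracle_expand_count <- function(structure, tol = 0.01) {
  total <- 0L
  for (i in seq_len(nrow(structure$sites))) {
    x0 <- as.numeric(structure$sites[i, c("x", "y", "z")])
    pos <- list()
    for (op in structure$ops) {
      p <- (as.vector(op$rot %*% x0) + op$trans) %% 1
      dup <- FALSE
      for (q in pos) {
        d <- p - q
        d <- d - round(d)
        if (sqrt(sum(d^2)) < tol) { dup <- TRUE; break }
      }
      if (!dup) pos[[length(pos) + 1L]] <- p
    }
    total <- total + length(pos)
  }
  total
}

# Joint partition function over all configuration combinations of k sites.
oracle_joint_stabilization <- function(sites, T) {
  rt <- 8.31446e-3 * T
  combos <- expand.grid(lapply(sites, function(s) seq_along(s$g)))
  z <- 0
  for (r in seq_len(nrow(combos))) {
    g_tot <- sum(vapply(seq_along(sites), function(k) {
      sites[[k]]$g[combos[r, k]]
    }, numeric(1)))
    d_tot <- prod(vapply(seq_along(sites), function(k) {
      sites[[k]]$d[combos[r, k]]
    }, numeric(1)))
    z <- z + d_tot * exp(-g_tot / rt)
  }
  g_min <- sum(vapply(sites, function(s) min(s$g), numeric(1)))
  g_min + rt * log(z) # = min(g) - (-RT ln Z)
}

# Continuous weighted cross-correlation score by fine-grid quadrature,
# independent of the package's shifted-dot-product discretization.
oracle_wcc_score <- function(x, p, q, l) {
  step <- mean(diff(x))
  corr <- function(a, b, m) {
    n <- length(a)
    if (m == 0) return(sum(a * b) * step)
    sum(a[1:(n - m)] * b[(m + 1):n]) * step
  }
  n_off <- floor(l / step)
  integ <- function(a, b) {
    tot <- corr(a, b, 0) * 1 * step
    for (m in 1:n_off) {
      w <- 1 - m * step / l
      tot <- tot + w * (corr(a, b, m) + corr(b, a, m)) * step
    }
    tot
  }
  integ(p, q) / sqrt(integ(p, p) * integ(q, q))
}

# A small 5-atom structure used by round-trip and parser tests.
fixture_structure <- function() {
  cell <- unit_cell(11.2, 7.9, 13.4, beta = 101.3)
  sites <- data.frame(
    label = c("C1", "N1", "O1A", "O1B", "C2"),
    element = c("C", "N", "O", "O", "C"),
    x = c(0.1234, 0.5678, 0.9012, 0.3456, 0.7890),
    y = c(0.2345, 0.6789, 0.0123, 0.4567, 0.8901),
    z = c(0.3456, 0.7890, 0.1234, 0.5678, 0.9012),
    occupancy = c(1, 1, 0.58, 0.42, 1),
    disorder_group = c(NA, NA, "1", "1", NA),
    stringsAsFactors = FALSE
  )
  crystal_structure(cell, spacegroup = "P21", sites = sites)
}
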