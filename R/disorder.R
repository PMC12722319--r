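# Isolated-site configurational disorder: Boltzmann occupancies and the
# free-energy stabilization each independently disordered site contributes.

#' Define an isolated disorder site
#'
#' One disordered fragment with a discrete set of configurations. Sites are
#' treated as independent: the total partition function factorizes, so
#' stabilizations add. Closely interacting disordered groups are outside this
#' model and must not be combined additively.
#'
#' @param site_id identifier.
#' @param config_free_energies per-configuration free energies in kJ/mol
#'   (only differences matter).
#' @param degeneracies positive integer degeneracy of each configuration
#'   (default 1).
#' @return object of class `disorder_site`.
#' @export
disorder_site <- function(site_id, config_free_energies, degeneracies = 1L) {
  g <- as.numeric(config_free_energies)
  if (length(g) < 1 || any(!is.finite(g))) {
    stop("need at least one finite configuration energy")
  }
  d <- rep_len(as.numeric(degeneracies), length(g))
  if (length(degeneracies) > 1 && length(degeneracies) != length(g)) {
    stop("degeneracies must match configuration energies in length")
  }
  if (any(d < 1 | d != round(d))) stop("degeneracies must be positive integers")
  structure(list(site_id = as.character(site_id), g = g, d = d),
            class = "disorder_site")
}

#' Boltzmann occupancies of a disorder site
#'
#' \eqn{p_i = d_i e^{-g_i/RT} / \sum_j d_j e^{-g_j/RT}}, computed with a
#' max-shift for numerical stability.
#'
#' @param site a [disorder_site].
#' @param T temperature in K (> 0).
#' @return probability vector over configurations (sums to 1).
#' @examples
#' # a 0.8 kJ/mol gap at 298 K gives the 58/42 occupancy split
#' site_occupancies(disorder_site("iPr", c(0, 0.8)), T = 298)
#' @export
site_occupancies <- function(site, T = 300) {
  stopifnot(inherits(site, "disorder_site"), T > 0)
  rt <- R_KJ * T
  w <- site$d * exp(-(site$g - min(site$g)) / rt)
  w / sum(w)
}

#' Configurational free-energy stabilization of a disorder site
#'
#' The drop of the site free energy below its best single configuration,
#' \eqn{\Delta F = \min(g) - (-RT \ln \sum_i d_i e^{-g_i/RT}) \ge 0},
#' returned as a positive stabilization magnitude in kJ/mol. A single
#' non-degenerate configuration gives 0; the upper bound is
#' \eqn{RT \ln \sum_i d_i}.
#'
#' @inheritParams site_occupancies
#' @return stabilization in kJ/mol (>= 0).
#' @export
site_stabilization <- function(site, T = 300) {
  stopifnot(inherits(site, "disorder_site"), T > 0)
  rt <- R_KJ * T
  rt * log(sum(site$d * exp(-(site$g - min(site$g)) / rt)))
}

#' Energy gap implied by two-configuration occupancies
#'
#' Inverse Boltzmann relation \eqn{\Delta g = -RT \ln(p_2/p_1)} (equal
#' degeneracies); round-trips with [site_occupancies()].
#'
#' @param p probability vector of length 2, strictly inside the simplex.
#' @param T temperature in K.
#' @return gap g2 - g1 in kJ/mol.
#' @examples
#' energy_gap_from_occupancies(c(0.58, 0.42), T = 298) # ~0.800 kJ/mol
#' @export
energy_gap_from_occupancies <- function(p, T = 300) {
  stopifnot(length(p) == 2, T > 0)
  if (any(p <= 0) || any(p >= 1)) {
    stop("occupancies of 0 or 1 imply an infinite energy gap")
  }
  -R_KJ * T * log(p[2] / p[1])
}

#' Full disorder correction for a set of independent sites
#'
#' @param sites list of [disorder_site].
#' @param T temperature in K.
#' @return list of class `disorder_correction`: `total_stabilization`
#'   (kJ/mol), `per_site` (named numeric), `occupancies` (named list of
#'   probability vectors).
#' @export
disorder_correction <- function(sites, T = 300) {
  stopifnot(is.list(sites))
  per <- vapply(sites, site_stabilization, numeric(1), T = T)
  names(per) <- vapply(sites, `[[`, character(1), "site_id")
  occ <- lapply(sites, site_occupancies, T = T)
  names(occ) <- names(per)
  structure(list(total_stabilization = sum(per), per_site = per,
                 occupancies = occ), class = "disorder_correction")
}

#' Apply a disorder correction to a landscape entry
#'
#' Lowers the entry's free energy by the summed stabilization of its
#' independent disorder sites and flags it as a disordered model. With an
#' empty site list the entry is returned unchanged.
#'
#' @param entry one landscape entry: a list or single-row data.frame with at
#'   least `elatt` (and optionally `dis_corr`, the accumulated stabilization
#'   in kJ/mol that [assemble_landscape()] subtracts from the free energy).
#' @param sites list of [disorder_site] (possibly empty).
#' @param T temperature in K.
#' @return the entry with `dis_corr` increased by the total stabilization and
#'   `disordered = TRUE` when any site was applied.
#' @export
apply_disorder_correction <- function(entry, sites, T = 300) {
  if (!length(sites)) return(entry)
  corr <- disorder_correction(sites, T = T)
  prev <- if (is.null(entry$dis_corr) || is.na(entry$dis_corr)) 0 else entry$dis_corr
  entry$dis_corr <- prev + corr$total_stabilization
  entry$disordered <- TRUE
  entry
}
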