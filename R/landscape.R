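# Crystal-energy landscape assembly: combine lattice energies with explicit
# or estimated vibrational terms, attach two-tier error bars, rank, and
# label entries matching experimental powder patterns.

#' Estimate the uniform vibrational shift
#'
#' For candidates whose vibrational free energy was not computed explicitly,
#' the landscape applies a uniform shift equal to the unweighted mean F_vib of
#' the candidates that do carry an explicit term; the spread (sample standard
#' deviation, n-1 denominator) of those terms widens the shifted entries'
#' error bars.
#'
#' @param entries data.frame with columns `elatt` and `fvib` (kJ/mol; `NA`
#'   where not explicitly computed).
#' @return list of class `shift_estimate`: `mean_fvib`, `sd_fvib`,
#'   `n_explicit`.
#' @export
estimate_fvib_shift <- function(entries) {
  stopifnot(is.data.frame(entries), "fvib" %in% names(entries))
  fv <- entries$fvib[!is.na(entries$fvib)]
  if (length(fv) < 2) {
    stop("need at least 2 entries with explicit fvib to estimate the shift")
  }
  structure(list(mean_fvib = mean(fv), sd_fvib = stats::sd(fv),
                 n_explicit = length(fv)), class = "shift_estimate")
}

#' Assemble a ranked crystal-energy landscape
#'
#' Free energy per entry is `elatt + fvib` where `fvib` is explicit, and
#' `elatt + mean(fvib_explicit)` otherwise; any accumulated disorder
#' stabilization in `dis_corr` is subtracted. Relative free energies are
#' referenced to the global minimum (which gets `free_energy_rel = 0`).
#' Error bars: `sigma = sigma_base` for explicit entries and
#' `sqrt(sigma_base^2 + sd_fvib^2)` for shifted entries. Entries are ranked
#' ascending in relative free energy; ties break toward higher density, then
#' lexicographic id.
#'
#' @param entries data.frame with columns `id`, `elatt` and optionally
#'   `spacegroup`, `fvib` (NA allowed), `density`, `dis_corr`, `match_label`.
#' @param T temperature in K (reporting temperature of the free energies).
#' @param sigma_base one standard error of the relative free-energy model,
#'   kJ/mol (default 1.9).
#' @return data.frame of class `crystal_landscape` with columns id,
#'   spacegroup, density, elatt, fvib, fvib_explicit, dis_corr, free_energy,
#'   free_energy_rel, sigma, rank, match_label; the shift estimate is kept in
#'   `attr(, "shift")` and `T` in `attr(, "temperature")`.
#' @export
assemble_landscape <- function(entries, T = 300, sigma_base = 1.9) {
  stopifnot(is.data.frame(entries))
  if (!nrow(entries)) stop("no landscape entries")
  if (sigma_base < 0) stop("sigma_base must be non-negative")
  need <- c("id", "elatt")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns: ", paste(need, collapse = ", "))
  }
  e <- entries
  if (is.null(e$spacegroup)) e$spacegroup <- NA_character_
  if (is.null(e$fvib)) e$fvib <- NA_real_
  if (is.null(e$density)) e$density <- NA_real_
  if (is.null(e$dis_corr)) e$dis_corr <- 0
  e$dis_corr[is.na(e$dis_corr)] <- 0
  if (is.null(e$match_label)) e$match_label <- NA_character_
  if (any(!is.finite(e$elatt))) stop("every entry needs a finite elatt")

  e$fvib_explicit <- !is.na(e$fvib)
  if (all(e$fvib_explicit)) {
    shift <- structure(list(mean_fvib = NA_real_, sd_fvib = 0,
                            n_explicit = nrow(e)), class = "shift_estimate")
  } else {
    shift <- estimate_fvib_shift(e)
  }
  fv_used <- ifelse(e$fvib_explicit, e$fvib, shift$mean_fvib)
  e$free_energy <- e$elatt + fv_used - e$dis_corr
  e$free_energy_rel <- e$free_energy - min(e$free_energy)
  e$sigma <- ifelse(e$fvib_explicit, sigma_base,
                    sqrt(sigma_base^2 + shift$sd_fvib^2))
  ord <- order(e$free_energy_rel, -e$density, e$id)
  e <- e[ord, , drop = FALSE]
  e$rank <- seq_len(nrow(e))
  e <- e[, c("id", "spacegroup", "density", "elatt", "fvib", "fvib_explicit",
             "dis_corr", "free_energy", "free_energy_rel", "sigma", "rank",
             "match_label")]
  rownames(e) <- NULL
  class(e) <- c("crystal_landscape", "data.frame")
  attr(e, "shift") <- shift
  attr(e, "temperature") <- T
  attr(e, "sigma_base") <- sigma_base
  e
}

#' Label landscape entries that match experimental powder patterns
#'
#' For each named experimental pattern, every candidate with a structure is
#' scored via [rank_candidates()] and the best-scoring candidate receives the
#' pattern's name as its `match_label`. A candidate that is best for several
#' patterns carries all labels, separated by `";"`, with a warning.
#'
#' @param landscape a [assemble_landscape()] result.
#' @param experimental_patterns named list of [powder_pattern] (names are the
#'   experimental form labels).
#' @param structures named list of [crystal_structure] keyed by landscape id.
#' @param sim_params,pattern_params forwarded to [rank_candidates()].
#' @return the landscape with `match_label` filled in.
#' @export
attach_match_labels <- function(landscape, experimental_patterns, structures,
                                sim_params = similarity_params(),
                                pattern_params = list()) {
  stopifnot(inherits(landscape, "crystal_landscape"))
  if (!length(experimental_patterns)) return(landscape)
  labels <- names(experimental_patterns)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("every experimental pattern must be named")
  }
  cands <- structures[names(structures) %in% landscape$id]
  if (!length(cands)) stop("no structures correspond to landscape ids")
  for (lab in labels) {
    res <- rank_candidates(experimental_patterns[[lab]], cands,
                           sim_params = sim_params,
                           pattern_params = pattern_params)
    best <- res$candidate_id[1]
    i <- match(best, landscape$id)
    if (!is.na(landscape$match_label[i])) {
      warning("candidate '", best, "' is the best match for multiple patterns")
      landscape$match_label[i] <- paste(landscape$match_label[i], lab, sep = ";")
    } else {
      landscape$match_label[i] <- lab
    }
  }
  landscape
}

#' Write / read the landscape table as CSV
#'
#' Columns: id, spacegroup, density, free_energy_rel, sigma, fvib_explicit,
#' rank, match_label; rows sorted by rank.
#'
#' @param landscape a [assemble_landscape()] result.
#' @param path CSV path.
#' @return `landscape_table` returns the exported data.frame (invisibly when
#'   writing); `read_landscape_table` returns the data.frame.
#' @export
landscape_table <- function(landscape, path = NULL) {
  stopifnot(inherits(landscape, "crystal_landscape"))
  tab <- as.data.frame(landscape)[, c("id", "spacegroup", "density",
                                      "free_energy_rel", "sigma",
                                      "fvib_explicit", "rank", "match_label")]
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    return(invisible(tab))
  }
  tab
}

#' @rdname landscape_table
#' @export
read_landscape_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  tab$match_label[!is.na(tab$match_label) & tab$match_label == ""] <- NA
  if (is.logical(tab$match_label)) tab$match_label <- as.character(tab$match_label)
  tab
}

#' Read an input energy table
#'
#' CSV with columns `id`, `spacegroup`, `elatt_kjmol`, `fvib_kjmol` (blank
#' allowed) and either `density` or `cif_path`; densities are computed from
#' the CIF when a path is given.
#'
#' @param path CSV path.
#' @param base_dir directory against which relative `cif_path`s are resolved.
#' @return data.frame ready for [assemble_landscape()].
#' @export
read_energy_table <- function(path, base_dir = dirname(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  names(tab)[names(tab) == "elatt_kjmol"] <- "elatt"
  names(tab)[names(tab) == "fvib_kjmol"] <- "fvib"
  if (!"density" %in% names(tab) && "cif_path" %in% names(tab)) {
    tab$density <- vapply(tab$cif_path, function(p) {
      if (!file.exists(p)) p <- file.path(base_dir, p)
      crystal_density(parse_cif(p))
    }, numeric(1))
  }
  tab
}
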