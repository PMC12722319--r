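# Risk statistics: stability probabilities from the landscape's error model,
# solubility-ratio thermodynamics, severity classification, report rendering.

#' Probability that a challenger is more stable than a reference form
#'
#' One-sided Gaussian tail \eqn{\Phi(-\Delta F / \sigma)} where
#' \eqn{\Delta F} is the challenger-minus-reference free-energy difference
#' (positive = challenger nominally less stable) and \eqn{\sigma} is the one
#' standard error of the relative free-energy model, applied directly to the
#' pairwise difference (no additional \eqn{\sqrt 2} inflation).
#'
#' @param delta_f free-energy difference in kJ/mol, vectorized.
#' @param sigma_pair standard error of the difference in kJ/mol (> 0).
#' @return probability in (0, 1).
#' @examples
#' prob_more_stable(3.89, 1.894) # ~0.020
#' prob_more_stable(5.51, 1.894) # ~0.002
#' @export
prob_more_stable <- function(delta_f, sigma_pair) {
  if (any(sigma_pair <= 0)) stop("sigma_pair must be positive")
  stats::pnorm(-delta_f / sigma_pair)
}

#' Calibrate the pairwise standard error from a stated tail probability
#'
#' Inverse of [prob_more_stable()]: the sigma under which a gap `delta_f`
#' has probability `p` of inverting.
#'
#' @param p tail probability in (0, 0.5).
#' @param delta_f gap in kJ/mol (> 0).
#' @return sigma in kJ/mol.
#' @export
calibrate_sigma_pair <- function(p, delta_f) {
  stopifnot(p > 0, p < 0.5, delta_f > 0)
  delta_f / stats::qnorm(1 - p)
}

#' Solubility ratio implied by a free-energy gap
#'
#' Textbook polymorph thermodynamics: \eqn{S_{ref}/S_{new} = e^{\Delta F/RT}}
#' where \eqn{\Delta F} is the reference form's free energy above the more
#' stable form. A 1.62 kJ/mol gap at 300 K gives ~1.9, i.e. about a two-fold
#' solubility loss if the more stable form takes over.
#'
#' @param delta_f free-energy gap in kJ/mol, vectorized.
#' @param T temperature in K (> 0).
#' @return fold solubility ratio.
#' @export
solubility_ratio <- function(delta_f, T = 300) {
  stopifnot(T > 0)
  exp(delta_f / (R_KJ * T))
}

#' Free-energy gap implied by a solubility ratio
#'
#' \eqn{\Delta F = RT \ln(\mathrm{ratio})}; exact inverse of
#' [solubility_ratio()].
#'
#' @param ratio solubility ratio (> 0), vectorized.
#' @param T temperature in K.
#' @return gap in kJ/mol.
#' @export
free_energy_from_solubility <- function(ratio, T = 300) {
  stopifnot(T > 0)
  if (any(ratio <= 0)) stop("solubility ratio must be positive")
  R_KJ * T * log(ratio)
}

#' Severity classification of a polymorph risk
#'
#' `severe` when the inversion probability reaches `p_threshold` AND the
#' predicted solubility loss exceeds what the formulation tolerates;
#' `moderate` when exactly one condition holds; `low` otherwise.
#'
#' @param p_more_stable inversion probability.
#' @param solubility_fold predicted fold solubility loss (>= 0).
#' @param tolerance_fold largest fold loss the formulation tolerates (>= 1);
#'   default 1.05, appropriate for near-saturated solution formulations.
#' @param p_threshold probability above which the threat is considered live
#'   (default 0.05).
#' @return one of `"low"`, `"moderate"`, `"severe"`.
#' @export
classify_risk <- function(p_more_stable, solubility_fold,
                          tolerance_fold = 1.05, p_threshold = 0.05) {
  stopifnot(tolerance_fold >= 1)
  hits <- (p_more_stable >= p_threshold) + (solubility_fold > tolerance_fold)
  c("low", "moderate", "severe")[hits + 1]
}

#' Pairwise risk assessments against the labeled experimental forms
#'
#' For every labeled reference form in the landscape, assesses every other
#' entry as a challenger: free-energy difference, inversion probability under
#' the pairwise sigma (the larger of the two entries' sigmas), the fold
#' solubility loss the reference would suffer if the challenger took over
#' (`exp((F_ref - F_chal)/RT)`, > 1 when the challenger is more stable), and
#' the severity class.
#'
#' @param landscape a [assemble_landscape()] result with at least one
#'   `match_label`.
#' @param reference_forms labels to assess against; default: all labels
#'   present in the landscape.
#' @param tolerance_fold,p_threshold see [classify_risk()].
#' @return data.frame with columns reference_form, challenger, delta_f,
#'   sigma_pair, p_more_stable, solubility_fold, severity.
#' @export
assess_risk <- function(landscape, reference_forms = NULL,
                        tolerance_fold = 1.05, p_threshold = 0.05) {
  stopifnot(inherits(landscape, "crystal_landscape"))
  T <- attr(landscape, "temperature")
  labs <- landscape$match_label[!is.na(landscape$match_label)]
  labs <- unique(unlist(strsplit(labs, ";", fixed = TRUE)))
  if (is.null(reference_forms)) reference_forms <- sort(labs)
  out <- list()
  for (ref in reference_forms) {
    has <- vapply(strsplit(ifelse(is.na(landscape$match_label), "",
                                  landscape$match_label), ";", fixed = TRUE),
                  function(x) ref %in% x, logical(1))
    if (!any(has)) stop("no landscape entry is labeled '", ref, "'")
    iref <- which(has)[1]
    for (j in seq_len(nrow(landscape))) {
      if (j == iref) next
      delta_f <- landscape$free_energy_rel[j] - landscape$free_energy_rel[iref]
      sigma_pair <- max(landscape$sigma[iref], landscape$sigma[j])
      p <- prob_more_stable(delta_f, sigma_pair)
      fold <- solubility_ratio(-delta_f, T) # >1 when challenger more stable
      out[[length(out) + 1L]] <- data.frame(
        reference_form = ref, challenger = landscape$id[j],
        delta_f = delta_f, sigma_pair = sigma_pair, p_more_stable = p,
        solubility_fold = fold,
        severity = classify_risk(p, fold, tolerance_fold, p_threshold),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$reference_form, -res$p_more_stable, res$challenger), ]
  rownames(res) <- NULL
  res
}

#' Render the risk report
#'
#' Deterministic human-readable text and machine-readable JSON carrying the
#' landscape table, every pairwise assessment, and the severity verdicts.
#'
#' @param landscape a [assemble_landscape()] result.
#' @param assessments data.frame from [assess_risk()] (may be empty/NULL for
#'   a landscape-only report).
#' @param format `"text"` or `"json"`.
#' @param path optional output file.
#' @return character: the report lines (text) or JSON string.
#' @export
render_report <- function(landscape, assessments = NULL,
                          format = c("text", "json"), path = NULL) {
  stopifnot(inherits(landscape, "crystal_landscape"))
  format <- match.arg(format)
  tab <- landscape_table(landscape)
  T <- attr(landscape, "temperature")
  if (format == "json") {
    payload <- list(
      temperature_K = T,
      sigma_base_kjmol = attr(landscape, "sigma_base"),
      landscape = tab,
      assessments = if (is.null(assessments) || !nrow(assessments))
        list() else assessments
    )
    out <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, na = "null", pretty = TRUE)
    out <- as.character(out)
    if (!is.null(path)) writeLines(out, path)
    return(out)
  }
  fmt_lab <- function(x) ifelse(is.na(x), "", paste0("  <- ", x))
  lines <- c(
    sprintf("Crystal energy landscape at %g K (%d structures)", T, nrow(tab)),
    sprintf("  sigma_base = %g kJ/mol", attr(landscape, "sigma_base")),
    "",
    sprintf("  %4s %-12s %-10s %8s %8s %7s%s", "rank", "id", "spacegroup",
            "dF(kJ/mol)", "sigma", "rho", ""),
    sprintf("  %4d %-12s %-10s %8.3f %8.3f %7s%s",
            tab$rank, tab$id, ifelse(is.na(tab$spacegroup), "?", tab$spacegroup),
            tab$free_energy_rel, tab$sigma,
            ifelse(is.na(tab$density), "-", sprintf("%.3f", tab$density)),
            fmt_lab(tab$match_label))
  )
  if (!is.null(assessments) && nrow(assessments)) {
    lines <- c(lines, "", "Risk assessments (challenger vs reference form):")
    for (i in seq_len(nrow(assessments))) {
      a <- assessments[i, ]
      lines <- c(lines, sprintf(
        "  %s vs %s: dF = %+.3f kJ/mol, P(more stable) = %.2g, fold = %.3g -> %s",
        a$challenger, a$reference_form, a$delta_f, signif(a$p_more_stable, 2),
        a$solubility_fold, a$severity
      ))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  lines
}
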