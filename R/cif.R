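# Crystal structures and a CIF 1.1 core-subset reader/writer.

#' Construct a crystal structure
#'
#' @param cell a [unit_cell].
#' @param spacegroup Hermann-Mauguin symbol; used to resolve operators when
#'   `ops` is not given, and kept as metadata otherwise.
#' @param sites data.frame with columns `label`, `element`, `x`, `y`, `z` and
#'   optionally `occupancy` (default 1) and `disorder_group` (default NA).
#'   Coordinates are fractional.
#' @param ops list of `symop`; defaults to the operators of `spacegroup`.
#' @param z_formula formula units per cell; defaults to the number of
#'   operators (one molecule per asymmetric unit).
#' @param formula optional molecular formula (e.g. `"C37H48N6O5S2"`), used
#'   preferentially for density.
#' @return object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, spacegroup = "P1", sites, ops = NULL,
                              z_formula = NULL, formula = NULL) {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(sites))
  need <- c("label", "element", "x", "y", "z")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(sites$occupancy)) sites$occupancy <- 1
  if (is.null(sites$disorder_group)) sites$disorder_group <- NA_character_
  sites$disorder_group <- as.character(sites$disorder_group)
  if (any(!is.finite(sites$x) | !is.finite(sites$y) | !is.finite(sites$z))) {
    stop("site coordinates must be finite")
  }
  if (any(sites$occupancy <= 0 | sites$occupancy > 1)) {
    stop("occupancies must lie in (0, 1]")
  }
  # sites sharing a disorder_group are alternative configurations of one
  # disordered fragment; their occupancies must sum to 1
  grp <- sites$disorder_group[!is.na(sites$disorder_group)]
  for (g in unique(grp)) {
    members <- sites[!is.na(sites$disorder_group) & sites$disorder_group == g, ]
    s <- sum(members$occupancy)
    if (nrow(members) > 1L && abs(s - 1) > 0.01) {
      stop(sprintf("disorder group '%s': occupancies sum to %.3f, expected 1",
                   g, s))
    }
  }
  if (is.null(ops)) ops <- spacegroup_ops(spacegroup)
  if (is.null(z_formula)) z_formula <- length(ops)
  rownames(sites) <- NULL
  structure(list(cell = cell, spacegroup = spacegroup,
                 sg_number = spacegroup_number(spacegroup),
                 ops = ops, sites = sites,
                 z_formula = as.integer(z_formula), formula = formula),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %s, %d op(s), %d site(s), Z=%d\n",
              x$spacegroup, length(x$ops), nrow(x$sites), x$z_formula))
  print(x$cell)
  invisible(x)
}

#' Crystallographic density
#'
#' \eqn{\rho = Z M / (N_A V)} with V from [cell_volume()]. The molar mass is
#' taken from `molar_mass` if given, else from the structure's declared
#' molecular formula, else summed over the expanded site list (occupancy
#' weighted) -- the site list is the least reliable source when hydrogens
#' are missing from the model.
#'
#' @param structure a [crystal_structure].
#' @param molar_mass molar mass in g/mol of one formula unit (optional).
#' @return density in g/cm^3.
#' @examples
#' # ritonavir form 4: Z = 2, M = 720.95 g/mol in a 1916.9 A^3 cell -> 1.249
#' @export
crystal_density <- function(structure, molar_mass = NULL) {
  stopifnot(inherits(structure, "crystal_structure"))
  v <- cell_volume(structure$cell)
  if (v <= 0) stop("invalid cell: zero volume")
  if (is.null(molar_mass) && !is.null(structure$formula)) {
    molar_mass <- molar_mass_from_formula(structure$formula)
  }
  if (!is.null(molar_mass)) {
    stopifnot(molar_mass > 0)
    mass_cell <- structure$z_formula * molar_mass
  } else {
    exp_sites <- expand_symmetry(structure)
    if (any(!exp_sites$element %in% names(.ATOMIC_MASS))) {
      stop("no atomic mass for element: ",
           setdiff(exp_sites$element, names(.ATOMIC_MASS))[1])
    }
    mass_cell <- sum(exp_sites$occupancy * .ATOMIC_MASS[exp_sites$element])
  }
  # v in A^3 = 1e-24 cm^3
  mass_cell / (N_AVOGADRO * v * 1e-24)
}

# ---- CIF reading ----------------------------------------------------------

.cif_tokenize <- function(lines) {
  toks <- character(0)
  for (ln in lines) {
    ln <- sub("^\\s+", "", ln)
    while (nzchar(ln)) {
      if (startsWith(ln, "#")) break
      first <- substr(ln, 1, 1)
      if (first %in% c("'", '"')) {
        rest <- substr(ln, 2, nchar(ln))
        close <- regexpr(first, rest, fixed = TRUE)
        if (close < 0) stop("unterminated quoted CIF value: ", ln)
        toks <- c(toks, substr(rest, 1, close - 1))
        ln <- substr(rest, close + 1, nchar(rest))
      } else {
        sp <- regexpr("\\s", ln)
        if (sp < 0) {
          toks <- c(toks, ln)
          ln <- ""
        } else {
          toks <- c(toks, substr(ln, 1, sp - 1))
          ln <- substr(ln, sp + 1, nchar(ln))
        }
      }
      ln <- sub("^\\s+", "", ln)
    }
  }
  toks[nzchar(toks)]
}

# numeric CIF value, stripping a standard-uncertainty suffix "14.13(2)"
.cif_num <- function(x) as.numeric(sub("\\(.*\\)$", "", x))

#' Parse a crystal structure from CIF text
#'
#' Reads the CIF 1.1 core subset: cell parameters, symmetry operators (from a
#' `_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz` loop, or
#' resolved from the space-group symbol for P1, P2\eqn{_1}, C2,
#' P2\eqn{_1}2\eqn{_1}2\eqn{_1}), and the atom-site loop with fractional
#' coordinates, occupancies (default 1) and disorder group tags.
#'
#' @param x path to a `.cif` file, or CIF text (character vector of lines or
#'   a single string).
#' @return a [crystal_structure].
#' @export
parse_cif <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
           else unlist(strsplit(x, "\n", fixed = TRUE))
  toks <- .cif_tokenize(lines)
  if (!length(toks)) stop("empty CIF document")

  vals <- list()   # scalar tag -> value
  loops <- list()  # list of list(tags=..., rows=matrix)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    t <- toks[i]
    if (grepl("^data_", t, ignore.case = TRUE)) {
      i <- i + 1L
    } else if (tolower(t) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(toks[i], "_")) {
        tags <- c(tags, tolower(toks[i]))
        i <- i + 1L
      }
      body <- character(0)
      while (i <= n && !startsWith(toks[i], "_") &&
             tolower(toks[i]) != "loop_" &&
             !grepl("^data_", toks[i], ignore.case = TRUE)) {
        body <- c(body, toks[i])
        i <- i + 1L
      }
      if (length(tags) && length(body) %% length(tags) == 0L && length(body)) {
        m <- matrix(body, ncol = length(tags), byrow = TRUE)
        colnames(m) <- tags
        loops[[length(loops) + 1L]] <- m
      }
    } else if (startsWith(t, "_")) {
      if (i + 1L <= n && !startsWith(toks[i + 1L], "_") &&
          tolower(toks[i + 1L]) != "loop_") {
        vals[[tolower(t)]] <- toks[i + 1L]
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }

  need_cell <- c("_cell_length_a", "_cell_length_b", "_cell_length_c")
  for (tag in need_cell) {
    if (is.null(vals[[tag]])) stop("CIF parse error: missing tag ", tag)
  }
  ang <- function(tag) if (is.null(vals[[tag]])) 90 else .cif_num(vals[[tag]])
  cell <- unit_cell(
    .cif_num(vals[["_cell_length_a"]]), .cif_num(vals[["_cell_length_b"]]),
    .cif_num(vals[["_cell_length_c"]]),
    ang("_cell_angle_alpha"), ang("_cell_angle_beta"), ang("_cell_angle_gamma")
  )

  find_loop <- function(tag) {
    for (lp in loops) if (tag %in% colnames(lp)) return(lp)
    NULL
  }
  symtags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  ops <- NULL
  for (st in symtags) {
    lp <- find_loop(st)
    if (!is.null(lp)) {
      ops <- lapply(lp[, st], parse_symop)
      break
    }
    if (!is.null(vals[[st]])) {
      ops <- list(parse_symop(vals[[st]]))
      break
    }
  }
  sg <- vals[["_symmetry_space_group_name_h-m"]]
  if (is.null(sg)) sg <- vals[["_space_group_name_h-m_alt"]]
  if (is.null(ops)) {
    if (is.null(sg)) {
      stop("CIF parse error: missing tag _space_group_symop_operation_xyz ",
           "(no operator loop and no space-group symbol)")
    }
    ops <- spacegroup_ops(sg)
  }
  if (is.null(sg)) sg <- "P1"

  atom_tag <- "_atom_site_fract_x"
  lp <- find_loop(atom_tag)
  if (is.null(lp)) stop("CIF parse error: missing tag ", atom_tag)
  col <- function(tag, default = NULL) {
    if (tag %in% colnames(lp)) lp[, tag] else default
  }
  label <- col("_atom_site_label", paste0("X", seq_len(nrow(lp))))
  element <- col("_atom_site_type_symbol")
  if (is.null(element)) element <- gsub("[^A-Za-z].*$", "", label)
  occ <- col("_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, nrow(lp)) else .cif_num(occ)
  dg <- col("_atom_site_disorder_group")
  dg <- if (is.null(dg)) rep(NA_character_, nrow(lp)) else {
    ifelse(dg %in% c(".", "?"), NA_character_, dg)
  }
  sites <- data.frame(
    label = label, element = element,
    x = .cif_num(lp[, "_atom_site_fract_x"]),
    y = .cif_num(lp[, "_atom_site_fract_y"]),
    z = .cif_num(lp[, "_atom_site_fract_z"]),
    occupancy = occ, disorder_group = dg, stringsAsFactors = FALSE
  )
  zf <- vals[["_cell_formula_units_z"]]
  formula <- vals[["_chemical_formula_sum"]]
  if (!is.null(formula)) formula <- gsub(" ", "", formula)
  crystal_structure(cell, spacegroup = sg, sites = sites, ops = ops,
                    z_formula = if (is.null(zf)) NULL else as.integer(.cif_num(zf)),
                    formula = formula)
}

#' Write a crystal structure as CIF text
#'
#' @param structure a [crystal_structure].
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of CIF lines, invisibly when `path` is given.
#' @export
write_cif <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "crystal_structure"))
  s <- structure
  lines <- c(
    "data_structure",
    sprintf("_symmetry_space_group_name_H-M '%s'", s$spacegroup),
    sprintf("_cell_length_a %.6f", s$cell$a),
    sprintf("_cell_length_b %.6f", s$cell$b),
    sprintf("_cell_length_c %.6f", s$cell$c),
    sprintf("_cell_angle_alpha %.6f", s$cell$alpha),
    sprintf("_cell_angle_beta %.6f", s$cell$beta),
    sprintf("_cell_angle_gamma %.6f", s$cell$gamma),
    sprintf("_cell_formula_units_Z %d", s$z_formula)
  )
  if (!is.null(s$formula)) {
    lines <- c(lines, sprintf("_chemical_formula_sum '%s'", s$formula))
  }
  lines <- c(lines, "loop_", "_space_group_symop_operation_xyz",
             vapply(s$ops, function(op) sprintf("'%s'", format_symop(op)),
                    character(1)))
  lines <- c(lines, "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "_atom_site_occupancy", "_atom_site_disorder_group")
  for (i in seq_len(nrow(s$sites))) {
    r <- s$sites[i, ]
    lines <- c(lines, sprintf(
      "%s %s %.8f %.8f %.8f %.6f %s",
      r$label, r$element, r$x, r$y, r$z, r$occupancy,
      if (is.na(r$disorder_group)) "." else r$disorder_group
    ))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
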