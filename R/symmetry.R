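# Symmetry operations: parsing of xyz operator strings, the built-in
# space-group table, and expansion of the asymmetric unit.

#' Parse a symmetry operator in xyz notation
#'
#' Accepts strings such as `"x, y, z"`, `"-x,y+1/2,-z"`, `"1/2+x,-y,z"`.
#'
#' @param s operator string.
#' @return a `symop`: list with `rot` (3x3 integer matrix) and `trans`
#'   (length-3 numeric, reduced mod 1 into \[0, 1)).
#' @export
parse_symop <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  parts <- strsplit(gsub("[ '\"]", "", tolower(s)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L || any(!nzchar(parts))) {
    stop("malformed symmetry operator: '", s, "'")
  }
  rot <- matrix(0L, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    toks <- regmatches(parts[i], gregexpr("[+-]?[^+-]+", parts[i]))[[1]]
    if (sum(nchar(toks)) != nchar(parts[i])) {
      stop("malformed symmetry operator: '", s, "'")
    }
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1L else 1L
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        rot[i, match(body, c("x", "y", "z"))] <-
          rot[i, match(body, c("x", "y", "z"))] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        trans[i] <- trans[i] + sign * nd[1] / nd[2]
      } else if (grepl("^[0-9]*\\.?[0-9]+$", body)) {
        trans[i] <- trans[i] + sign * as.numeric(body)
      } else {
        stop("malformed symmetry operator: '", s, "'")
      }
    }
  }
  det3 <- function(m) {
    m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
      m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
      m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  }
  if (!det3(rot) %in% c(-1L, 1L)) {
    stop("symmetry operator rotation must have determinant +/-1: '", s, "'")
  }
  structure(list(rot = rot, trans = trans %% 1), class = "symop")
}

#' Format a symmetry operator back to xyz notation
#' @param op a `symop`.
#' @return character scalar such as `"-x,y+1/2,-z"`.
#' @export
format_symop <- function(op) {
  stopifnot(inherits(op, "symop"))
  frac_str <- function(t) {
    if (abs(t) < 1e-9) return("")
    # denominators occurring in crystallographic translations
    for (den in c(2L, 3L, 4L, 6L)) {
      num <- t * den
      if (abs(num - round(num)) < 1e-9) {
        return(sprintf("+%d/%d", as.integer(round(num)), den))
      }
    }
    sprintf("%+.6f", t)
  }
  vars <- c("x", "y", "z")
  out <- character(3)
  for (i in 1:3) {
    terms <- ""
    for (j in 1:3) {
      if (op$rot[i, j] != 0L) {
        terms <- paste0(terms, if (op$rot[i, j] > 0) "+" else "-", vars[j])
      }
    }
    terms <- paste0(terms, frac_str(op$trans[i]))
    out[i] <- sub("^\\+", "", terms)
  }
  paste(out, collapse = ",")
}

# Built-in generators for the space groups the package resolves by symbol.
.SPACEGROUPS <- list(
  P1 = list(number = 1L, ops = c("x,y,z")),
  P21 = list(number = 4L, ops = c("x,y,z", "-x,y+1/2,-z")),
  C2 = list(number = 5L, ops = c("x,y,z", "-x,y,-z",
                                 "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z")),
  P212121 = list(number = 19L, ops = c("x,y,z", "-x+1/2,-y,z+1/2",
                                       "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"))
)

.normalize_sg_symbol <- function(symbol) {
  s <- gsub("[ _()]", "", symbol)
  # map full Hermann-Mauguin forms to the short symbols used as table keys
  s <- sub("^P121$", "P21", sub("^P1211$", "P21", s))
  s <- sub("^C121$", "C2", s)
  s
}

#' Symmetry operators for a space-group symbol
#'
#' Resolves a Hermann-Mauguin symbol via the built-in table
#' (P1, P2\eqn{_1}, C2, P2\eqn{_1}2\eqn{_1}2\eqn{_1}).
#'
#' @param symbol Hermann-Mauguin symbol, spaces optional (e.g. `"P 21"`).
#' @return list of `symop`.
#' @export
spacegroup_ops <- function(symbol) {
  key <- .normalize_sg_symbol(symbol)
  if (!key %in% names(.SPACEGROUPS)) {
    stop("space group symbol not in built-in table: '", symbol,
         "' (known: ", paste(names(.SPACEGROUPS), collapse = ", "), ")")
  }
  lapply(.SPACEGROUPS[[key]]$ops, parse_symop)
}

#' @rdname spacegroup_ops
#' @export
spacegroup_number <- function(symbol) {
  key <- .normalize_sg_symbol(symbol)
  if (!key %in% names(.SPACEGROUPS)) return(NA_integer_)
  .SPACEGROUPS[[key]]$number
}

#' Expand the asymmetric unit into the full cell
#'
#' Applies every symmetry operator to every asymmetric-unit site, wraps
#' fractional coordinates into \[0, 1), and merges copies of the same site
#' closer than `tol` fractional units (minimum-image), keeping one copy.
#' Sites on special positions therefore collapse to their orbit size.
#'
#' @param structure a [crystal_structure].
#' @param tol merge tolerance in fractional coordinates (default 0.01).
#' @return data.frame with columns label, element, x, y, z, occupancy,
#'   disorder_group.
#' @export
expand_symmetry <- function(structure, tol = 0.01) {
  stopifnot(inherits(structure, "crystal_structure"))
  ops <- structure$ops
  if (length(ops) == 0L) stop("structure has no symmetry operators")
  sites <- structure$sites
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    x0 <- as.numeric(sites[i, c("x", "y", "z")])
    pos <- t(vapply(ops, function(op) {
      (as.vector(op$rot %*% x0) + op$trans) %% 1
    }, numeric(3)))
    keep <- rep(TRUE, nrow(pos))
    for (j in seq_len(nrow(pos))[-1]) {
      for (k in seq_len(j - 1)) {
        if (!keep[k]) next
        d <- pos[j, ] - pos[k, ]
        d <- d - round(d) # minimum image in fractional space
        if (sqrt(sum(d^2)) < tol) {
          keep[j] <- FALSE
          break
        }
      }
    }
    pos <- pos[keep, , drop = FALSE]
    out[[i]] <- data.frame(
      label = sites$label[i], element = sites$element[i],
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      occupancy = sites$occupancy[i],
      disorder_group = sites$disorder_group[i],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
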