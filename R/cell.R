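# Unit cells: construction, volume, lattice matrix, density.

#' Construct a unit cell
#'
#' @param a,b,c cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return object of class `unit_cell`.
#' @examples
#' unit_cell(14.13, 5.16, 26.47, beta = 96.67)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(vals))) stop("cell parameters must be finite")
  if (any(vals[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(vals[4:6] <= 0 | vals[4:6] >= 180)) {
    stop("cell angles must lie strictly between 0 and 180 degrees")
  }
  cell <- structure(as.list(vals), class = "unit_cell")
  # triclinic volume discriminant must be positive for a realizable cell
  if (.cell_discriminant(cell) <= 0) {
    stop("invalid cell: angle combination gives non-positive volume discriminant")
  }
  cell
}

.cell_discriminant <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Unit-cell volume
#'
#' Triclinic formula
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma+2\cos\alpha\cos\beta\cos\gamma}};
#' reduces to \eqn{abc\sin\beta} for monoclinic cells.
#'
#' @param cell a [unit_cell].
#' @return volume in cubic Angstrom.
#' @examples
#' cell_volume(unit_cell(14.13, 5.16, 26.47, beta = 96.67)) # ~1916.9
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  disc <- .cell_discriminant(cell)
  if (disc <= 0) stop("invalid cell: non-positive volume discriminant")
  cell$a * cell$b * cell$c * sqrt(disc)
}

#' Direct lattice matrix (rows are the a, b, c vectors, Angstrom)
#'
#' Standard Cartesian convention: a along x, b in the xy plane.
#'
#' @param cell a [unit_cell].
#' @return 3x3 numeric matrix.
#' @export
lattice_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- cell_volume(cell)
  rbind(
    c(cell$a, 0, 0),
    c(cell$b * cg, cell$b * sg, 0),
    c(cell$c * cb, cell$c * (ca - cb * cg) / sg, v / (cell$a * cell$b * sg))
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg  V=%.2f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)
  ))
  invisible(x)
}
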