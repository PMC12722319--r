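# Physical constants and embedded element tables shared across the package.

#' Gas constant in kJ/(mol K)
#' @keywords internal
R_KJ <- 8.31446e-3

#' Avogadro constant in 1/mol
#' @keywords internal
N_AVOGADRO <- 6.02214076e23

# IUPAC 2021 standard atomic weights (abridged), g/mol.
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403163, Na = 22.98976928, Mg = 24.305, P = 30.973761998,
  S = 32.06, Cl = 35.45, K = 39.0983, Ca = 40.078, Br = 79.904,
  I = 126.90447
)

# Atomic numbers for the constant form-factor fallback.
.ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Br = 35, I = 53
)

# 4-term Cromer-Mann coefficients (International Tables C, Table 6.1.1.4)
# for the elements of typical organic pharmaceuticals.
# f(s) = sum_i a_i exp(-b_i s^2) + c, with s = sin(theta)/lambda in 1/Angstrom.
.CROMER_MANN <- list(
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

#' Molar mass from a molecular formula
#'
#' Parses a Hill-notation formula such as `"C37H48N6O5S2"` against the
#' embedded IUPAC 2021 standard atomic weights.
#'
#' @param formula character scalar, e.g. `"C37H48N6O5S2"`.
#' @return molar mass in g/mol.
#' @examples
#' molar_mass_from_formula("C37H48N6O5S2") # ritonavir, 720.95 g/mol
#' @export
molar_mass_from_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  total <- 0
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% names(.ATOMIC_MASS)) {
      stop("no atomic mass for element: ", el)
    }
    total <- total + n * .ATOMIC_MASS[[el]]
  }
  total
}
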