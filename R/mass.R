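# m/z utilities for MS-based intermediate identification.

# IUPAC monoisotopic masses of the most abundant isotope.
MONOISOTOPIC_MASS <- c(
  H = 1.00782503207, B = 11.0093054, C = 12.0, N = 14.0030740048,
  O = 15.9949146196, F = 18.99840322, P = 30.97376163, S = 31.97207100,
  Cl = 34.96885268, Br = 78.9183371, I = 126.904473
)

# Integer masses of the most abundant isotope (nominal mass arithmetic).
NOMINAL_MASS <- c(
  H = 1L, B = 11L, C = 12L, N = 14L, O = 16L, F = 19L, P = 31L, S = 32L,
  Cl = 35L, Br = 79L, I = 127L
)

PROTON_MASS <- 1.007276

as_formula <- function(formula) {
  if (inherits(formula, "molecular_formula")) return(formula)
  if (inherits(formula, "molecular_graph")) return(molecular_formula(formula))
  if (is.character(formula)) return(parse_formula(formula))
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(structure(stats::setNames(as.integer(formula), names(formula)),
                     class = "molecular_formula"))
  }
  stop("cannot interpret molecular formula input", call. = FALSE)
}

check_formula_elements <- function(f, table) {
  if (length(f) == 0L) stop("empty molecular formula", call. = FALSE)
  bad <- setdiff(names(f), names(table))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

#' Monoisotopic m/z of a molecular formula
#'
#' Sums IUPAC monoisotopic atomic masses; the `+H` / `-H` adducts add or
#' subtract the proton mass 1.007276 Da. Rounding is round-half-even to
#' `digits` decimals (4 by default, matching high-resolution MS reporting).
#'
#' @param formula A `molecular_formula`, a formula string such as
#'   `"C8H9NO3"`, or a `molecular_graph`.
#' @param adduct `"neutral"`, `"+H"` (protonated), or `"-H"` (deprotonated).
#' @param digits Decimals to round to; `NA` for no rounding.
#' @return The m/z value (a number).
#' @examples
#' monoisotopic_mz("C8H9NO3", "+H")  # 168.0655, the aldoxime [M+H]+
#' @export
monoisotopic_mz <- function(formula, adduct = c("neutral", "+H", "-H"),
                            digits = 4) {
  adduct <- match.arg(adduct)
  f <- as_formula(formula)
  check_formula_elements(f, MONOISOTOPIC_MASS)
  m <- sum(MONOISOTOPIC_MASS[names(f)] * as.numeric(f))
  m <- m + switch(adduct, neutral = 0, `+H` = PROTON_MASS, `-H` = -PROTON_MASS)
  if (is.na(digits)) m else round(m, digits)
}

#' Nominal (integer) m/z of a molecular formula
#'
#' Integer mass arithmetic on most-abundant-isotope masses, as used for
#' unit-resolution SIM/MRM settings; `+H`/`-H` add or subtract 1.
#'
#' @inheritParams monoisotopic_mz
#' @return An integer m/z.
#' @examples
#' nominal_mz("C8H9NO3", "+H")  # 168
#' @export
nominal_mz <- function(formula, adduct = c("neutral", "+H", "-H")) {
  adduct <- match.arg(adduct)
  f <- as_formula(formula)
  check_formula_elements(f, NOMINAL_MASS)
  m <- sum(NOMINAL_MASS[names(f)] * as.integer(f))
  as.integer(m + switch(adduct, neutral = 0L, `+H` = 1L, `-H` = -1L))
}
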