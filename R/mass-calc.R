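# Monoisotopic atomic masses (CODATA/AME, Da) for the elements that occur in
# small-molecule environmental analytes. The charge carrier is the proton
# (1.0072765 Da), i.e. the hydrogen atom mass corrected for the electron.
.MONO_MASS <- c(
  C  = 12.000000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  F  = 18.9984032,
  Cl = 34.96885271,
  Br = 78.9183376,
  I  = 126.904468,
  Na = 22.98976928,
  K  = 38.9637069,
  Si = 27.9769265327
)

.PROTON_MASS <- 1.0072765

#' Parse a molecular formula
#'
#' Converts a Hill-notation formula string such as \code{"C12H11NO"} into a
#' named vector of element counts. Element symbols must be among the supported
#' set (C, H, N, O, S, P, F, Cl, Br, I, Na, K, Si).
#'
#' @param formula character(1) molecular formula.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C12H11NO")
#' @export
parseFormula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("formula must be a non-empty character string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(tokens) || sum(nchar(tokens)) != nchar(formula))
    stop(sprintf("cannot parse formula '%s'", formula))
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, names(.MONO_MASS))
  if (length(unknown))
    stop(sprintf("unknown element symbol(s): %s",
                 paste(unknown, collapse = ", ")))
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  if (sum(counts) < 1L) stop("formula must contain at least one atom")
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of monoisotopic atomic masses over the formula's element counts.
#'
#' @param formula character(1) formula (e.g. \code{"C12H9NO"}) or a named
#'   count vector from [parseFormula()].
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopicMass("C12H9NO")   # 183.068414
#' @export
monoisotopicMass <- function(formula) {
  counts <- if (is.character(formula)) parseFormula(formula) else {
    if (is.null(names(formula)) || any(!names(formula) %in% names(.MONO_MASS)))
      stop("named count vector with known element symbols required")
    formula
  }
  sum(.MONO_MASS[names(counts)] * as.numeric(counts))
}

#' m/z of a protonated or deprotonated molecule
#'
#' Computes the ion m/z for the \code{[M+H]+} and \code{[M-H]-} adducts using
#' the electron-corrected proton mass (1.0072765 Da), so that positive- and
#' negative-mode values of the same formula differ by exactly two proton
#' masses.
#'
#' @param formula molecular formula (string or parsed counts).
#' @param adduct \code{"[M+H]+"} or \code{"[M-H]-"} (an ASCII hyphen is
#'   accepted for the minus sign).
#' @return Ion m/z in Da (full precision; round only for display).
#' @examples
#' adductMz("C12H9NO", "[M+H]+")    # 184.0757 (quinone monoimine)
#' adductMz("C12H11NO", "[M-H]-")   # 184.0768
#' @export
adductMz <- function(formula, adduct = c("[M+H]+", "[M-H]-")) {
  adduct <- gsub("−", "-", adduct[1])
  if (!adduct %in% c("[M+H]+", "[M-H]-"))
    stop(sprintf("unsupported adduct '%s'; use [M+H]+ or [M-H]-", adduct))
  m <- monoisotopicMass(formula)
  if (adduct == "[M+H]+") m + .PROTON_MASS else m - .PROTON_MASS
}
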