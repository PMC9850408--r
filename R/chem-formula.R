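# Monoisotopic masses of the lightest stable isotope of each supported element,
# plus the electron mass. CODATA/IUPAC values, Da.
ELEMENT_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668
)

ELECTRON_MASS <- 0.00054857990
PROTON_MASS   <- ELEMENT_MASS[["H"]] - ELECTRON_MASS
C13_DELTA     <- 1.0033548  # 13C - 12C spacing, Da

#' Parse an elemental formula string
#'
#' Turns a Hill-style formula such as `"C27H30O16"` into a named integer
#' vector of element counts. Two-letter element symbols (Na, K) are
#' recognised; counts default to 1 when omitted (`"CH4O"`).
#'
#' @param formula A formula string, or an already-parsed named numeric
#'   vector (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C27H30O16")
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
      stop("`formula` must be a single formula string or a named count vector.",
           call. = FALSE)
    }
    s <- gsub("[[:space:]+]", "", formula)
    if (!nzchar(s)) stop("Empty formula.", call. = FALSE)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    tokens <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
    if (sum(nchar(tokens)) != nchar(s)) {
      stop("Cannot parse formula '", formula, "'.", call. = FALSE)
    }
    elems <- sub("[0-9]*$", "", tokens)
    nums <- sub("^[A-Za-z]+", "", tokens)
    counts <- ifelse(nzchar(nums), as.numeric(nums), 1)
    names(counts) <- elems
    counts <- tapply(counts, factor(names(counts), levels = unique(elems)), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(ELEMENT_MASS))
  if (length(unknown)) {
    stop("Unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Element counts must be non-negative integers.", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("Formula has no atoms.", call. = FALSE)
  counts
}

#' Monoisotopic (exact) mass of a neutral formula
#'
#' Sum of element count times the mass of the principal isotope
#' (12C, 1H, 14N, 16O, 31P, 32S, 23Na, 39K). Charge is not considered
#' here; see [ion_mz()] for ionic species.
#'
#' @param formula Formula string or named count vector (see [parse_formula()]).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.010565
#' monoisotopic_mass("C7H6O4")   # DHB, 154.026609
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * ELEMENT_MASS[names(counts)])
}
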