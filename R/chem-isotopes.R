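# Per-element isotope abundance vectors over nominal mass shifts 0,+1,+2,...
# (IUPAC representative abundances). Aggregated nominal-mass model: fine
# structure within an A+k peak is not resolved.
ISOTOPE_ABUNDANCE <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  P  = 1,
  Na = 1,
  K  = c(0.932581, 0.000117, 0.067302)
)

conv_trunc <- function(a, b, n) {
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax >= 1L) {
      idx <- i:(i + jmax - 1L)
      out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
    }
  }
  out
}

#' Coarse isotope pattern of a formula
#'
#' Relative abundances of the A, A+1, ..., A+(n_peaks-1) isotopologue peaks
#' at nominal-mass resolution, from multinomial convolution of per-element
#' heavy-isotope probabilities (e.g. 13C 1.07%, 15N 0.364%, 18O 0.205%,
#' 34S 4.25%). Abundances are normalised so the monoisotopic peak A = 1.
#' Intended for confirming a formula assignment against an observed
#' distribution, not for fine-structure work.
#'
#' @param formula Formula string or named count vector.
#' @param n_peaks Number of isotopologue peaks to return (default 4).
#' @return A tibble with columns `shift` (0, 1, ...), `mz_shift` (Da,
#'   `shift * 1.0033548` as a nominal 13C spacing), and `abundance`
#'   (monoisotopic peak = 1).
#' @examples
#' isotope_pattern("C6H12O6")
#' isotope_pattern("C1")$abundance[2]  # ~0.0108
#' @export
isotope_pattern <- function(formula, n_peaks = 4) {
  counts <- parse_formula(formula)
  dist <- 1
  for (el in names(counts)) {
    p <- ISOTOPE_ABUNDANCE[[el]]
    if (is.null(p)) p <- 1
    for (i in seq_len(counts[[el]])) {
      dist <- conv_trunc(dist, p, n_peaks)
    }
  }
  dist <- dist[seq_len(n_peaks)]
  tibble::tibble(
    shift = seq_len(n_peaks) - 1L,
    mz_shift = (seq_len(n_peaks) - 1L) * C13_DELTA,
    abundance = dist / dist[1]
  )
}
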