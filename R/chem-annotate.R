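#' Neutral-loss library
#'
#' Common neutral losses seen between a precursor and its in-source
#' fragments in positive-mode MALDI/ESI of plant metabolites and lipids:
#' water, glycosyl units (deoxyhexose for rutinose-type sugars, hexose,
#' pentose), the phosphatidylcholine head-group marker trimethylamine,
#' the phosphatidylethanolamine head group, CO and CO2.
#'
#' @return Tibble with columns `name`, `formula`, `mass` (Da).
#' @examples
#' loss_library()
#' @export
loss_library <- function() {
  tibble::tibble(
    name = c("water", "deoxyhexose", "hexose", "pentose",
             "trimethylamine", "PE head", "CO", "CO2",
             "deoxyhexose+hexose"),
    formula = c("H2O", "C6H10O4", "C6H10O5", "C5H8O4",
                "C3H9N", "C2H8NO4P", "CO", "CO2", "C12H20O9"),
    mass = vapply(
      c("H2O", "C6H10O4", "C6H10O5", "C5H8O4",
        "C3H9N", "C2H8NO4P", "CO", "CO2", "C12H20O9"),
      monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
  )
}

# Mass deltas for alkali exchange relative to the protonated species.
ADDUCT_DELTAS <- function() {
  tibble::tibble(
    name = c("Na adduct (Na-H)", "K adduct (K-H)"),
    delta = c(ELEMENT_MASS[["Na"]] - ELEMENT_MASS[["H"]],
              ELEMENT_MASS[["K"]] - ELEMENT_MASS[["H"]])
  )
}

#' Annotate peak relations in a pseudo-MS/MS spectrum
#'
#' Assigns each peak of a pseudo-spectrum a chemical relation to the bait
#' (or to an already-assigned peak) by exact-mass differences, greedily and
#' in a fixed priority order: 13C isotope (k x 1.0033548 Da above an
#' assigned peak, k = 1..3), alkali adduct (Na-H +21.981944, K-H +37.955881
#' relative to an assigned peak), multimer (m/z consistent with k copies of
#' the bait's neutral mass, k <= 3), then neutral loss from the bait
#' (matched against `losses`). Peaks matching nothing are `"unassigned"`.
#' The bait peak itself is labelled `"precursor"`.
#'
#' @param spectrum A [pseudo_spectrum] object or a data frame with a `mz`
#'   column (peaks).
#' @param bait_mz Bait ion m/z. Defaults to the spectrum's own bait.
#' @param bait_formula Optional neutral formula of the bait molecule; when
#'   given, multimer relations use its exact mass, otherwise the bait's
#'   neutral mass is inferred as `bait_mz - proton`.
#' @param tol_ppm Mass tolerance in ppm for any relation (default 5).
#' @param losses Neutral-loss table as from [loss_library()].
#' @return Tibble with one row per peak: `peak_mz`, `relation`
#'   (`precursor|isotope|adduct|multimer|neutral_loss|unassigned`),
#'   `reference_mz`, `ppm`, `detail`.
#' @export
annotate_relations <- function(spectrum, bait_mz = NULL, bait_formula = NULL,
                               tol_ppm = 5, losses = loss_library()) {
  peaks <- tibble::as_tibble(spectrum)
  if (!nrow(peaks)) stop("Spectrum has no peaks.", call. = FALSE)
  if (is.null(bait_mz)) bait_mz <- attr(spectrum, "bait_mz")
  if (is.null(bait_mz)) stop("`bait_mz` is required.", call. = FALSE)
  mz <- sort(peaks$mz)

  res <- tibble::tibble(
    peak_mz = mz,
    relation = "unassigned",
    reference_mz = NA_real_,
    ppm = NA_real_,
    detail = NA_character_
  )
  tol_da <- function(m) m * tol_ppm / 1e6

  # bait peak: nearest within tolerance
  d <- abs(mz - bait_mz)
  if (any(d <= tol_da(bait_mz))) {
    i <- which.min(d)
    res$relation[i] <- "precursor"
    res$reference_mz[i] <- bait_mz
    res$ppm[i] <- ppm_error(mz[i], bait_mz)
    res$detail[i] <- "bait"
  }

  assigned <- function() which(res$relation != "unassigned")
  ad <- ADDUCT_DELTAS()
  m_neutral <- if (!is.null(bait_formula)) monoisotopic_mass(bait_formula)
               else bait_mz - PROTON_MASS

  pass_isotope <- function(i) {
    # ascending-m/z scan lets A+2 stack once A+1's reference is known;
    # chains always point at the monoisotopic peak, never at an isotope
    for (j in assigned()) {
      if (res$relation[j] == "isotope") next
      for (kk in 1:3) {
        target <- mz[j] + kk * C13_DELTA
        if (abs(mz[i] - target) <= tol_da(target)) {
          res$relation[i] <<- "isotope"
          res$reference_mz[i] <<- mz[j]
          res$ppm[i] <<- ppm_error(mz[i], target)
          res$detail[i] <<- paste0("13C", kk)
          return(TRUE)
        }
      }
    }
    FALSE
  }
  pass_adduct <- function(i) {
    for (j in assigned()) {
      if (res$relation[j] == "isotope") next
      for (a in seq_len(nrow(ad))) {
        target <- mz[j] + ad$delta[a]
        if (abs(mz[i] - target) <= tol_da(target)) {
          res$relation[i] <<- "adduct"
          res$reference_mz[i] <<- mz[j]
          res$ppm[i] <<- ppm_error(mz[i], target)
          res$detail[i] <<- ad$name[a]
          return(TRUE)
        }
      }
    }
    FALSE
  }
  pass_multimer <- function(i) {
    for (kk in 2:3) {
      for (cation in c("H", "Na", "K")) {
        target <- kk * m_neutral + ELEMENT_MASS[[cation]] - ELECTRON_MASS
        if (abs(mz[i] - target) <= tol_da(target)) {
          res$relation[i] <<- "multimer"
          res$reference_mz[i] <<- bait_mz
          res$ppm[i] <<- ppm_error(mz[i], target)
          res$detail[i] <<- sprintf("[%dM+%s]+", kk, cation)
          return(TRUE)
        }
      }
    }
    FALSE
  }
  pass_loss <- function(i) {
    delta <- bait_mz - mz[i]
    if (delta <= 0) return(FALSE)
    hit <- which(abs(losses$mass - delta) <= tol_da(bait_mz))
    if (!length(hit)) return(FALSE)
    hit <- hit[which.min(abs(losses$mass[hit] - delta))]
    res$relation[i] <<- "neutral_loss"
    res$reference_mz[i] <<- bait_mz
    res$ppm[i] <<- ppm_error(mz[i], bait_mz - losses$mass[hit])
    res$detail[i] <<- losses$name[hit]
    TRUE
  }

  # greedy assignment in priority order isotope -> adduct -> multimer ->
  # loss, iterated to a fixed point so relations can chain (e.g. the 13C
  # isotope of a fragment becomes assignable once the fragment is)
  repeat {
    changed <- FALSE
    for (pass in list(pass_isotope, pass_adduct, pass_multimer, pass_loss)) {
      for (i in order(mz)) {
        if (res$relation[i] != "unassigned") next
        if (pass(i)) changed <- TRUE
      }
    }
    if (!changed) break
  }

  res
}
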