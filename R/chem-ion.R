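#' Built-in adduct table
#'
#' The ion types routinely seen in positive-mode MALDI of small molecules.
#' Each row describes how an ion is formed from `k` copies of the neutral
#' molecule M: `m/z = (k * M + delta_mass - z * electron_mass) / |z|`.
#' `"[M]+"` is the radical cation (electron removal only), used for
#' anthocyanidins.
#'
#' @return A tibble with columns `name`, `k` (multimer factor),
#'   `delta_formula` (atoms added, `""` for none), `delta_mass` (Da),
#'   `charge`.
#' @examples
#' adduct_table()
#' @export
adduct_table <- function() {
  tibble::tibble(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M]+",
             "[2M+H]+", "[2M+Na]+", "[3M+H]+", "[3M+Na]+"),
    k = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L),
    delta_formula = c("H", "Na", "K", "", "H", "Na", "H", "Na"),
    delta_mass = c(ELEMENT_MASS[["H"]], ELEMENT_MASS[["Na"]], ELEMENT_MASS[["K"]], 0,
                   ELEMENT_MASS[["H"]], ELEMENT_MASS[["Na"]],
                   ELEMENT_MASS[["H"]], ELEMENT_MASS[["Na"]]),
    charge = 1L
  )
}

#' m/z of an ionic species
#'
#' Computes the mass-to-charge ratio of an adduct/multimer ion of a neutral
#' molecule: `m/z = (k*M + adduct mass - z * m_e) / |z|` for cations (the
#' electron mass is subtracted per positive charge). The adduct may be a
#' name from [adduct_table()], a custom spec, or a neutral-loss-bearing
#' species built with `loss`.
#'
#' @param neutral Neutral molecule: a formula string/vector or a mass in Da.
#' @param adduct Adduct name (e.g. `"[M+H]+"`, `"[M+Na]+"`, `"[M]+"`) or a
#'   one-row data frame with columns `k`, `delta_mass`, `charge`.
#' @param loss Optional neutral loss applied to the ion: formula string or
#'   mass in Da (e.g. `"H2O"`, or `"C6H10O4"` for a deoxyhexose).
#' @param k Multimer factor override; defaults to the adduct's own `k`.
#' @param n_loss How many copies of `loss` depart (default 1).
#' @return m/z in Da (per unit charge).
#' @examples
#' ion_mz("C27H30O16", "[M+H]+")   # rutin, 611.1607
#' ion_mz("C27H30O16", "[M+Na]+")  # 633.1426
#' ion_mz("C7H6O4", "[M+H]+", loss = "H2O", k = 3, n_loss = 3) # DHB cluster 409.0554
#' @export
ion_mz <- function(neutral, adduct = "[M+H]+", loss = NULL, k = NULL, n_loss = 1) {
  m <- if (is.numeric(neutral) && is.null(names(neutral))) {
    if (length(neutral) != 1L || neutral <= 0) {
      stop("Neutral mass must be a single positive number.", call. = FALSE)
    }
    neutral
  } else {
    monoisotopic_mass(neutral)
  }
  if (is.character(adduct)) {
    tab <- adduct_table()
    row <- tab[tab$name == adduct, ]
    if (nrow(row) == 0L) {
      stop("Unknown adduct '", adduct, "'. See adduct_table().", call. = FALSE)
    }
  } else {
    row <- tibble::as_tibble(adduct)
    stopifnot(all(c("k", "delta_mass", "charge") %in% names(row)))
  }
  z <- row$charge[[1]]
  if (z == 0) stop("Ion charge must be non-zero.", call. = FALSE)
  kk <- if (is.null(k)) row$k[[1]] else k
  loss_mass <- 0
  if (!is.null(loss)) {
    loss_mass <- if (is.numeric(loss) && is.null(names(loss))) loss else monoisotopic_mass(loss)
  }
  (kk * m + row$delta_mass[[1]] - n_loss * loss_mass - sign(z) * abs(z) * ELECTRON_MASS) / abs(z)
}

#' Parts-per-million mass error
#'
#' @param observed,theoretical m/z values in Da.
#' @return Signed error in ppm.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
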