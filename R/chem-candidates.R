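#' Enumerate elemental formulas matching an accurate m/z
#'
#' Exhaustive search over per-element count bounds for singly charged
#' cation formulas whose theoretical m/z (formula mass minus one electron)
#' falls within `tol_ppm` of the query. Non-hydrogen counts are enumerated
#' and the hydrogen count is solved from the residual mass, so the search
#' cost is the product of the non-H ranges. Candidates are filtered by two
#' standard plausibility heuristics (both toggleable): ring-plus-double-bond
#' equivalents >= 0 and 0.2 <= H/C <= 3.1.
#'
#' @param mz Query m/z (Da), positive ion, charge +1.
#' @param tol_ppm Mass window in ppm (default 2).
#' @param bounds Named list of `c(min, max)` element count bounds, e.g.
#'   `list(C = c(0, 60), H = c(0, 120), O = c(0, 30))`. Elements not listed
#'   are excluded. H bounds cap the solved hydrogen count.
#' @param charge Ion charge; only +1 is supported.
#' @param rdbe_filter,hc_filter Apply the RDBE >= 0 and H/C ratio filters.
#' @param max_combinations Cap on the product of non-H ranges (default 1e6).
#' @return Tibble sorted by `|ppm|`: `formula`, element count columns,
#'   `mz_theoretical`, `ppm`, `rdbe`.
#' @examples
#' formula_candidates(611.1607, tol_ppm = 2,
#'   bounds = list(C = c(0, 40), H = c(0, 60), O = c(0, 20)))
#' @export
formula_candidates <- function(mz, tol_ppm = 2,
                               bounds = list(C = c(0, 60), H = c(0, 120),
                                             N = c(0, 5), O = c(0, 30)),
                               charge = 1L,
                               rdbe_filter = TRUE, hc_filter = TRUE,
                               max_combinations = 1e6) {
  if (charge != 1L) stop("Only charge +1 enumeration is supported.", call. = FALSE)
  stopifnot(mz > 0, tol_ppm > 0)
  unknown <- setdiff(names(bounds), names(ELEMENT_MASS))
  if (length(unknown)) {
    stop("Unknown element(s) in bounds: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  h_bounds <- bounds[["H"]] %||% c(0, 0)
  other <- bounds[names(bounds) != "H"]
  n_comb <- prod(vapply(other, function(b) b[2] - b[1] + 1, numeric(1)))
  if (n_comb > max_combinations) {
    stop("Search space (", format(n_comb, big.mark = ","),
         " non-H combinations) exceeds max_combinations; tighten the bounds.",
         call. = FALSE)
  }

  target <- mz + ELECTRON_MASS  # mass of the cation formula's atoms
  tol_da <- mz * tol_ppm / 1e6
  mH <- ELEMENT_MASS[["H"]]

  grid <- expand.grid(lapply(other, function(b) b[1]:b[2]))
  names(grid) <- names(other)
  heavy_mass <- as.numeric(as.matrix(grid) %*% ELEMENT_MASS[names(other)])
  resid <- target - heavy_mass

  out <- vector("list", 0L)
  # hydrogen counts bracketing the residual mass
  h_lo <- floor((resid - tol_da) / mH)
  h_hi <- ceiling((resid + tol_da) / mH)
  for (i in seq_len(nrow(grid))) {
    if (resid[i] < -tol_da) next
    for (h in max(h_lo[i], h_bounds[1]):min(h_hi[i], h_bounds[2])) {
      if (h < 0) next
      m_th <- heavy_mass[i] + h * mH
      err <- m_th - target
      if (abs(err) > tol_da) next
      counts <- c(as.list(grid[i, , drop = FALSE]), H = h)
      nC <- counts[["C"]] %||% 0
      nN <- counts[["N"]] %||% 0
      nP <- counts[["P"]] %||% 0
      nNa <- counts[["Na"]] %||% 0
      nK <- counts[["K"]] %||% 0
      # RDBE for the cation composition; monovalent Na/K count like H
      rdbe <- nC + 1 + (nN + nP) / 2 - (h + nNa + nK) / 2
      if (rdbe_filter && rdbe < 0) next
      if (hc_filter && nC > 0) {
        hc <- h / nC
        if (hc < 0.2 || hc > 3.1) next
      }
      if (hc_filter && nC == 0 && h > 0 && sum(unlist(counts)) == h) next
      out[[length(out) + 1L]] <- tibble::tibble(
        formula = format_formula(counts),
        !!!counts,
        mz_theoretical = m_th - ELECTRON_MASS,
        ppm = ppm_error(mz, m_th - ELECTRON_MASS),
        rdbe = rdbe
      )
    }
  }
  if (!length(out)) {
    empty <- tibble::tibble(formula = character(),
                            mz_theoretical = numeric(), ppm = numeric(),
                            rdbe = numeric())
    return(empty)
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, abs(.data$ppm))
}

# Hill-order formula string from a count list/vector (C, H, then alphabetical)
format_formula <- function(counts) {
  counts <- unlist(counts)
  counts <- counts[counts > 0]
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
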