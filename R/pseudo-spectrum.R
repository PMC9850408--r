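#' Build a pseudo-MS/MS spectrum from highly colocalized features
#'
#' Features whose PCC with the bait meets `threshold` (the bait's own
#' feature included, since it self-correlates at 1) become peaks; each
#' peak's intensity is the arithmetic mean of that feature's intensity
#' over the same pixel set used for the correlation. The result mimics a
#' low-collision-energy MS/MS spectrum of the bait and can be exported
#' with [export_spectrum()].
#'
#' @param dataset The [msi_dataset()] the correlation was computed on
#'   (checked by fingerprint).
#' @param result A `pica_coloc` from [colocalize()] on that dataset.
#' @param threshold PCC cutoff (inclusive; default 0.9).
#' @return A `pseudo_spectrum`: tibble with columns `mz`, `intensity`,
#'   `pcc`, sorted by m/z, with bait/threshold/provenance attributes.
#' @export
build_pseudo_spectrum <- function(dataset, result, threshold = 0.9) {
  stopifnot(inherits(dataset, "msi_dataset"), inherits(result, "pica_coloc"))
  if (!identical(result$dataset_id, dataset_id(dataset))) {
    stop("Provenance mismatch: this colocalization result was not computed ",
         "on the supplied dataset.", call. = FALSE)
  }
  hits <- result$entries[result$entries$pcc >= threshold, ]
  if (!nrow(hits)) {
    stop("No features reach PCC >= ", threshold,
         "; consider a lower threshold (max observed PCC = ",
         format(max(result$entries$pcc), digits = 4), ").", call. = FALSE)
  }
  idx <- match(hits$feature_mz, dataset$mz)
  mean_int <- colMeans(dataset$intensities[, idx, drop = FALSE])
  out <- tibble::tibble(mz = hits$feature_mz, intensity = as.numeric(mean_int),
                        pcc = hits$pcc)
  out <- out[order(out$mz), ]
  structure(out,
            bait_mz = result$bait$mz,
            threshold = threshold,
            n_pixels = result$n_pixels,
            dataset_id = result$dataset_id,
            tic_normalized = result$tic_normalized,
            class = c("pseudo_spectrum", class(out)))
}

#' @export
print.pseudo_spectrum <- function(x, ...) {
  cat(sprintf("<pseudo_spectrum> bait m/z %.4f, PCC >= %s, %d peaks (%d pixels)\n",
              attr(x, "bait_mz"), format(attr(x, "threshold")), nrow(x),
              attr(x, "n_pixels")))
  NextMethod()
}

#' Export a pseudo-spectrum to a spectral file format
#'
#' `"msp"` (NIST text library entry), `"mgf"` (Mascot generic format, one
#' BEGIN/END IONS block with `PEPMASS` = bait m/z), or `"csv"` (columns
#' `mz`, `intensity`, `pcc`; round-trips exactly via [read_spectrum_csv()]).
#' Values are written at full double precision.
#'
#' @param spectrum A `pseudo_spectrum`.
#' @param path Output path.
#' @param format `"msp"`, `"mgf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_spectrum <- function(spectrum, path, format = c("msp", "mgf", "csv")) {
  stopifnot(inherits(spectrum, "pseudo_spectrum"), nrow(spectrum) >= 1L)
  format <- match.arg(format)
  bait <- attr(spectrum, "bait_mz")
  fmt <- function(v) sprintf("%.17g", v)
  lines <- switch(
    format,
    msp = c(
      sprintf("Name: pseudo-MS/MS of m/z %.4f", bait),
      sprintf("PrecursorMZ: %s", fmt(bait)),
      sprintf("Comment: PCC>=%s", format(attr(spectrum, "threshold"))),
      sprintf("Num Peaks: %d", nrow(spectrum)),
      sprintf("%s %s", fmt(spectrum$mz), fmt(spectrum$intensity)),
      ""
    ),
    mgf = c(
      "BEGIN IONS",
      sprintf("TITLE=pseudo-MS/MS of m/z %.4f", bait),
      sprintf("PEPMASS=%s", fmt(bait)),
      "CHARGE=1+",
      sprintf("%s %s", fmt(spectrum$mz), fmt(spectrum$intensity)),
      "END IONS"
    ),
    csv = NULL
  )
  if (format == "csv") {
    readr::write_csv(tibble::tibble(mz = spectrum$mz,
                                    intensity = spectrum$intensity,
                                    pcc = spectrum$pcc), path)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Re-import a CSV pseudo-spectrum
#'
#' @param path CSV written by [export_spectrum()].
#' @return Tibble with `mz`, `intensity`, `pcc`.
#' @export
read_spectrum_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @export
autoplot.pseudo_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(
      title = sprintf("Pseudo-MS/MS of m/z %.4f (PCC >= %s)",
                      attr(object, "bait_mz"),
                      format(attr(object, "threshold"))),
      x = "m/z", y = "mean intensity") +
    ggplot2::theme_minimal()
}
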