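#' Total-ion-current normalization
#'
#' Scales each pixel's spectrum so its summed intensity (TIC) equals a
#' common target, correcting pixel-to-pixel ionization variation. Zero-TIC
#' pixels are kept (as zeros) so pixel indexing stays stable; their count
#' is recorded in the metadata.
#'
#' @param dataset An [msi_dataset()].
#' @param target `"mean"` (default: mean TIC of pixels with signal) or a
#'   fixed positive number.
#' @return A TIC-normalized `msi_dataset` (idempotent under
#'   re-application).
#' @examples
#' d <- msi_dataset(data.frame(x = 1:2, y = c(1L, 1L)),
#'                  rbind(c(1, 1), c(2, 2)), mz = c(100, 200))
#' tic_normalize(d)$intensities
#' @export
tic_normalize <- function(dataset, target = "mean") {
  stopifnot(inherits(dataset, "msi_dataset"))
  tic <- rowSums(dataset$intensities)
  nz <- tic > 0
  if (!any(nz)) stop("All pixels have zero TIC; nothing to normalize.", call. = FALSE)
  tgt <- if (identical(target, "mean")) mean(tic[nz]) else {
    stopifnot(is.numeric(target), length(target) == 1L, target > 0)
    target
  }
  scale <- ifelse(nz, tgt / tic, 0)
  out <- dataset
  out$intensities <- dataset$intensities * scale
  out$metadata$tic_normalized <- TRUE
  out$metadata$tic_target <- tgt
  out$metadata$zero_tic_pixels <- sum(!nz)
  out
}

#' Pick peaks from the dataset's mean spectrum
#'
#' Detects local maxima on the mean spectrum over all pixels and keeps
#' those whose height exceeds `snr_min` times the noise level. Noise is
#' estimated robustly as 1.4826 x the median absolute deviation of the
#' mean spectrum (MAD scaled to Gaussian sigma).
#'
#' @param dataset An [msi_dataset()] on a shared (continuous) axis.
#' @param snr_min Minimum signal-to-noise ratio (default 6).
#' @return Tibble of candidate features: `mz`, `mean_intensity`, `snr`,
#'   sorted by m/z. Empty (with a warning) for a flat spectrum.
#' @export
pick_peaks <- function(dataset, snr_min = 6) {
  stopifnot(inherits(dataset, "msi_dataset"), snr_min > 0)
  s <- colMeans(dataset$intensities)
  noise <- 1.4826 * stats::mad(s, constant = 1)
  if (noise == 0 && all(s == 0)) {
    warning("Flat spectrum: no signal, no noise; returning no peaks.")
    return(tibble::tibble(mz = numeric(), mean_intensity = numeric(),
                          snr = numeric()))
  }
  n <- length(s)
  is_max <- rep(TRUE, n)
  if (n > 1) {
    left <- c(Inf, s[-n]); right <- c(s[-1], Inf)
    is_max <- s > left & s >= right
    is_max[1] <- s[1] > right[1]
    is_max[n] <- s[n] > left[n]
  }
  snr <- if (noise > 0) s / noise else ifelse(s > 0, Inf, 0)
  keep <- is_max & snr >= snr_min
  tibble::tibble(mz = dataset$mz[keep], mean_intensity = s[keep],
                 snr = snr[keep])
}

#' Recalibrate the m/z axis against known reference masses
#'
#' Matches each reference to the nearest axis feature within its search
#' window and fits a mass-dependent correction from observed to true m/z:
#' a constant offset for a single reference, a linear map (offset + slope,
#' absorbing ppm-proportional drift) for two or more. The fitted map is
#' applied to the whole axis and the per-reference residuals are recorded
#' in the metadata.
#'
#' @param dataset An [msi_dataset()].
#' @param refs Data frame with columns `mz` (true m/z of a known internal
#'   calibrant) and optionally `tol` (match half-window in Da, default
#'   0.05).
#' @return Recalibrated `msi_dataset`; `metadata$recalibration` holds the
#'   matched references and residuals.
#' @export
recalibrate <- function(dataset, refs, tol = 0.05) {
  stopifnot(inherits(dataset, "msi_dataset"))
  refs <- tibble::as_tibble(refs)
  stopifnot("mz" %in% names(refs))
  if (!"tol" %in% names(refs)) refs$tol <- tol
  obs <- rep(NA_real_, nrow(refs))
  for (i in seq_len(nrow(refs))) {
    d <- abs(dataset$mz - refs$mz[i])
    j <- which.min(d)
    if (length(j) && d[j] <= refs$tol[i]) obs[i] <- dataset$mz[j]
  }
  matched <- !is.na(obs)
  if (!any(matched)) {
    stop("No reference matched the axis. Windows searched: ",
         paste(sprintf("%.4f±%.3f", refs$mz, refs$tol), collapse = ", "),
         call. = FALSE)
  }
  o <- obs[matched]; t <- refs$mz[matched]
  if (sum(matched) == 1L) {
    offset <- t - o
    new_axis <- dataset$mz + offset
    fit <- c(intercept = offset, slope = 1)
  } else {
    lmfit <- stats::lm(t ~ o)
    new_axis <- as.numeric(stats::coef(lmfit)[1] + stats::coef(lmfit)[2] * dataset$mz)
    fit <- c(intercept = unname(stats::coef(lmfit)[1]),
             slope = unname(stats::coef(lmfit)[2]))
  }
  resid <- (fit[["intercept"]] + fit[["slope"]] * o) - t
  out <- dataset
  out$mz <- new_axis
  out$metadata$recalibration <- list(
    refs = tibble::tibble(true_mz = t, observed_mz = o, residual = resid),
    fit = fit
  )
  out
}
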