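#' Construct an MSI dataset
#'
#' The central in-memory container: a pixels-by-features intensity matrix
#' with a shared, ascending m/z axis and integer grid coordinates per
#' pixel. Rows follow acquisition order.
#'
#' @param coords Data frame with integer columns `x`, `y` (1-based grid
#'   indices), one row per pixel, in acquisition order.
#' @param intensities Numeric matrix, `nrow(coords)` x `length(mz)`,
#'   non-negative and finite.
#' @param mz Strictly ascending numeric vector of feature m/z (Da).
#' @param metadata Optional named list (source file, normalization state...).
#' @return An object of class `msi_dataset`.
#' @examples
#' d <- msi_dataset(data.frame(x = 1:2, y = c(1L, 1L)),
#'                  matrix(1:4, 2), mz = c(100, 200))
#' d
#' @export
msi_dataset <- function(coords, intensities, mz, metadata = list()) {
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  coords$x <- as.integer(coords$x)
  coords$y <- as.integer(coords$y)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(coords) != nrow(intensities)) {
    stop("coords and intensity rows disagree: ", nrow(coords), " vs ",
         nrow(intensities), " pixels.", call. = FALSE)
  }
  if (length(mz) != ncol(intensities)) {
    stop("mz axis and intensity columns disagree: ", length(mz), " vs ",
         ncol(intensities), " features.", call. = FALSE)
  }
  if (length(mz) && (any(diff(mz) <= 0) || any(mz <= 0))) {
    stop("mz axis must be strictly ascending and positive.", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("Intensities must be finite and non-negative.", call. = FALSE)
  }
  if (anyDuplicated(coords[c("x", "y")])) {
    stop("Pixel coordinates must be unique.", call. = FALSE)
  }
  dimnames(intensities) <- NULL
  structure(
    list(coords = coords, intensities = intensities, mz = as.numeric(mz),
         pixel_order = seq_len(nrow(coords)), metadata = metadata),
    class = "msi_dataset"
  )
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat("<msi_dataset> ", n_pixels(x), " pixels x ", n_features(x), " features\n",
      sep = "")
  if (n_features(x)) {
    cat("  m/z range: ", format(min(x$mz), digits = 8), " - ",
        format(max(x$mz), digits = 8), " Da\n", sep = "")
  }
  cat("  grid: x 1..", max(x$coords$x), ", y 1..", max(x$coords$y), "\n", sep = "")
  if (isTRUE(x$metadata$tic_normalized)) cat("  TIC-normalized\n")
  invisible(x)
}

#' Pixel and feature counts
#' @param dataset An `msi_dataset`.
#' @return Integer count.
#' @export
n_pixels <- function(dataset) nrow(dataset$intensities)

#' @rdname n_pixels
#' @export
n_features <- function(dataset) ncol(dataset$intensities)

#' Feature summary table of a dataset
#'
#' @param x An `msi_dataset`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `mz`, `mean_intensity`,
#'   `nonzero_pixels`.
#' @export
tidy.msi_dataset <- function(x, ...) {
  tibble::tibble(
    mz = x$mz,
    mean_intensity = colMeans(x$intensities),
    nonzero_pixels = colSums(x$intensities > 0)
  )
}

#' One-row dataset summary
#' @inheritParams tidy.msi_dataset
#' @return One-row tibble: pixel/feature counts, m/z range, TIC stats.
#' @export
glance.msi_dataset <- function(x, ...) {
  tic <- rowSums(x$intensities)
  tibble::tibble(
    n_pixels = n_pixels(x), n_features = n_features(x),
    mz_min = if (n_features(x)) min(x$mz) else NA_real_,
    mz_max = if (n_features(x)) max(x$mz) else NA_real_,
    median_tic = stats::median(tic),
    zero_tic_pixels = sum(tic == 0),
    tic_normalized = isTRUE(x$metadata$tic_normalized)
  )
}

# light internal fingerprint used for provenance checks
dataset_id <- function(dataset) {
  paste(n_pixels(dataset), n_features(dataset),
        format(sum(dataset$intensities), digits = 12),
        format(sum(dataset$mz), digits = 12), sep = "/")
}
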