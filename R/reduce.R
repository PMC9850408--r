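# Computation-reduction strategies: PICA cost scales as
# (number of features) x (number of pixels), so cutting either axis cuts
# run time proportionally without touching the PCC of what survives.

#' Drop features above a mass cutoff
#'
#' Small metabolites are overwhelmingly singly charged in MALDI, so
#' fragments of a precursor all fall below it in m/z; restricting the
#' axis to `mz <= max_mz` keeps every fragment while shrinking the
#' feature space. The PCC of surviving features is unchanged (column
#' selection is correlation-neutral).
#'
#' @param dataset An [msi_dataset()].
#' @param max_mz Inclusive upper mass bound (Da).
#' @return Reduced `msi_dataset`; `metadata$feature_reduction` records the
#'   before/after counts.
#' @seealso [bait_cutoff()] for the recommended cutoff given a bait.
#' @export
reduce_features <- function(dataset, max_mz) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (max_mz < min(dataset$mz)) {
    stop("No features at or below m/z ", format(max_mz), ".", call. = FALSE)
  }
  keep <- dataset$mz <= max_mz
  out <- dataset
  out$mz <- dataset$mz[keep]
  out$intensities <- dataset$intensities[, keep, drop = FALSE]
  out$metadata$feature_reduction <- list(
    max_mz = max_mz, before = n_features(dataset), after = sum(keep))
  out
}

#' Default mass cutoff for a bait
#'
#' `bait m/z + 40 Da`: wide enough that K+ adducts of the bait
#' (+37.956 Da relative to the protonated species) stay in range.
#'
#' @param bait_mz Bait ion m/z (Da).
#' @return Cutoff in Da.
#' @examples
#' bait_cutoff(611.161)  # 651.161, retains [M+Na]+ 633.14 and [M+K]+ 649.12
#' @export
bait_cutoff <- function(bait_mz) bait_mz + 40

#' Keep every nth pixel
#'
#' Retains pixels at acquisition-order positions 1, 1+n, 1+2n, ...; the
#' result has `ceiling(n_pixels / n)` pixels. Metabolite distributions
#' span many pixels, so a regular thinning preserves the spatial
#' correlation structure while dividing the correlation cost by `n`.
#'
#' @param dataset An [msi_dataset()].
#' @param n Subsampling stride (>= 1; `n = 1` is the identity).
#' @return Subsampled `msi_dataset`.
#' @examples
#' d <- msi_dataset(data.frame(x = 1:5, y = rep(1L, 5)),
#'                  matrix(1:5), mz = 100)
#' n_pixels(subsample_pixels(d, 2))  # 3
#' @export
subsample_pixels <- function(dataset, n) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be an integer >= 1.", call. = FALSE)
  }
  keep <- seq.int(1L, n_pixels(dataset), by = n)
  out <- dataset
  out$coords <- dataset$coords[keep, ]
  out$intensities <- dataset$intensities[keep, , drop = FALSE]
  out$pixel_order <- dataset$pixel_order[keep]
  out$metadata$pixel_subsampling <- list(every_n = n, kept = length(keep))
  out
}

parse_roi_rect <- function(roi) {
  # "x1:x2,y1:y2"
  m <- regmatches(roi, regexec(
    "^\\s*(\\d+)\\s*:\\s*(\\d+)\\s*,\\s*(\\d+)\\s*:\\s*(\\d+)\\s*$", roi))[[1]]
  if (length(m) != 5L) {
    stop("Cannot parse ROI rectangle '", roi, "'; expected \"x1:x2,y1:y2\".",
         call. = FALSE)
  }
  v <- as.integer(m[-1])
  list(x = sort(v[1:2]), y = sort(v[3:4]))
}

point_in_polygon <- function(px, py, vx, vy) {
  # even-odd rule, boundary-inclusive
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary test: point on segment
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    within <- pmin(x1, x2) - 1e-9 <= px & px <= pmax(x1, x2) + 1e-9 &
      pmin(y1, y2) - 1e-9 <= py & py <= pmax(y1, y2) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    # even-odd crossing test
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Restrict a dataset to a region of interest
#'
#' Keeps pixels whose coordinates fall inside the ROI. Three ROI forms are
#' accepted: a rectangle string `"x1:x2,y1:y2"` (bounds inclusive), a
#' polygon given as a data frame with vertex columns `x`, `y`
#' (boundary-inclusive even-odd rule), or an integer vector of pixel
#' indices in acquisition order.
#'
#' @param dataset An [msi_dataset()].
#' @param roi Rectangle string, polygon data frame, or pixel index vector.
#' @return Filtered `msi_dataset`. Errors if the ROI selects no pixels.
#' @examples
#' d <- simulate_msi(sim_config(grid = c(10, 10), seed = 1))$dataset
#' n_pixels(roi_filter(d, "1:5,1:10"))  # 50
#' @export
roi_filter <- function(dataset, roi) {
  stopifnot(inherits(dataset, "msi_dataset"))
  cx <- dataset$coords$x; cy <- dataset$coords$y
  keep <- if (is.character(roi) && length(roi) == 1L) {
    r <- parse_roi_rect(roi)
    cx >= r$x[1] & cx <= r$x[2] & cy >= r$y[1] & cy <= r$y[2]
  } else if (is.data.frame(roi)) {
    stopifnot(all(c("x", "y") %in% names(roi)), nrow(roi) >= 3L)
    point_in_polygon(cx, cy, roi$x, roi$y)
  } else if (is.numeric(roi)) {
    idx <- as.integer(roi)
    if (any(idx < 1L | idx > n_pixels(dataset))) {
      stop("Pixel indices out of range.", call. = FALSE)
    }
    seq_len(n_pixels(dataset)) %in% idx
  } else {
    stop("Unsupported ROI specification.", call. = FALSE)
  }
  if (!any(keep)) stop("ROI does not intersect the pixel grid.", call. = FALSE)
  out <- dataset
  out$coords <- dataset$coords[keep, ]
  out$intensities <- dataset$intensities[keep, , drop = FALSE]
  out$pixel_order <- dataset$pixel_order[keep]
  out$metadata$roi <- list(kept = sum(keep), of = n_pixels(dataset))
  out
}
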