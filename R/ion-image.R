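#' Extract an ion image
#'
#' Per pixel, sums the intensities of all features whose m/z lies within
#' `mz ± tol` — the exact-mass, fixed-bin-width convention used for MALDI
#' image display (default half-window 0.003 Da).
#'
#' @param dataset An [msi_dataset()].
#' @param mz Query m/z (Da).
#' @param tol Half-window in Da (> 0; default 0.003).
#' @return An `ion_image`: tibble with columns `x`, `y`, `intensity` (one
#'   row per pixel, acquisition order), with attributes `mz` and `tol`.
#'   All-zero with a warning when no feature falls in the window.
#' @examples
#' d <- msi_dataset(data.frame(x = 1:2, y = c(1L, 1L)),
#'                  rbind(c(1, 5), c(2, 6)), mz = c(100, 200))
#' extract_ion_image(d, 200)
#' @export
extract_ion_image <- function(dataset, mz, tol = 0.003) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("`tol` must be a positive half-window in Da.", call. = FALSE)
  }
  sel <- dataset$mz >= mz - tol & dataset$mz <= mz + tol
  vals <- if (!any(sel)) {
    warning("No feature within ", format(mz), " ± ", format(tol),
            " Da; returning an all-zero image.")
    rep(0, n_pixels(dataset))
  } else if (sum(sel) == 1L) {
    dataset$intensities[, sel]
  } else {
    rowSums(dataset$intensities[, sel, drop = FALSE])
  }
  out <- tibble::tibble(x = dataset$coords$x, y = dataset$coords$y,
                        intensity = as.numeric(vals))
  structure(out, mz = mz, tol = tol, n_features_in_window = sum(sel),
            class = c("ion_image", class(out)))
}

ion_image_matrix <- function(image) {
  w <- max(image$x); h <- max(image$y)
  if (anyDuplicated(cbind(image$x, image$y))) {
    stop("Coordinates do not form a grid (duplicated positions).", call. = FALSE)
  }
  m <- matrix(0, nrow = h, ncol = w)
  m[cbind(image$y, image$x)] <- image$intensity
  m
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 2-D Gaussian blur with reflected edges
blur_matrix <- function(m, sigma = 1) {
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))  # replicate-edge padding
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(t(m2), 2, pad_conv))
}

#' Render an ion image to a PNG raster
#'
#' Maps the pixel grid to a grayscale raster, optionally applying Gaussian
#' smoothing (sigma = 1 pixel) and contrast enhancement (clipping at the
#' 2nd/98th intensity percentiles before scaling). Deterministic for a
#' fixed input.
#'
#' @param image An `ion_image` from [extract_ion_image()].
#' @param path Output PNG path.
#' @param smoothing,contrast Logical toggles.
#' @return `path`, invisibly. The rendered matrix is attached as attribute
#'   `"raster"` for inspection.
#' @export
render_ion_image <- function(image, path, smoothing = TRUE, contrast = TRUE) {
  m <- ion_image_matrix(image)
  if (smoothing) m <- blur_matrix(m, sigma = 1)
  if (contrast) {
    qs <- stats::quantile(m, c(0.02, 0.98), names = FALSE)
    m <- pmin(pmax(m, qs[1]), qs[2])
  }
  rng <- range(m)
  norm <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else matrix(0, nrow(m), ncol(m))
  png::writePNG(norm, target = path)
  invisible(structure(path, raster = m))
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.ion_image <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("m/z %.4f ± %.3f", attr(object, "mz"),
                      attr(object, "tol")),
      x = "x", y = "y") +
    ggplot2::theme_minimal()
}
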