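#' Pearson correlation of two pixel-intensity vectors
#'
#' The colocalization metric: `sum((x-mean(x))(y-mean(y))) /
#' sqrt(sum((x-mean(x))^2) * sum((y-mean(y))^2))`. When either vector has
#' zero variance the coefficient is undefined; `NA` is returned (never an
#' error), so constant features can be flagged rather than crash a run.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' pcc(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) {
    stop("Vectors differ in length: ", length(x), " vs ", length(y), call. = FALSE)
  }
  if (length(x) < 2L) stop("Need at least 2 pixels.", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  vx <- sum(dx * dx); vy <- sum(dy * dy)
  if (vx == 0 || vy == 0) return(NA_real_)
  r <- sum(dx * dy) / sqrt(vx * vy)
  max(-1, min(1, r))
}

#' Colocalize a bait ion against every mass feature
#'
#' The core PICA operation. The bait's ion image (binned window
#' `mz ± tol`, as for display) is correlated pixel-by-pixel against every
#' feature column of the dataset; features are ranked by descending PCC
#' and the top `top_n` retained. Zero-variance (undefined-PCC) features
#' are excluded from the ranking but counted. Ties at the `top_n` boundary
#' break by ascending m/z, so results are deterministic.
#'
#' @param dataset A TIC-normalized [msi_dataset()] (a warning is issued
#'   otherwise).
#' @param bait_mz Bait ion m/z (Da). Must match at least one feature
#'   within `tol`.
#' @param tol Bait match half-window in Da (default 0.003).
#' @param top_n Number of top-ranked features to keep (default 100).
#' @param label Optional free-text bait label.
#' @return A `pica_coloc` object. [tidy()] returns the ranked entries
#'   (`feature_mz`, `pcc`); [glance()] a one-row summary.
#' @examples
#' d <- msi_dataset(data.frame(x = 1:4, y = rep(1L, 4)),
#'                  cbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1)),
#'                  mz = c(100, 150, 200))
#' coloc <- colocalize(tic_normalize(d), bait_mz = 100)
#' tidy(coloc)
#' @export
colocalize <- function(dataset, bait_mz, tol = 0.003, top_n = 100,
                       label = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"), bait_mz > 0, tol > 0, top_n >= 1)
  if (!isTRUE(dataset$metadata$tic_normalized)) {
    warning("Dataset is not TIC-normalized; PCC values will reflect raw ",
            "pixel-to-pixel ionization variation.")
  }
  sel <- abs(dataset$mz - bait_mz) <= tol
  if (!any(sel)) {
    nearest <- dataset$mz[which.min(abs(dataset$mz - bait_mz))]
    stop(sprintf(
      "No feature within %.4f ± %.3f Da; nearest feature is m/z %.4f.",
      bait_mz, tol, nearest), call. = FALSE)
  }
  bait_img <- extract_ion_image(dataset, bait_mz, tol)
  b <- bait_img$intensity

  X <- dataset$intensities
  n <- nrow(X)
  db <- b - mean(b)
  vb <- sum(db * db)
  if (vb == 0) {
    stop("Bait image has zero variance; PCC is undefined everywhere.",
         call. = FALSE)
  }
  Xc <- sweep(X, 2, colMeans(X))
  cross <- as.numeric(crossprod(Xc, db))
  vx <- as.numeric(colSums(Xc^2))
  r <- ifelse(vx > 0, cross / sqrt(vx * vb), NA_real_)
  r <- pmax(-1, pmin(1, r))
  # BLAS accumulation can leave exact self/scaled correlations 1 ulp shy of
  # +-1; snap so documented ties (e.g. bait vs its own feature) are exact
  r[!is.na(r) & abs(r - 1) < 1e-13] <- 1
  r[!is.na(r) & abs(r + 1) < 1e-13] <- -1

  entries <- tibble::tibble(feature_mz = dataset$mz, pcc = r)
  defined <- entries[!is.na(entries$pcc), ]
  defined <- defined[order(-defined$pcc, defined$feature_mz), ]
  kept <- utils::head(defined, top_n)

  structure(
    list(
      bait = list(mz = bait_mz, tol = tol, label = label),
      entries = kept,
      top_n = top_n,
      n_features = n_features(dataset),
      n_pixels = n,
      n_undefined = sum(is.na(r)),
      dataset_id = dataset_id(dataset),
      tic_normalized = isTRUE(dataset$metadata$tic_normalized)
    ),
    class = "pica_coloc"
  )
}

#' @export
print.pica_coloc <- function(x, ...) {
  cat(sprintf("<pica_coloc> bait m/z %.4f (±%.3f Da)\n", x$bait$mz, x$bait$tol))
  cat(sprintf("  %d pixels, %d features (%d undefined PCC), top %d kept\n",
              x$n_pixels, x$n_features, x$n_undefined, x$top_n))
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' @rdname colocalize
#' @param x A `pica_coloc` object.
#' @param ... Unused.
#' @export
tidy.pica_coloc <- function(x, ...) x$entries

#' @rdname colocalize
#' @export
glance.pica_coloc <- function(x, ...) {
  tibble::tibble(
    bait_mz = x$bait$mz, n_pixels = x$n_pixels, n_features = x$n_features,
    n_ranked = nrow(x$entries), n_undefined = x$n_undefined,
    max_pcc = max(x$entries$pcc), tic_normalized = x$tic_normalized
  )
}

#' Classify colocalized features into PCC bands
#'
#' Partitions the ranked entries into `high` (PCC >= `high`, the
#' pseudo-MS/MS construction set), `moderate` (`moderate_low` <= PCC <
#' `high`, candidate structurally related ions) and `other`. Thresholds
#' are per-analysis choices; 0.9/0.6 are the customary defaults.
#'
#' @param result A `pica_coloc` object or a data frame with a `pcc` column.
#' @param high High-colocalization cutoff (default 0.9, inclusive).
#' @param moderate_low Lower edge of the moderate band (default 0.6,
#'   inclusive).
#' @return Tibble of the entries with an added `band` factor
#'   (`high`/`moderate`/`other`); exhaustive and disjoint over defined
#'   entries.
#' @examples
#' classify_bands(data.frame(feature_mz = 1:4, pcc = c(1, .96, .82, .5)))
#' @export
classify_bands <- function(result, high = 0.9, moderate_low = 0.6) {
  stopifnot(moderate_low < high, high <= 1, moderate_low >= -1)
  entries <- if (inherits(result, "pica_coloc")) result$entries
             else tibble::as_tibble(result)
  stopifnot("pcc" %in% names(entries))
  entries$band <- factor(
    ifelse(entries$pcc >= high, "high",
           ifelse(entries$pcc >= moderate_low, "moderate", "other")),
    levels = c("high", "moderate", "other")
  )
  attr(entries, "thresholds") <- c(high = high, moderate_low = moderate_low)
  entries
}

#' @export
autoplot.pica_coloc <- function(object, high = 0.9, moderate_low = 0.6, ...) {
  df <- classify_bands(object, high = high, moderate_low = moderate_low)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pcc,
                                   colour = .data$band)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(high, moderate_low), linetype = 3) +
    ggplot2::labs(
      title = sprintf("Colocalization with bait m/z %.4f", object$bait$mz),
      x = "rank", y = "PCC") +
    ggplot2::theme_minimal()
}
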