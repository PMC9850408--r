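# Ground-truth MSI simulator. Emulates the phenomena PICA exploits or must
# survive: a skin-localized metabolite whose in-source fragments, isotopes,
# alkali adducts and dimer are pixel-wise proportional to it; a second
# metabolite confined to the flesh; matrix cluster ions enriched on the
# bare slide and depleted over tissue (the matrix is absorbed by porous
# tissue); a constant-intensity co-occurring artifact (co-occurrence
# without correlation); and multiplicative log-normal pixel noise.

#' Simulation configuration
#'
#' Defaults describe a small "tomato-like" section: a rectangular grid
#' whose outer margin is bare slide, a skin band just inside it, and
#' flesh in the interior. The default bait is a rutin-like flavonoid
#' ([M+H]+ 611.1607) in the skin with two glycosidic in-source fragments
#' (deoxyhexose and rutinosyl losses), Na+/K+ adducts, 13C isotopes and a
#' [2M+H]+ dimer; a hexose occupies the flesh; three DHB cluster ions sit
#' on the slide; feature 888.888 is a constant-on-mask artifact.
#'
#' @param grid `c(width, height)` in pixels (>= 2x2).
#' @param slide_margin Bare-slide border thickness, pixels.
#' @param skin_thickness Skin band thickness, pixels.
#' @param metabolites List of metabolite specs; see the default for the
#'   shape (`formula`, `region`, `base`, `adducts` named fractions,
#'   `fragments` list of `loss`/`yield`, `multimer_k`/`multimer_frac`,
#'   `isotope_depth`).
#' @param matrix_species List: `formula`, cluster sizes `k`, per-cluster
#'   water losses, `base`, `tissue_factor` (matrix signal retained over
#'   tissue, < 1 = depletion).
#' @param artifact List: `mz`, `value`, or `NULL` for none. The artifact
#'   is constant on the pixels occupied by the first metabolite.
#' @param noise_sigma Log-normal sigma of multiplicative pixel noise
#'   (default 0.2).
#' @param noise_floor Scale of additive non-negative baseline noise
#'   (default 0 = off).
#' @param field_smooth Gaussian smoothing sigma (pixels) of the spatial
#'   abundance field (default 3).
#' @param field_log_sd Log-scale SD of the abundance field (default 0.5).
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid = c(32, 32),
                       slide_margin = 2,
                       skin_thickness = 3,
                       metabolites = NULL,
                       matrix_species = NULL,
                       artifact = list(mz = 888.888, value = 500),
                       noise_sigma = 0.2,
                       noise_floor = 0,
                       field_smooth = 3,
                       field_log_sd = 0.5,
                       seed = 1L) {
  if (is.null(metabolites)) {
    metabolites <- list(
      rutin = list(
        formula = "C27H30O16", region = "skin", base = 100,
        adducts = c(H = 1, Na = 0.25, K = 0.08),
        fragments = list(
          list(loss = "C6H10O4", yield = 0.4),   # deoxyhexose -> m/z 465.103
          list(loss = "C12H20O9", yield = 0.6)   # rutinosyl -> aglycone 303.050
        ),
        multimer_k = 2L, multimer_frac = 0.03,
        isotope_depth = 2L
      ),
      hexose = list(
        formula = "C6H12O6", region = "flesh", base = 60,
        adducts = c(H = 1, Na = 0.3),
        fragments = list(list(loss = "H2O", yield = 0.3)),
        multimer_k = 0L, multimer_frac = 0,
        isotope_depth = 1L
      )
    )
  }
  if (is.null(matrix_species)) {
    matrix_species <- list(formula = "C7H6O4", k = 1:3, base = 200,
                           tissue_factor = 0.2)
  }
  stopifnot(length(grid) == 2L, all(grid >= 2), noise_sigma >= 0,
            noise_floor >= 0)
  for (m in metabolites) {
    stopifnot(all(m$adducts >= 0 & m$adducts <= 1),
              all(vapply(m$fragments, function(f) f$yield, numeric(1)) >= 0),
              all(vapply(m$fragments, function(f) f$yield, numeric(1)) <= 1))
  }
  structure(list(grid = grid, slide_margin = slide_margin,
                 skin_thickness = skin_thickness, metabolites = metabolites,
                 matrix_species = matrix_species, artifact = artifact,
                 noise_sigma = noise_sigma, noise_floor = noise_floor,
                 field_smooth = field_smooth, field_log_sd = field_log_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

region_masks <- function(config) {
  w <- config$grid[1]; h <- config$grid[2]
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  edge <- pmin(xs - 1L, ys - 1L, w - xs, h - ys)  # distance to border
  slide <- edge < config$slide_margin
  skin <- !slide & edge < config$slide_margin + config$skin_thickness
  flesh <- !slide & !skin
  list(coords = tibble::tibble(x = xs, y = ys),
       slide = slide, skin = skin, flesh = flesh)
}

# seeded Gaussian random field: grid white noise, separable Gaussian blur,
# standardized, exponentiated -> positive, spatially autocorrelated
random_field <- function(w, h, smooth_sigma, log_sd) {
  z <- matrix(stats::rnorm(w * h), nrow = h, ncol = w)
  z <- blur_matrix(z, sigma = smooth_sigma)
  z <- (z - mean(z)) / stats::sd(z)
  exp(log_sd * z)
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# element-count arithmetic for deriving ion compositions
counts_add <- function(a, b, mult = 1) {
  all_el <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(all_el)), all_el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + mult * b
  if (any(out < 0)) stop("Negative element count in derived composition.",
                         call. = FALSE)
  out[out > 0]
}

#' Simulate an MSI dataset with known ground truth
#'
#' Per pixel p and metabolite m, abundance `A(m, p) = base x smooth
#' seeded random field x region mask`; every derived ion (fragment,
#' adduct, isotope, multimer) has noise-free intensity proportional to
#' `A(m, p)`, so all ions of one metabolite are pixel-wise proportional —
#' the property PICA detects. Observed intensity multiplies in log-normal
#' noise (`exp(rnorm(0, sigma))`) and optionally adds a non-negative
#' baseline. Feature m/z values come from [ion_mz()] and isotope
#' intensities from [isotope_pattern()], so the generator and the
#' annotator share one chemistry source. Bit-reproducible for a fixed
#' seed; the caller's RNG state is preserved.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (an [msi_dataset()]) and `ground_truth`
#'   (tibble: `mz`, `parent`, `relation`
#'   (`precursor|fragment|adduct|multimer|isotope|matrix|artifact`),
#'   `region`, `detail`). A warning is issued when two generated features
#'   sit closer than 1 mDa (intentional collision testing is allowed).
#' @examples
#' sim <- simulate_msi(sim_config(seed = 42))
#' sim$dataset
#' head(sim$ground_truth)
#' @export
simulate_msi <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_rng(config$seed, {
    masks <- region_masks(config)
    w <- config$grid[1]; h <- config$grid[2]
    np <- w * h
    coords <- masks$coords
    pix_idx <- cbind(coords$y, coords$x)  # matrix is h x w

    features <- list()  # each: mz, noise_free vector, gt row
    add_feature <- function(mz, values, parent, relation, region, detail) {
      features[[length(features) + 1L]] <<- list(
        mz = mz, values = values,
        gt = tibble::tibble(mz = mz, parent = parent, relation = relation,
                            region = region, detail = detail))
    }

    proton_ion <- function(counts) counts_add(counts, c(H = 1))

    for (name in names(config$metabolites)) {
      m <- config$metabolites[[name]]
      fld <- random_field(w, h, config$field_smooth, config$field_log_sd)
      A <- m$base * fld[pix_idx] * as.numeric(masks[[m$region]])
      counts <- parse_formula(m$formula)

      emit_with_isotopes <- function(ion_counts, intensity, relation, detail) {
        mz0 <- (sum(ion_counts * ELEMENT_MASS[names(ion_counts)]) -
                  ELECTRON_MASS)
        add_feature(mz0, intensity, name, relation, m$region, detail)
        depth <- m$isotope_depth %||% 0L
        if (depth > 0L) {
          pat <- isotope_pattern(ion_counts, n_peaks = depth + 1L)
          for (k in seq_len(depth)) {
            ab <- pat$abundance[k + 1L]
            if (ab <= 0) next
            add_feature(mz0 + k * C13_DELTA, intensity * ab, name, "isotope",
                        m$region, sprintf("13C%d of %s", k, detail))
          }
        }
      }

      f_H <- m$adducts[["H"]] %||% 0
      # protonated precursor and its fragments
      if (f_H > 0) {
        ionc <- proton_ion(counts)
        emit_with_isotopes(ionc, A * f_H, "precursor", "[M+H]+")
        for (fr in m$fragments) {
          loss_counts <- parse_formula(fr$loss)
          frag_counts <- counts_add(ionc, loss_counts, mult = -1)
          emit_with_isotopes(frag_counts, A * f_H * fr$yield, "fragment",
                             sprintf("[M+H-%s]+", fr$loss))
        }
      }
      for (cation in intersect(names(m$adducts), c("Na", "K"))) {
        frac <- m$adducts[[cation]]
        if (frac <= 0) next
        ionc <- counts_add(counts, stats::setNames(1, cation))
        emit_with_isotopes(ionc, A * frac, "adduct",
                           sprintf("[M+%s]+", cation))
      }
      if ((m$multimer_k %||% 0L) >= 2L && m$multimer_frac > 0) {
        kk <- m$multimer_k
        ionc <- proton_ion(counts_add(counts, counts, mult = kk - 1))
        mz0 <- sum(ionc * ELEMENT_MASS[names(ionc)]) - ELECTRON_MASS
        add_feature(mz0, A * m$multimer_frac, name, "multimer",
                    m$region, sprintf("[%dM+H]+", kk))
      }
    }

    # matrix cluster ions: slide-enriched, tissue-depleted
    ms <- config$matrix_species
    if (!is.null(ms)) {
      fld <- random_field(w, h, config$field_smooth, config$field_log_sd)
      weight <- ifelse(masks$slide, 1, ms$tissue_factor)
      base_vec <- ms$base * fld[pix_idx] * weight
      for (kk in ms$k) {
        mzk <- ion_mz(ms$formula, "[M+H]+", loss = "H2O", k = kk, n_loss = kk)
        add_feature(mzk, base_vec / kk, "matrix", "matrix", "slide",
                    sprintf("[%dM+H-%dH2O]+", kk, kk))
      }
    }

    # constant-on-mask artifact: same footprint as the first metabolite
    if (!is.null(config$artifact)) {
      first_prec <- features[[1]]$values
      mask <- first_prec > 0
      add_feature(config$artifact$mz,
                  ifelse(mask, config$artifact$value, 0),
                  "artifact", "artifact", "mask", "constant on mask")
    }

    mzs <- vapply(features, function(f) f$mz, numeric(1))
    ord <- order(mzs)
    features <- features[ord]
    mzs <- mzs[ord]
    if (any(diff(mzs) < 1e-3)) {
      warning("Generated features closer than 1 mDa: ",
              paste(sprintf("%.4f", mzs[c(diff(mzs) < 1e-3, FALSE)]),
                    collapse = ", "))
    }

    X <- vapply(features, function(f) f$values, numeric(np))
    noise_free_artifact <- !is.null(config$artifact)
    if (config$noise_sigma > 0) {
      art_col <- if (noise_free_artifact) {
        which(vapply(features, function(f) f$gt$relation == "artifact",
                     logical(1)))
      } else integer()
      noise <- matrix(exp(stats::rnorm(length(X), 0, config$noise_sigma)),
                      nrow = np)
      if (length(art_col)) noise[, art_col] <- 1  # artifact stays constant
      X <- X * noise
    }
    if (config$noise_floor > 0) {
      X <- X + abs(matrix(stats::rnorm(length(X), 0, config$noise_floor),
                          nrow = np))
    }

    gt <- dplyr::bind_rows(lapply(features, function(f) f$gt))
    dataset <- msi_dataset(coords, X, mzs,
                           metadata = list(source = "simulate_msi",
                                           seed = config$seed,
                                           noise_sigma = config$noise_sigma))
    list(dataset = dataset, ground_truth = gt)
  })
}

#' Add a constant-on-mask artifact feature
#'
#' Demonstrates that co-occurrence is not correlation: a feature present
#' on exactly the same pixels as a target but with flat intensity
#' correlates imperfectly with it, because correlation rewards
#' proportionality, not overlap. The new feature takes `value` on `mask`
#' pixels and 0 elsewhere.
#'
#' @param dataset An [msi_dataset()].
#' @param mask Logical vector over pixels (acquisition order).
#' @param value Constant intensity on the mask.
#' @param mz m/z to file the feature under (default 888.888).
#' @return The dataset with one added feature.
#' @export
make_artifact_feature <- function(dataset, mask, value, mz = 888.888) {
  stopifnot(inherits(dataset, "msi_dataset"),
            is.logical(mask), length(mask) == n_pixels(dataset), value > 0)
  if (all(mask)) {
    stop("Universal mask: the artifact would be constant over all pixels ",
         "and its PCC undefined.", call. = FALSE)
  }
  if (!any(mask)) stop("Empty mask.", call. = FALSE)
  newcol <- ifelse(mask, value, 0)
  pos <- findInterval(mz, dataset$mz)
  if (mz %in% dataset$mz) stop("Feature m/z already present.", call. = FALSE)
  new_mz <- append(dataset$mz, mz, after = pos)
  X <- cbind(dataset$intensities[, seq_len(pos), drop = FALSE],
             newcol,
             if (pos < n_features(dataset))
               dataset$intensities[, (pos + 1L):n_features(dataset), drop = FALSE])
  out <- dataset
  out$mz <- new_mz
  out$intensities <- unname(as.matrix(X))
  out
}
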