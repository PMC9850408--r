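test_that("pcc evaluates the correlation formula with its documented edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pcc(x, x), 1)                       # perfect linear relation
  expect_equal(pcc(x, -2 * x + 7), -1)             # perfect inverse
  expect_equal(pcc(x, c(1, 3, 2, 4)), 0.8, tolerance = 0)  # covariance 4, variances 5,5
  expect_true(is.na(pcc(x, rep(2, 4))))            # zero variance: undefined
  expect_error(pcc(x, 1:3), "length")
})

test_that("pcc is symmetric, affine-invariant, and sign-flips under negation", {
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- stats::runif(30); y <- stats::runif(30)
      expect_equal(pcc(x, y), pcc(y, x), tolerance = 1e-14)
      expect_equal(pcc(2.5 * x + 3, y), pcc(x, y), tolerance = 1e-12)
      expect_equal(pcc(-x, y), -pcc(x, y), tolerance = 1e-14)
      expect_equal(pcc(x, y), pcc_brute(x, y), tolerance = 1e-14)
    }
  })
})

test_that("colocalize ranks the bait first and sees through pixelwise scaling", {
  b <- c(0, 5, 1, 9, 3, 7)
  d <- msi_dataset(data.frame(x = 1:6, y = rep(1L, 6)),
                   cbind(b, 0.3 * b, rev(b)), mz = c(100, 200, 300))
  res <- suppressWarnings(colocalize(d, bait_mz = 100))
  expect_equal(res$entries$feature_mz[1:2], c(100, 200))  # tie at 1: m/z order
  expect_equal(res$entries$pcc[1:2], c(1, 1), tolerance = 1e-12)
  expect_error(suppressWarnings(colocalize(d, bait_mz = 150)),
               "nearest feature")
})

test_that("colocalize matches the brute-force formula on random datasets", {
  withr::with_seed(3, {
    for (i in 1:5) {
      np <- sample(10:100, 1); nf <- sample(3:20, 1)
      d <- msi_dataset(
        data.frame(x = seq_len(np), y = rep(1L, np)),
        matrix(stats::runif(np * nf, 0, 50), np, nf),
        mz = sort(stats::runif(nf, 100, 1000)))
      bait <- d$mz[sample(nf, 1)]
      res <- suppressWarnings(colocalize(d, bait, top_n = nf))
      bvec <- extract_ion_image(d, bait)$intensity
      expected <- vapply(seq_len(nf),
                         function(j) pcc_brute(bvec, d$intensities[, j]),
                         numeric(1))
      got <- res$entries$pcc[match(d$mz, res$entries$feature_mz)]
      expect_lt(max(abs(got - expected)), 1e-12)
    }
  })
})

test_that("rankings are invariant to global rescaling and undefined features drop out", {
  d <- tiny_dataset(nx = 5, ny = 5, mz = c(100, 200, 300, 400))
  d$intensities[, 4] <- 2  # constant column: undefined PCC
  r1 <- suppressWarnings(colocalize(d, 100))
  d2 <- d; d2$intensities <- d$intensities * 17
  r2 <- suppressWarnings(colocalize(d2, 100))
  expect_equal(r1$entries$feature_mz, r2$entries$feature_mz)
  expect_equal(r1$entries$pcc, r2$entries$pcc, tolerance = 1e-12)
  expect_equal(r1$n_undefined, 1L)
  expect_false(400 %in% r1$entries$feature_mz)
})

test_that("top_n boundary ties break deterministically by ascending m/z", {
  b <- c(1, 2, 3, 4, 5)
  d <- msi_dataset(data.frame(x = 1:5, y = rep(1L, 5)),
                   cbind(b, 2 * b, 3 * b, rev(b)), mz = c(100, 200, 300, 400))
  res <- suppressWarnings(colocalize(d, 100, top_n = 2))
  expect_equal(res$entries$feature_mz, c(100, 200))
  expect_warning(colocalize(d, 100), "TIC-normalized")
  expect_equal(nrow(tidy(suppressWarnings(colocalize(d, 100, top_n = 2)))), 2L)
})

test_that("band classification is exhaustive, disjoint and boundary-inclusive", {
  df <- data.frame(feature_mz = 1:4, pcc = c(1.0, 0.96, 0.82, 0.5))
  out <- classify_bands(df)
  expect_equal(as.character(out$band), c("high", "high", "moderate", "other"))
  # pcc exactly at the 0.9 edge belongs to 'high' (inclusive threshold)
  expect_equal(as.character(classify_bands(
    data.frame(pcc = 0.9))$band), "high")
  low <- classify_bands(data.frame(pcc = c(0.1, 0.59)))
  expect_equal(sum(low$band %in% c("high", "moderate")), 0L)
  # custom per-analysis edges (petunidin-style 0.85/0.8)
  pet <- classify_bands(data.frame(pcc = c(0.87, 0.82)), high = 0.85,
                        moderate_low = 0.8)
  expect_equal(as.character(pet$band), c("high", "moderate"))
})

test_that("glance summarises a colocalization run", {
  d <- tic_normalize(tiny_dataset(nx = 5, ny = 4, mz = c(100, 200, 300)))
  g <- glance(colocalize(d, 200))
  expect_equal(g$n_pixels, 20L)
  expect_equal(g$max_pcc, 1)
  expect_true(g$tic_normalized)
})
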