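test_that("noise-free derived ions are exactly proportional to their precursor", {
  sim <- simulate_msi(sim_config(noise_sigma = 0, seed = 9))
  d <- sim$dataset; gt <- sim$ground_truth
  prec <- d$intensities[, which(gt$parent == "rutin" & gt$relation == "precursor")]
  frag465 <- d$intensities[, which.min(abs(gt$mz - 465.1028))]
  # fragment = yield x precursor, pixel by pixel
  expect_equal(frag465, 0.4 * prec, tolerance = 1e-12)
  derived <- which(gt$parent == "rutin" & gt$relation != "precursor")
  for (j in derived) {
    r <- pcc(prec, d$intensities[, j])
    expect_equal(r, 1, tolerance = 1e-12, info = gt$detail[j])
  }
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  s1 <- simulate_msi(sim_config(seed = 123))
  s2 <- simulate_msi(sim_config(seed = 123))
  expect_identical(s1$dataset$intensities, s2$dataset$intensities)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_msi(sim_config(seed = 124))
  expect_false(identical(s1$dataset$intensities, s3$dataset$intensities))
})

test_that("the generator does not disturb the caller's RNG stream", {
  withr::with_seed(77, {
    before <- stats::runif(1)
  })
  withr::with_seed(77, {
    invisible(simulate_msi(sim_config(seed = 5)))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})

test_that("ground truth covers every feature exactly once with valid relations", {
  sim <- simulate_msi(sim_config(seed = 21))
  expect_equal(nrow(sim$ground_truth), n_features(sim$dataset))
  expect_equal(sim$ground_truth$mz, sim$dataset$mz)
  expect_true(all(sim$ground_truth$relation %in%
    c("precursor", "fragment", "adduct", "multimer", "isotope",
      "matrix", "artifact")))
})

test_that("feature m/z values come from the shared exact-mass chemistry", {
  gt <- simulate_msi(sim_config(seed = 2))$ground_truth
  expect_equal(gt$mz[gt$detail == "[M+H]+" & gt$parent == "rutin"],
               ion_mz("C27H30O16", "[M+H]+"), tolerance = 1e-9)
  expect_equal(gt$mz[gt$detail == "[M+Na]+" & gt$parent == "rutin"],
               ion_mz("C27H30O16", "[M+Na]+"), tolerance = 1e-9)
  expect_equal(gt$mz[gt$detail == "[3M+H-3H2O]+"],
               ion_mz("C7H6O4", "[M+H]+", loss = "H2O", k = 3, n_loss = 3),
               tolerance = 1e-9)
})

test_that("near-collisions in feature m/z trigger a warning, not an error", {
  cfg <- sim_config(seed = 1, artifact = list(mz = 611.1611, value = 500))
  expect_warning(sim <- simulate_msi(cfg), "1 mDa")
  expect_equal(nrow(sim$ground_truth), n_features(sim$dataset))
})

test_that("constant-on-mask artifacts co-occur but do not fully correlate", {
  sim <- simulate_msi(sim_config(seed = 6))
  d <- tic_normalize(sim$dataset)
  bait_col <- which(sim$ground_truth$relation == "precursor" &
                      sim$ground_truth$parent == "rutin")
  mask <- sim$dataset$intensities[, bait_col] > 0
  d2 <- make_artifact_feature(d, mask, 500, mz = 999.999)
  r <- pcc(d2$intensities[, match(999.999, d2$mz)],
           d2$intensities[, bait_col])
  expect_lt(r, 1)
  expect_gt(r, 0)        # it does co-occur
  # affine invariance: doubling the constant changes nothing
  d3 <- make_artifact_feature(d, mask, 1000, mz = 999.999)
  r3 <- pcc(d3$intensities[, match(999.999, d3$mz)],
            d3$intensities[, bait_col])
  expect_equal(r, r3, tolerance = 1e-12)
  # artifact against its own copy is a perfect match
  a <- d2$intensities[, match(999.999, d2$mz)]
  expect_equal(pcc(a, a), 1)
  expect_error(make_artifact_feature(d, rep(TRUE, n_pixels(d)), 500),
               "Universal mask")
})

test_that("noise monotonically erodes the mean PCC of derived ions", {
  mean_derived_pcc <- function(sigma, seed) {
    sim <- simulate_msi(sim_config(noise_sigma = sigma, seed = seed))
    d <- tic_normalize(sim$dataset)
    res <- colocalize(d, 611.1607)
    derived <- sim$ground_truth$mz[sim$ground_truth$parent == "rutin"]
    mean(res$entries$pcc[res$entries$feature_mz %in% derived])
  }
  seeds <- 1:4
  by_sigma <- vapply(c(0, 0.3, 0.8), function(s) {
    mean(vapply(seeds, function(sd) mean_derived_pcc(s, sd), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(by_sigma) < 0))
  expect_equal(by_sigma[1], 1, tolerance = 1e-9)
})
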