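test_that("TIC normalization scales rows to the mean TIC and is idempotent", {
  d <- msi_dataset(data.frame(x = 1:2, y = c(1L, 1L)),
                   rbind(c(1, 1), c(2, 2)), mz = c(100, 200))
  n1 <- tic_normalize(d)
  # TICs 2 and 4, mean 3: both rows scale to sum 3
  expect_equal(n1$intensities, rbind(c(1.5, 1.5), c(1.5, 1.5)))
  n2 <- tic_normalize(n1)
  expect_equal(n2$intensities, n1$intensities, tolerance = 1e-12)
  expect_true(n1$metadata$tic_normalized)
})

test_that("TIC normalization honours fixed targets, keeps ratios, flags zero pixels", {
  d <- msi_dataset(data.frame(x = 1L, y = 1L), matrix(c(5, 0), 1), mz = c(1, 2))
  expect_equal(tic_normalize(d, target = 10)$intensities, matrix(c(10, 0), 1))
  dz <- msi_dataset(data.frame(x = 1:2, y = c(1L, 1L)),
                    rbind(c(2, 6), c(0, 0)), mz = c(1, 2))
  nz <- tic_normalize(dz)
  expect_equal(nz$intensities[1, 2] / nz$intensities[1, 1], 3)  # within-pixel ratio
  expect_equal(nz$intensities[2, ], c(0, 0))                    # retained, not dropped
  expect_equal(nz$metadata$zero_tic_pixels, 1L)
  all0 <- msi_dataset(data.frame(x = 1L, y = 1L), matrix(0), mz = 1)
  expect_error(tic_normalize(all0), "zero TIC")
})

test_that("peak picking applies the S/N >= 6 rule against MAD noise", {
  # deterministic baseline with mad = 0.6745 so noise = 1.4826*mad = 1
  base <- rep(c(1 - 0.6745, 1, 1 + 0.6745), length.out = 99)
  spec <- c(base[1:40], 100, base[41:70], 5, base[71:99])
  mz <- 100 + 0.01 * seq_along(spec)
  d <- msi_dataset(data.frame(x = 1L, y = 1L), matrix(spec, 1), mz)
  noise <- 1.4826 * stats::mad(spec, constant = 1)
  pk6 <- pick_peaks(d, snr_min = 6)
  # oracle: direct SNR computation says only the 100-height peak clears 6
  expect_equal(nrow(pk6), sum(c(100, 5) / noise >= 6))
  expect_equal(nrow(pk6), 1L)
  expect_equal(pk6$mz, mz[41])
  expect_equal(pk6$snr, 100 / noise, tolerance = 1e-9)
  # threshold monotonicity: raise snr_min above the peak's SNR
  expect_equal(nrow(pick_peaks(d, snr_min = 100 / noise + 1)), 0L)
  # lowering it admits the second peak
  expect_equal(nrow(pick_peaks(d, snr_min = 4)), 2L)
})

test_that("flat spectra yield no peaks with a warning", {
  d <- msi_dataset(data.frame(x = 1L, y = 1L), matrix(0, 1, 5), mz = 1:5)
  expect_warning(pk <- pick_peaks(d), "Flat")
  expect_equal(nrow(pk), 0L)
})

test_that("recalibration inverts known offset and linear distortions", {
  true_axis <- c(303.0499, 409.0554, 611.1607, 933.2659)
  # constant +0.002 Da shift, one reference: offset-only fit
  d <- msi_dataset(data.frame(x = 1L, y = 1L), matrix(1, 1, 4),
                   true_axis + 0.002)
  r <- recalibrate(d, data.frame(mz = 409.0554, tol = 0.01))
  expect_equal(r$mz, true_axis, tolerance = 1e-6)
  # offset + 2 ppm slope, two references: linear fit, residuals <= 1e-6
  distorted <- true_axis * (1 + 2e-6) + 0.001
  d2 <- msi_dataset(data.frame(x = 1L, y = 1L), matrix(1, 1, 4), distorted)
  r2 <- recalibrate(d2, data.frame(mz = c(303.0499, 933.2659), tol = 0.01))
  expect_equal(r2$mz, true_axis, tolerance = 1e-6)
  expect_true(all(abs(r2$metadata$recalibration$refs$residual) <= 1e-6))
  # references nowhere near the axis
  expect_error(recalibrate(d, data.frame(mz = 1500, tol = 0.01)),
               "No reference matched")
})
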