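fake_spectrum <- function(mzs) {
  tibble::tibble(mz = mzs, intensity = rep(1, length(mzs)),
                 pcc = rep(1, length(mzs)))
}

test_that("isotope, adduct and loss relations are assigned by exact mass", {
  bait <- ion_mz("C27H30O16", "[M+H]+")  # 611.1607
  ann <- annotate_relations(
    fake_spectrum(c(611.1607, 612.1640, 633.1426, 465.1028, 303.0499)),
    bait_mz = bait, bait_formula = "C27H30O16")
  get <- function(mz) ann[which.min(abs(ann$peak_mz - mz)), ]
  expect_equal(get(611.1607)$relation, "precursor")
  iso <- get(612.1640)
  expect_equal(iso$relation, "isotope")        # delta 1.0033 from the bait
  expect_equal(iso$detail, "13C1")
  expect_equal(iso$reference_mz, 611.1607)
  na <- get(633.1426)
  expect_equal(na$relation, "adduct")          # delta 21.98194 (Na-H)
  expect_match(na$detail, "Na")
  expect_equal(get(465.1028)$relation, "neutral_loss")
  expect_equal(get(465.1028)$detail, "deoxyhexose")   # delta 146.0579
  expect_equal(get(303.0499)$relation, "neutral_loss")
  expect_equal(get(303.0499)$detail, "deoxyhexose+hexose")
})

test_that("lipid head-group losses diagnose the PC class", {
  bait <- ion_mz("C44H86NO8P", "[M+K]+")  # 826.5723
  ann <- annotate_relations(
    fake_spectrum(c(bait, bait - monoisotopic_mass("C3H9N"))),
    bait_mz = bait)
  loss <- ann[ann$relation == "neutral_loss", ]
  expect_equal(nrow(loss), 1L)
  expect_equal(loss$detail, "trimethylamine")  # 59.0735 Da below the bait
  expect_lt(abs(loss$ppm), 5)
})

test_that("multimers chain to the bait and strangers stay unassigned", {
  bait <- ion_mz("C27H30O16", "[M+H]+")
  dimer <- ion_mz("C27H30O16", "[2M+H]+")
  ann <- annotate_relations(fake_spectrum(c(bait, dimer, 777.777)),
                            bait_mz = bait, bait_formula = "C27H30O16")
  expect_equal(ann$relation[which.min(abs(ann$peak_mz - dimer))], "multimer")
  expect_equal(ann$relation[which.min(abs(ann$peak_mz - 777.777))],
               "unassigned")
  # every peak receives exactly one row
  expect_equal(nrow(ann), 3L)
})

test_that("isotopes may stack to 13C2 and chain off fragments, not off isotopes", {
  bait <- ion_mz("C27H30O16", "[M+H]+")
  frag <- ion_mz("C27H30O16", "[M+H]+", loss = "C6H10O4")
  peaks <- c(bait, frag, frag + 1.0033548, frag + 2 * 1.0033548)
  ann <- annotate_relations(fake_spectrum(peaks), bait_mz = bait)
  iso <- ann[ann$relation == "isotope", ]
  expect_equal(nrow(iso), 2L)
  # both isotopes reference the fragment (the monoisotopic peak), not each other
  expect_equal(iso$reference_mz, rep(frag, 2), tolerance = 1e-6)
  expect_setequal(iso$detail, c("13C1", "13C2"))
})

test_that("annotation respects the ppm tolerance and the relation invariant", {
  bait <- 611.1607
  ann <- annotate_relations(fake_spectrum(c(bait, bait + 1.01)),
                            bait_mz = bait, tol_ppm = 5)
  # 1.01 Da is ~11 ppm off the 13C spacing: no isotope call
  expect_equal(ann$relation[2], "unassigned")
  assigned <- annotate_relations(
    fake_spectrum(c(bait, bait + 1.0033548)), bait_mz = bait)
  expect_true(all(abs(assigned$ppm[assigned$relation != "unassigned"]) <= 5))
})
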