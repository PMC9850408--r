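test_that("monoisotopic masses match hand-computed element sums", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C7H6O4"), 154.026609, tolerance = 1e-6)
  # additivity over formula union
  expect_equal(monoisotopic_mass("C6H12O6"),
               2 * monoisotopic_mass("C3H6O3"), tolerance = 1e-12)
  expect_equal(monoisotopic_mass("C27H30O16"),
               monoisotopic_mass("C15H10O7") + monoisotopic_mass("C12H20O9"),
               tolerance = 1e-12)
})

test_that("formula parsing handles counts, two-letter symbols, and errors", {
  expect_equal(parse_formula("CH4O")[["H"]], 4)
  expect_equal(parse_formula("C2H8NO4P")[["P"]], 1)
  expect_error(parse_formula("NaCl"), "Unknown element")
  expect_error(parse_formula(""), "Empty")
  expect_error(parse_formula("Xx2"), "Unknown element|Cannot parse")
  expect_error(monoisotopic_mass(""), "Empty")
})

test_that("ion m/z reproduces published theoretical values at printed precision", {
  # DHB lock mass [3DHB + H - 3H2O]+
  expect_equal(round(ion_mz("C7H6O4", "[M+H]+", loss = "H2O",
                            k = 3, n_loss = 3), 4), 409.0554)
  anchors <- list(
    list("C27H30O16", "[M+H]+", 611.161),   # rutin
    list("C27H30O16", "[M+Na]+", 633.143),
    list("C15H10O7", "[M+H]+", 303.050),    # aglycone fragment
    list("C16H13O7", "[M]+", 317.066),      # petunidin radical cation
    list("C17H15O7", "[M]+", 331.081),      # malvidin
    list("C43H49O23", "[M]+", 933.266),     # acylated anthocyanin
    list("C44H86NO8P", "[M+K]+", 826.572),  # PC(36:1)
    list("C46H80NO8P", "[M+K]+", 844.525)   # PC(38:6)
  )
  for (a in anchors) {
    expect_equal(round(ion_mz(a[[1]], a[[2]]), 3), a[[3]],
                 info = paste(a[[1]], a[[2]]))
  }
  # fragment by neutral loss
  expect_equal(round(ion_mz("C27H30O16", "[M+H]+", loss = "C6H10O4"), 3),
               465.103)
})

test_that("proton/sodium m/z difference is the exact Na-H delta for any molecule", {
  withr::with_seed(4, {
    for (m in stats::runif(10, 100, 2000)) {
      expect_equal(ion_mz(m, "[M+Na]+") - ion_mz(m, "[M+H]+"),
                   21.9819442488, tolerance = 1e-9)
    }
  })
  expect_error(ion_mz("H2O", data.frame(k = 1, delta_mass = 0, charge = 0)),
               "non-zero")
  expect_error(ion_mz("QZ3"), "Unknown element|Cannot parse")
})

test_that("isotope patterns follow single-atom and convolution expectations", {
  # single carbon: A+1 = p/(1-p)
  expect_equal(isotope_pattern("C1")$abundance[2], 0.0107 / 0.9893,
               tolerance = 1e-6)
  # water: A+1 from 2H and 17O only, far below 1%
  expect_lt(isotope_pattern("H2O")$abundance[2], 0.01)
  expect_equal(isotope_pattern("H2O")$abundance[2],
               2 * 0.000115 / 0.999885 + 0.00038 / 0.99757, tolerance = 1e-6)
  # doubling all counts roughly doubles A+1 in the small-probability regime
  a1 <- isotope_pattern("C10H20O5")$abundance[2]
  a2 <- isotope_pattern("C20H40O10")$abundance[2]
  expect_equal(a2 / a1, 2, tolerance = 0.02)
  # monotone decreasing for CHO formulas below ~90 carbons
  for (f in c("C6H12O6", "C27H30O16", "C50H53O26", "C80H100O30")) {
    ab <- isotope_pattern(f)$abundance
    expect_true(all(diff(ab) < 0), info = f)
  }
})

test_that("formula enumeration finds the generating formula and respects bounds", {
  hits <- formula_candidates(611.1607, tol_ppm = 2,
                             bounds = list(C = c(0, 40), H = c(0, 60),
                                           O = c(0, 20)))
  expect_true("C27H31O16" %in% hits$formula)
  # completeness: any synthetic CHO ion m/z is recovered within tolerance
  withr::with_seed(11, {
    for (i in 1:8) {
      # chemically sensible CHO cations: 0.3 <= H/C and H <= 2C + 2
      nc <- sample(5:29, 1)
      nh <- sample(seq(ceiling(0.3 * nc), 2L * nc + 2L), 1)
      no <- sample(1:15, 1)
      f <- stats::setNames(c(nc, nh, no), c("C", "H", "O"))
      mz <- sum(f * picar:::ELEMENT_MASS[names(f)]) - picar:::ELECTRON_MASS
      hits <- formula_candidates(mz, tol_ppm = 2,
                                 bounds = list(C = c(0, 40), H = c(0, 60),
                                               O = c(0, 20)))
      expect_true(picar:::format_formula(f) %in% hits$formula,
                  info = picar:::format_formula(f))
    }
  })
  expect_equal(nrow(formula_candidates(1.5, bounds = list(C = c(0, 5),
                                                          H = c(0, 5)))), 0)
  expect_error(
    formula_candidates(500, bounds = list(C = c(0, 1000), O = c(0, 1000),
                                          N = c(0, 1000))),
    "max_combinations")
})

test_that("candidate lists are sorted by absolute ppm error", {
  hits <- formula_candidates(303.0499, tol_ppm = 10,
                             bounds = list(C = c(0, 20), H = c(0, 30),
                                           O = c(0, 10)))
  expect_true(nrow(hits) >= 1)
  expect_true(!is.unsorted(abs(hits$ppm)))
})
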