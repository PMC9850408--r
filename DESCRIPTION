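Package: picar
Title: Pixel Intensity Correlation Analysis for Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolution of MALDI mass spectrometry imaging (MSI) datasets by
    pixel intensity correlation analysis (PICA). A bait ion's per-pixel
    intensities are correlated (Pearson) against every detected mass feature;
    highly colocalized ions -- in-source fragments, natural isotopes, alkali
    adducts and multimers of the bait -- are assembled into pseudo-MS/MS
    spectra for metabolite identification, annotated by exact-mass chemistry
    (isotope spacings, Na+/K+ adducts, multimers, neutral losses, formula
    enumeration within a ppm window, coarse isotope-pattern simulation), and
    summarised as colocalization networks. Includes a minimal imzML
    reader/writer with TIC normalization, peak picking, alignment and
    recalibration, three computation-reduction strategies (mass-range cut,
    every-nth-pixel subsampling, region-of-interest filtering), and a
    ground-truth synthetic MSI generator so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
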