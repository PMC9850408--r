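---
title: "Colocalization-based deconvolution of MALDI imaging data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colocalization-based deconvolution of MALDI imaging data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picar)
```

## The model

A MALDI imaging run measures one mass spectrum per pixel. After peak
picking and alignment the data are a pixels × features matrix, and each
feature's column is an image. The working assumption of pixel intensity
correlation analysis is physical: every ion derived from one metabolite
— in-source fragments, ¹³C isotopologues, Na⁺/K⁺ adducts, multimers —
is produced from the same local pool of molecules, so its pixel
intensity is (up to noise) a fixed multiple of the precursor's. Two
consequences drive the whole package:

* across pixels, derived ions correlate with their precursor near
  perfectly (PCC → 1 as noise → 0), regardless of how abundance or
  ionization efficiency varies spatially;
* mere *co-occurrence* (same footprint, unrelated intensities) produces
  distinctly lower correlation, because PCC measures proportionality,
  not overlap.

PCC is computed over **all** retained pixels, zeros included. This is a
deliberate choice, not a default inherited from `cor()`: off-tissue
zeros are what separate a skin-localized ion family (jointly zero
outside the skin) from an ion that merely shares the tissue's bounding
box. Zero-variance columns have an undefined coefficient (the
denominator vanishes); they are flagged and excluded from the ranking
rather than erroring, since constant columns occur routinely in cropped
or subsampled data.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| bait window `tol` | 0.003 | Da | half-width of the exact-mass bin used for ion images; matches FT-ICR-grade alignment |
| `top_n` | 100 | — | ranked features kept per bait; enough to hold an ion family plus candidates |
| high band | ≥ 0.9 | PCC | pseudo-MS/MS construction set; derived ions cluster well above it at realistic noise |
| moderate band | 0.6–0.9 | PCC | structurally related candidates; per-analysis edges are exposed (`classify_bands()`, e.g. 0.85/0.8 for anthocyanin work) |
| `snr_min` | 6 | — | peak retention on the mean spectrum, noise = 1.4826 × MAD |
| relation tolerance | 5 | ppm | isotope/adduct/multimer/loss assignment |
| formula window | 2 | ppm | elemental-composition enumeration |
| reduction cutoff | bait + 40 | Da | keeps K⁺ adducts (+37.956) of the bait in range |

The PCC thresholds are conventions, not fitted constants: ion families
are perfectly correlated only in the noise-free limit, and isomeric
interference (two metabolites sharing a fragment m/z) erodes the
coefficient from above. Treat 0.9 as "specific but possibly
incomplete", and lower bands as candidate pools needing orthogonal
evidence.

## Preprocessing choices

**TIC normalization** scales every pixel spectrum to a common total
(default: the mean total of non-empty pixels, keeping intensities on a
familiar scale). Zero-TIC pixels are kept as zeros so pixel indexing —
and hence subsampling arithmetic — is stable. The operation is
idempotent and preserves within-pixel ratios, which is all that
correlation sees: any per-pixel rescaling leaves the PCC between two
features of the same family unchanged in the noise-free limit.

**Alignment** of processed-mode (per-pixel centroid) imzML uses
single-linkage clustering in one dimension: pooled centroids are sorted
and split at gaps larger than `bin_tol` (0.003 Da); the cluster
representative is the intensity-weighted mean. This is transparent and
exactly testable, which matters more here than the sophistication of a
full preprocessing suite; baseline correction and resampling are out of
scope.

**Recalibration** fits observed → true m/z from matched internal
reference masses: a constant offset for one reference, a linear map
(absorbing ppm-proportional drift) for two or more. Residuals are kept
in the metadata so a bad calibrant is visible.

**Peak picking** finds local maxima of the mean spectrum and applies
S/N ≥ `snr_min` with noise estimated as 1.4826 × MAD of the mean
spectrum — robust to the spectrum being mostly peaks or mostly
baseline.

## Annotation rules

Relations are assigned greedily in a fixed priority order — isotope
(Δ = k × 1.0033548 Da, k ≤ 3, measured from an already-assigned
monoisotopic peak), alkali adduct (Na−H, K−H), multimer (k·M + H/Na/K,
k ≤ 3), neutral loss from the bait — iterated to a fixed point so that
chains resolve (the ¹³C satellite of a fragment becomes assignable once
the fragment is). Each peak receives exactly one relation or
`unassigned`; nothing errors on an unknown peak. The priority order
exists because a mass difference can occasionally satisfy two rules at
the configured tolerance; putting isotopes first reflects their
unambiguous spacing, and determinism is required for reproducible
output.

Formula enumeration searches non-hydrogen element counts exhaustively
within user bounds and solves hydrogen from the residual mass, filtered
by RDBE ≥ 0 and 0.2 ≤ H/C ≤ 3.1 (both toggleable). Isotope patterns are
simulated at nominal-mass resolution by multinomial convolution of
per-element heavy-isotope probabilities — adequate for confirming an
elemental composition against an observed A+1/A+2 ratio, and not a
fine-structure model.

## The synthetic generator

Testing a deconvolution method requires data whose ion relationships
are known exactly, so the generator is first-class code sharing its
chemistry with the annotator ([ion_mz()], [isotope_pattern()]). The
default scene is a small tissue section on a slide: a 32 × 32 grid with
a 2-pixel bare-slide margin, a 3-pixel "skin" band, and "flesh"
interior. Abundance fields are seeded Gaussian random fields (white
noise smoothed with a σ = 3 px kernel, standardized, exponentiated with
log-SD 0.5) — positive, spatially autocorrelated, with the
pixel-to-pixel heterogeneity (CV ≈ 0.5) typical of tissue MALDI.
Noise is multiplicative log-normal (σ = 0.2 by default): MALDI
pixel variation is scale-dependent and intensities must stay
non-negative; an optional additive floor exists but defaults to off.
The skin metabolite is a rutin-like flavonoid (two glycosidic
fragments at yields 0.4/0.6, Na⁺ 0.25 / K⁺ 0.08 adduct fractions, ¹³C
depth 2, 3% dimer), with a hexose in the flesh, three DHB-cluster ions
enriched on the slide and attenuated 5× over tissue (porous tissue
absorbs matrix), and a constant-500-unit artifact on the bait's exact
footprint. Every generated feature carries a ground-truth row (parent,
relation, region), and a fixed seed reproduces the dataset bit for bit
without disturbing the caller's RNG stream.

What the generator does *not* emulate bounds what green tests mean:
real spectra have ~50,000 features, not ~26, so the simulation probes
correctness of the statistic and pipeline, not large-scale false
discovery; there is no mass-axis drift, isomeric overlap, or detector
saturation; and fragments are strictly proportional to precursors,
whereas real ISF yields can vary with matrix thickness. One consequence
is worth spelling out: with so few features, the bait's own family
dominates the simulated tissue TIC, so TIC rescaling flattens the
bait's image on its footprint — something that cannot happen when TIC
is spread over tens of thousands of features. The co-occurrence ≠
correlation demonstration (flat artifact vs varying bait) is therefore
run on the generated intensities directly, where its premise — a
spatially varying bait — actually holds; there the artifact scores
PCC ≈ 0.82–0.87, never reaching the 0.9 band.

## Numerical and degenerate-input policy

* Correlations are computed on column-centred matrices (no naive
  sum-of-squares cancellation); values within 10⁻¹³ of ±1 are snapped to
  ±1 so that exact ties (a bait against its own feature) break by the
  documented rule — ascending m/z — rather than by BLAS summation order.
* Ranking ties at the `top_n` boundary also break by ascending m/z;
  results are fully deterministic.
* Pixel subsampling keeps acquisition positions 1, 1+n, 1+2n, …
  (inclusive start, `ceiling(n_pixels/n)` kept — 62,978 pixels → 6,298
  at n = 10, 630 at n = 100).
* ROI polygons use the boundary-inclusive even-odd rule; rectangles are
  corner-inclusive; an ROI selecting nothing is an error, not an empty
  dataset.
* Empty windows in ion-image extraction warn and return zeros; an
  all-zero dataset refuses TIC normalization; writing a featureless or
  pixel-less imzML is refused.
* imzML I/O writes continuous mode, 64-bit little-endian floats,
  uncompressed; the reader additionally accepts processed mode and
  32-bit floats. Coordinates and the m/z axis round-trip losslessly.

## Problem sizes

The test suite and examples run on 32 × 32 grids (~1,000 pixels,
~26 features) with 20-replicate recovery studies — sizes chosen so the
full pipeline, including simulation, exercises in seconds while leaving
every statistical property (recovery ≥ 95% of derived ions at σ = 0.2,
zero matrix contamination, noise-monotone PCC decay) measurable. The
subsampling arithmetic is additionally checked on a 62,978-pixel grid,
the realistic pixel count for a tissue section.

## Known limitations

* Shared fragments: when two metabolites with different distributions
  produce the same fragment m/z, the fragment's image is a mixture and
  its PCC with either parent drops; the affected ion may fall out of
  the 0.9 band entirely. This is intrinsic to the method, not an
  implementation limit.
* Feature-reduction at `bait + 40 Da` assumes singly charged ions; it
  would discard fragments of multiply charged species.
* The network is a star per bait; feature–feature correlation
  structure is deliberately not computed.
* Formula enumeration is limited to charge +1 cations over
  C/H/N/O/P/S/Na/K with monovalent treatment of Na/K in the RDBE
  heuristic.
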