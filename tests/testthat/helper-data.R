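# Fixtures built in code: tiny datasets and a processed-mode imzML writer
# (the package itself only writes continuous mode, so the reader's
# processed branch needs an external-style fixture).

tiny_dataset <- function(nx = 4, ny = 3, mz = c(100, 200, 300), seed = 1) {
  withr::with_seed(seed, {
    coords <- expand.grid(x = seq_len(nx), y = seq_len(ny))
    vals <- matrix(stats::runif(nx * ny * length(mz), 0, 100),
                   nrow = nx * ny, ncol = length(mz))
    msi_dataset(coords, vals, mz)
  })
}

# minimal processed-mode imzML: per-pixel centroid lists, 64-bit floats
write_processed_imzml <- function(path, coords, peaks_per_pixel) {
  ibd <- sub("\\.imzML$", ".ibd", path)
  con <- file(ibd, "wb")
  uuid <- as.raw(rep(1, 16))
  writeBin(uuid, con)
  offset <- 16
  spec_xml <- character(0)
  for (i in seq_along(peaks_per_pixel)) {
    p <- peaks_per_pixel[[i]]
    n <- length(p$mz)
    writeBin(as.numeric(p$mz), con, size = 8, endian = "little")
    mz_off <- offset; offset <- offset + n * 8
    writeBin(as.numeric(p$intensity), con, size = 8, endian = "little")
    int_off <- offset; offset <- offset + n * 8
    arr <- function(ref, off) paste0(
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="', ref, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', off, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', n, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', n * 8, '"/>',
      '<binary/></binaryDataArray>')
    spec_xml[i] <- paste0(
      '<spectrum id="spectrum=', i, '" index="', i - 1, '" defaultArrayLength="', n, '">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="', coords$x[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="', coords$y[i], '"/>',
      '</scan></scanList><binaryDataArrayList count="2">',
      arr("mzArray", mz_off), arr("intensityArray", int_off),
      '</binaryDataArrayList></spectrum>')
  }
  close(con)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="run0"><spectrumList count="', length(peaks_per_pixel), '">',
    paste0(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>'), path)
  path
}

# direct transcription of the correlation formula, kept independent of the
# package's matrix implementation
pcc_brute <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  num <- sum((x - xb) * (y - yb))
  den <- sqrt(sum((x - xb)^2) * sum((y - yb)^2))
  if (den == 0) return(NA_real_)
  num / den
}
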