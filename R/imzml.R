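# Minimal imzML support: continuous-mode writer, continuous + processed
# reader, 32/64-bit floats, no compression. The .ibd binary companion file
# is located by swapping the .imzML extension.

ibd_path <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

random_uuid <- function() {
  bytes <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  # RFC 4122 version/variant bits
  bytes[7] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[7]), 0x0F), 0x40))
  bytes[9] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[9]), 0x3F), 0x80))
  bytes
}

format_uuid <- function(bytes) {
  h <- format(bytes)
  paste0("{", paste0(h[1:4], collapse = ""), "-", paste0(h[5:6], collapse = ""),
         "-", paste0(h[7:8], collapse = ""), "-", paste0(h[9:10], collapse = ""),
         "-", paste0(h[11:16], collapse = ""), "}")
}

#' Write an MSI dataset as continuous-mode imzML
#'
#' Writes the `.imzML` XML index and its `.ibd` binary companion (64-bit
#' floats, no compression). The shared m/z axis is stored once; each
#' pixel's intensity vector is stored in acquisition order. Lossless for
#' coordinates and the m/z axis; intensities round-trip at double
#' precision.
#'
#' @param dataset An [msi_dataset()].
#' @param path Output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @seealso [read_imzml()]
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (n_features(dataset) == 0L) {
    stop("Refusing to write a dataset with no features.", call. = FALSE)
  }
  if (n_pixels(dataset) == 0L) {
    stop("Refusing to write a dataset with no pixels.", call. = FALSE)
  }
  uuid <- random_uuid()
  ibd <- ibd_path(path)
  np <- n_pixels(dataset); nf <- n_features(dataset)

  con <- tryCatch(file(ibd, "wb"), error = function(e) {
    stop("Cannot open '", ibd, "' for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  writeBin(as.numeric(dataset$mz), con, size = 8, endian = "little")
  for (i in seq_len(np)) {
    writeBin(as.numeric(dataset$intensities[i, ]), con, size = 8, endian = "little")
  }

  mz_offset <- 16
  int_offsets <- 16 + nf * 8 + (seq_len(np) - 1) * nf * 8
  spectra <- vapply(seq_len(np), function(i) {
    paste0(
      '   <spectrum id="spectrum=', i, '" index="', i - 1L,
      '" defaultArrayLength="', nf, '">\n',
      '    <scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      dataset$coords$x[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      dataset$coords$y[i], '"/></scan></scanList>\n',
      '    <binaryDataArrayList count="2">\n',
      '     <binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      mz_offset, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
      nf, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="',
      nf * 8, '"/><binary/></binaryDataArray>\n',
      '     <binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      format(int_offsets[i], scientific = FALSE), '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
      nf, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="',
      nf * 8, '"/><binary/></binaryDataArray>\n',
      '    </binaryDataArrayList>\n   </spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    ' <cvList count="2">\n',
    '  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
    '  <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
    ' </cvList>\n',
    ' <fileDescription>\n',
    '  <fileContent>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="',
    format_uuid(uuid), '"/>\n',
    '  </fileContent>\n',
    ' </fileDescription>\n',
    ' <referenceableParamGroupList count="2">\n',
    '  <referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>\n',
    '  <referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>\n',
    ' </referenceableParamGroupList>\n',
    ' <run id="run0">\n',
    '  <spectrumList count="', np, '">\n',
    paste0(spectra, collapse = "\n"), "\n",
    '  </spectrumList>\n',
    ' </run>\n',
    '</mzML>\n')
  ok <- tryCatch({ writeLines(xml, path, useBytes = TRUE); TRUE },
                 error = function(e) {
                   stop("Cannot write '", path, "': ", conditionMessage(e),
                        call. = FALSE)
                 })
  invisible(path)
}

cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, paste0(".//cvParam[@accession='", accession, "']"))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

has_cv <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, paste0(".//cvParam[@accession='", accession, "']")), "xml_missing")
}

#' Read an imzML file
#'
#' Supports continuous mode (shared m/z axis, used directly) and processed
#' mode (per-pixel centroid lists, merged onto a common axis by
#' [align_features()] with gap threshold `bin_tol`). Uncompressed 32- or
#' 64-bit float arrays.
#'
#' @param path Path to a `.imzML` file (the `.ibd` companion must sit next
#'   to it).
#' @param bin_tol Alignment gap threshold in Da for processed-mode files
#'   (default 0.003).
#' @return An [msi_dataset()]; `metadata` records the source path, mode and
#'   binary UUID. Pixel order is the file's spectrum order.
#' @export
read_imzml <- function(path, bin_tol = 0.003) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("Ill-formed imzML: ", conditionMessage(e), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(spectra)) stop("Empty imzML: file contains no spectra.", call. = FALSE)
  mode <- if (has_cv(xml2::xml_find_first(doc, ".//fileContent"), "IMS:1000031")) {
    "processed"
  } else "continuous"

  # precision per referenceable param group id
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  group_size <- function(g) if (has_cv(g, "MS:1000521")) 4L else 8L
  sizes <- stats::setNames(vapply(groups, group_size, integer(1)),
                           xml2::xml_attr(groups, "id"))
  group_kind <- function(g) {
    if (has_cv(g, "MS:1000514")) "mz" else if (has_cv(g, "MS:1000515")) "intensity" else NA
  }
  kinds <- stats::setNames(vapply(groups, group_kind, character(1)),
                           xml2::xml_attr(groups, "id"))

  ibd <- ibd_path(path)
  if (!file.exists(ibd)) stop("Missing .ibd companion: ", ibd, call. = FALSE)
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  uuid <- readBin(con, "raw", 16L)

  read_array <- function(arr, idx) {
    off <- as.numeric(cv_value(arr, "IMS:1000102"))
    len <- as.numeric(cv_value(arr, "IMS:1000103"))
    if (is.na(off) || is.na(len)) {
      stop("Spectrum ", idx, ": missing external offset/length.", call. = FALSE)
    }
    ref <- xml2::xml_attr(
      xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
    size <- if (!is.na(ref) && ref %in% names(sizes)) {
      sizes[[ref]]
    } else if (has_cv(arr, "MS:1000521")) 4L else 8L
    kind <- if (!is.na(ref) && ref %in% names(kinds)) {
      kinds[[ref]]
    } else if (has_cv(arr, "MS:1000514")) "mz" else "intensity"
    seek(con, where = off, origin = "start")
    vals <- readBin(con, "double", n = len, size = size, endian = "little")
    if (length(vals) != len) {
      stop("Spectrum ", idx, ": truncated binary data.", call. = FALSE)
    }
    list(kind = kind, values = vals)
  }

  np <- length(spectra)
  xs <- integer(np); ys <- integer(np)
  mz_list <- vector("list", np); int_list <- vector("list", np)
  for (i in seq_len(np)) {
    s <- spectra[[i]]
    xs[i] <- as.integer(cv_value(s, "IMS:1000050"))
    ys[i] <- as.integer(cv_value(s, "IMS:1000051"))
    if (is.na(xs[i]) || is.na(ys[i])) {
      stop("Spectrum ", i, ": missing pixel position.", call. = FALSE)
    }
    arrs <- xml2::xml_find_all(s, ".//binaryDataArray")
    if (length(arrs) < 2L) {
      stop("Spectrum ", i, ": expected m/z and intensity arrays.", call. = FALSE)
    }
    for (arr in arrs) {
      a <- read_array(arr, i)
      if (a$kind == "mz") mz_list[[i]] <- a$values else int_list[[i]] <- a$values
    }
    if (is.null(mz_list[[i]]) || is.null(int_list[[i]]) ||
        length(mz_list[[i]]) != length(int_list[[i]])) {
      stop("Spectrum ", i, ": m/z and intensity arrays disagree.", call. = FALSE)
    }
  }
  coords <- tibble::tibble(x = xs, y = ys)
  meta <- list(source = path, mode = mode, uuid = paste(format(uuid), collapse = ""))

  if (mode == "continuous") {
    mz_axis <- mz_list[[1]]
    intens <- do.call(rbind, int_list)
    msi_dataset(coords, intens, mz_axis, metadata = meta)
  } else {
    peaks <- tibble::tibble(
      pixel = rep(seq_len(np), lengths(mz_list)),
      mz = unlist(mz_list),
      intensity = unlist(int_list)
    )
    aligned <- align_features(peaks, n_pixels = np, bin_tol = bin_tol)
    meta$bin_tol <- bin_tol
    msi_dataset(coords, aligned$intensities, aligned$mz, metadata = meta)
  }
}

#' Align per-pixel centroid peaks onto a common m/z axis
#'
#' Single-linkage clustering in one dimension: pooled centroids are sorted
#' and split wherever the gap between successive m/z values exceeds
#' `bin_tol`. Each cluster becomes one feature whose representative m/z is
#' the intensity-weighted mean of its members; a pixel contributing several
#' centroids to one cluster has them summed.
#'
#' @param peaks Data frame with columns `pixel` (1-based index), `mz`,
#'   `intensity`.
#' @param n_pixels Total number of pixels (rows of the output matrix).
#' @param bin_tol Gap threshold in Da (default 0.003).
#' @return List with `mz` (ascending representative axis) and
#'   `intensities` (`n_pixels` x `n_features` matrix).
#' @export
align_features <- function(peaks, n_pixels, bin_tol = 0.003) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("pixel", "mz", "intensity") %in% names(peaks)),
            bin_tol > 0)
  if (!nrow(peaks)) {
    return(list(mz = numeric(), intensities = matrix(0, n_pixels, 0)))
  }
  ord <- order(peaks$mz)
  peaks <- peaks[ord, ]
  cluster <- cumsum(c(1, diff(peaks$mz) > bin_tol))
  cl <- factor(cluster, levels = unique(cluster))  # keep ascending-mz order
  w <- peaks$intensity
  # intensity-weighted mean; fall back to plain mean for all-zero clusters
  wsum <- as.numeric(tapply(w, cl, sum))
  rep_mz <- ifelse(
    wsum > 0,
    as.numeric(tapply(w * peaks$mz, cl, sum)) / wsum,
    as.numeric(tapply(peaks$mz, cl, mean))
  )
  nf <- length(rep_mz)
  intens <- matrix(0, n_pixels, nf)
  idx <- cbind(peaks$pixel, cluster)
  for (r in seq_len(nrow(peaks))) {
    intens[idx[r, 1], idx[r, 2]] <- intens[idx[r, 1], idx[r, 2]] + peaks$intensity[r]
  }
  list(mz = as.numeric(rep_mz), intensities = intens)
}
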