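# imzML reading/writing. imzML stores spectral metadata as mzML-flavoured XML
# with the numeric arrays in a sibling binary ".ibd" file addressed by byte
# offsets. Continuous mode shares one m/z axis across all spectra; processed
# mode stores a separate axis per spectrum and is rebinned on load.

IMS_CONTINUOUS <- "IMS:1000030"
IMS_PROCESSED  <- "IMS:1000031"

ibd_path <- function(path) {
  base <- sub("\\.[iI][mM][zZ][mM][lL]$", "", path)
  paste0(base, ".ibd")
}

#' Write a data cube to imzML (continuous mode)
#'
#' Writes `<path>` (XML) and the sibling `<path minus extension>.ibd` binary
#' file. Arrays are stored as uncompressed 64-bit floats; the shared m/z axis
#' is written once. Internal 0-based coordinates are shifted to the 1-based
#' imzML convention.
#'
#' @param cube an [ims_cube()].
#' @param path output path, conventionally ending in `.imzML`.
#' @param uuid_seed integer seed for the dataset UUID so runs are reproducible.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(cube, path, uuid_seed = 0L) {
  stopifnot(inherits(cube, "ims_cube"))
  n <- n_pixels(cube)
  p <- ncol(cube$intensities)
  uuid <- with_seed(uuid_seed, as.raw(sample.int(256L, 16L, replace = TRUE) - 1L))
  uuid_str <- paste0(
    "{", paste(sprintf("%02x", as.integer(uuid)), collapse = ""), "}")

  ib <- file(ibd_path(path), open = "wb")
  writeBin(uuid, ib)
  mz_offset <- 16
  writeBin(as.double(cube$mz), ib, size = 8, endian = "little")
  int_offsets <- mz_offset + 8 * p + (seq_len(n) - 1) * 8 * p
  for (i in seq_len(n))
    writeBin(as.double(cube$intensities[i, ]), ib, size = 8, endian = "little")
  close(ib)

  spec_xml <- vapply(seq_len(n), function(i) {
    paste0(
      '  <spectrum id="spectrum=', i, '" index="', i - 1L,
      '" defaultArrayLength="0">\n',
      '   <scanList count="1"><scan>\n',
      '    <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      cube$coords$x[i] + 1L, '"/>\n',
      '    <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      cube$coords$y[i] + 1L, '"/>\n',
      '   </scan></scanList>\n',
      '   <binaryDataArrayList count="2">\n',
      imzml_bda("mzArray", mz_offset, p),
      imzml_bda("intensityArray", int_offsets[i], p),
      '   </binaryDataArrayList>\n',
      '  </spectrum>\n')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<fileDescription><fileContent>\n',
    ' <cvParam cvRef="IMS" accession="', IMS_CONTINUOUS,
    '" name="continuous"/>\n',
    ' <cvParam cvRef="IMS" accession="IMS:1000080"',
    ' name="universally unique identifier" value="', uuid_str, '"/>\n',
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">\n',
    ' <referenceableParamGroup id="mzArray">\n',
    '  <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
    '  <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '  <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    ' </referenceableParamGroup>\n',
    ' <referenceableParamGroup id="intensityArray">\n',
    '  <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
    '  <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '  <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    ' </referenceableParamGroup>\n',
    '</referenceableParamGroupList>\n',
    '<run id="run0">\n',
    ' <spectrumList count="', n, '">\n',
    paste(spec_xml, collapse = ""),
    ' </spectrumList>\n',
    '</run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

imzml_bda <- function(ref, offset, len) {
  paste0(
    '    <binaryDataArray encodedLength="0">\n',
    '     <referenceableParamGroupRef ref="', ref, '"/>\n',
    '     <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
    format(offset, scientific = FALSE), '"/>\n',
    '     <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="',
    len, '"/>\n',
    '     <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="',
    format(8 * len, scientific = FALSE), '"/>\n',
    '     <binary/>\n',
    '    </binaryDataArray>\n')
}

#' Read an imzML file into a data cube
#'
#' Continuous-mode files keep the file's common m/z axis verbatim. For
#' processed-mode files each spectrum's peaks are rebinned by summation onto a
#' uniform axis of width `bin_width` Da (bin centers are reported as the m/z
#' axis); `bin_width` is then required. imzML 1-based pixel coordinates are
#' shifted to the package's 0-based convention.
#'
#' @param path path to the `.imzML` file; the sibling `.ibd` must be present.
#' @param bin_width bin width in Da for processed-mode files.
#' @return an [ims_cube()].
#' @export
read_imzml <- function(path, bin_width = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed imzML: ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mode_cv <- xml2::xml_find_all(doc, ".//fileContent/cvParam")
  accs <- xml2::xml_attr(mode_cv, "accession")
  continuous <- IMS_CONTINUOUS %in% accs
  processed <- IMS_PROCESSED %in% accs
  if (!continuous && !processed)
    stop("malformed imzML: fileContent declares neither continuous nor processed mode")
  if (processed && is.null(bin_width))
    stop("processed-mode imzML requires a bin_width (Da) configuration value")

  # data types per referenceable param group
  grp_nodes <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  grp_size <- list()
  for (g in grp_nodes) {
    id <- xml2::xml_attr(g, "id")
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "./cvParam"), "accession")
    grp_size[[id]] <- if ("MS:1000521" %in% acc) 4L else 8L  # 32- vs 64-bit float
  }

  ibd <- ibd_path(path)
  if (!file.exists(ibd)) stop("missing .ibd file: ", ibd)
  con <- file(ibd, open = "rb")
  on.exit(close(con))

  specs <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(specs) == 0) stop("malformed imzML: no spectra")
  n <- length(specs)
  xs <- integer(n); ys <- integer(n)
  mz_list <- vector("list", n); int_list <- vector("list", n)

  read_array <- function(offset, len, size) {
    seek(con, where = offset, origin = "start")
    readBin(con, what = "double", n = len, size = size, endian = "little")
  }

  for (i in seq_len(n)) {
    s <- specs[[i]]
    sid <- xml2::xml_attr(s, "id")
    pos <- xml2::xml_find_all(s, ".//scan/cvParam")
    pacc <- xml2::xml_attr(pos, "accession")
    pval <- xml2::xml_attr(pos, "value")
    xi <- suppressWarnings(as.integer(pval[pacc == "IMS:1000050"][1]))
    yi <- suppressWarnings(as.integer(pval[pacc == "IMS:1000051"][1]))
    if (is.na(xi) || is.na(yi))
      stop("malformed imzML: missing pixel position in ", sid)
    xs[i] <- xi - 1L; ys[i] <- yi - 1L
    for (bda in xml2::xml_find_all(s, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
      cv <- xml2::xml_find_all(bda, "./cvParam")
      acc <- xml2::xml_attr(cv, "accession")
      val <- xml2::xml_attr(cv, "value")
      is_mz <- identical(ref, "mzArray") || "MS:1000514" %in% acc
      offset <- as.numeric(val[acc == "IMS:1000102"][1])
      len <- as.integer(val[acc == "IMS:1000103"][1])
      if (is.na(offset) || is.na(len))
        stop("malformed imzML: missing external offset/length in ", sid)
      size <- if (!is.null(ref) && !is.na(ref) && !is.null(grp_size[[ref]]))
        grp_size[[ref]] else if ("MS:1000521" %in% acc) 4L else 8L
      arr <- read_array(offset, len, size)
      if (is_mz) mz_list[[i]] <- arr else int_list[[i]] <- arr
    }
    if (is.null(mz_list[[i]]) || is.null(int_list[[i]]))
      stop("malformed imzML: spectrum ", sid, " lacks m/z or intensity array")
    if (length(mz_list[[i]]) != length(int_list[[i]]))
      stop("malformed imzML: array length mismatch in ", sid)
  }

  if (continuous) {
    mz <- mz_list[[1]]
    inten <- do.call(rbind, int_list)
  } else {
    lo <- floor(min(unlist(mz_list)) / bin_width)
    hi <- floor(max(unlist(mz_list)) / bin_width)
    nb <- hi - lo + 1L
    mz <- (lo:hi + 0.5) * bin_width
    inten <- matrix(0, n, nb)
    for (i in seq_len(n)) {
      b <- floor(mz_list[[i]] / bin_width) - lo + 1L
      for (k in seq_along(b))
        inten[i, b[k]] <- inten[i, b[k]] + int_list[[i]][k]
    }
  }
  ims_cube(inten, mz, xs, ys)
}
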