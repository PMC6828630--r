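# Image-file helpers: microscopy images in as multichannel arrays, masks and
# score images out as PNG, numeric tables as TSV.

#' Read a PNG or TIFF image as a multichannel array
#'
#' Microscopy images (e.g. brightfield H&E) enter the segmentation step the
#' same way as PCA score stacks: as `height x width x channels` numeric
#' arrays. Grayscale images gain a singleton channel dimension.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric array `H x W x C`.
#' @export
read_multichannel_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
  img
}

#' Write a binary mask as a 0/255 grayscale PNG
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 PNG back into a logical mask
#' @param path PNG path; any nonzero pixel (first channel) is foreground.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write a score image as min-max scaled 16-bit PNG
#' @param img numeric matrix; `NA` (off-tissue) pixels map to 0.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_png <- function(img, path) {
  rng <- range(img, na.rm = TRUE)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  scaled[is.na(scaled)] <- 0
  png::writePNG(scaled, path, dpi = NULL)
  invisible(path)
}

# internal: deterministic TSV writer for result tables (LF, %.10g numbers)
write_table_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}
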