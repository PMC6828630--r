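#' Write a data cube as a tab-delimited pixel-spectrum matrix
#'
#' The dialect is fixed so files are byte-reproducible: the header row is
#' `x<TAB>y<TAB><mz_1><TAB>...` with m/z printed at 4 decimals, followed by one
#' row per pixel (integer `x`, integer `y`, then intensities at up to 15
#' significant digits), LF newlines, no trailing whitespace. Pixel coordinates
#' double as unique observation identifiers for downstream modeling.
#'
#' @param cube an [ims_cube()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ims_tsv <- function(cube, path) {
  stopifnot(inherits(cube, "ims_cube"))
  header <- paste(c("x", "y", sprintf("%.4f", cube$mz)), collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  n <- n_pixels(cube)
  if (n > 0) {
    body <- matrix("", n, 2L + ncol(cube$intensities))
    body[, 1] <- as.character(cube$coords$x)
    body[, 2] <- as.character(cube$coords$y)
    body[, -(1:2)] <- sprintf("%.15g", cube$intensities)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a tab-delimited pixel-spectrum matrix
#'
#' Reads files in the [write_ims_tsv()] dialect. The grid shape is inferred as
#' `(max(y) + 1, max(x) + 1)`.
#'
#' @param path input file path.
#' @return an [ims_cube()] with empty processing history.
#' @export
read_ims_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 2 || fields[1] != "x" || fields[2] != "y")
    stop("not a pixel-spectrum TSV: header must start with 'x\\ty'")
  mz <- as.numeric(fields[-(1:2)])
  if (anyNA(mz)) stop("non-numeric m/z value in header")
  p <- length(mz)
  dat <- tryCatch(
    scan(path, what = double(), skip = 1L, sep = "\t", quiet = TRUE),
    error = function(e) NULL)
  if (is.null(dat)) {
    # rescan line by line to report which row is bad
    lines <- readLines(path)[-1]
    for (i in seq_along(lines)) {
      v <- suppressWarnings(as.numeric(strsplit(lines[i], "\t", fixed = TRUE)[[1]]))
      if (anyNA(v)) stop(sprintf("non-numeric cell in data row %d", i))
    }
    stop("malformed TSV body")
  }
  if (length(dat) %% (p + 2L) != 0)
    stop("ragged TSV: row length does not match header")
  m <- matrix(dat, ncol = p + 2L, byrow = TRUE)
  xs <- as.integer(m[, 1]); ys <- as.integer(m[, 2])
  if (nrow(m) && anyDuplicated(paste(xs, ys)))
    stop("duplicate pixel coordinates in TSV")
  ims_cube(m[, -(1:2), drop = FALSE], mz, xs, ys)
}
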