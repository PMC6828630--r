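#' Pixel-spectrum data cube
#'
#' An `ims_cube` holds one spectrum per pixel of an imaging mass spectrometry
#' acquisition: an `n_pixels x n_peaks` intensity matrix on a common m/z axis,
#' plus the pixel-to-image-grid correspondence. Pixel coordinates are 0-based,
#' `x` indexing columns and `y` indexing rows of the image grid; grid positions
#' without a spectrum (non-rectangular acquisitions) are simply absent from the
#' coordinate index and appear as `NA` in reconstructed images.
#'
#' @param intensities numeric matrix, one row per pixel, one column per peak.
#'   Raw intensities must be non-negative.
#' @param mz strictly increasing numeric vector of m/z values (Da), one per
#'   column of `intensities`.
#' @param x,y integer vectors of 0-based grid positions, one per row of
#'   `intensities`. `(x, y)` pairs must be unique.
#' @param grid_shape integer `(height, width)` of the image grid. Defaults to
#'   the tight bounding box `(max(y) + 1, max(x) + 1)`.
#' @param history character vector of preprocessing step names already applied
#'   (empty for raw data).
#'
#' @return An object of class `ims_cube` with elements `intensities`, `mz`,
#'   `coords` (list with `x`, `y`, `grid`) and `history`.
#' @export
ims_cube <- function(intensities, mz, x, y, grid_shape = NULL,
                     history = character()) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- NULL
  mz <- as.numeric(mz)
  x <- as.integer(x)
  y <- as.integer(y)
  if (length(mz) != ncol(intensities))
    stop("length(mz) must equal ncol(intensities)")
  if (length(x) != nrow(intensities) || length(y) != nrow(intensities))
    stop("coordinate vectors must have one entry per spectrum row")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("mz axis must be strictly increasing")
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0))
    stop("coordinates must be non-negative integers")
  if (anyDuplicated(paste(x, y)))
    stop("duplicate pixel coordinates")
  if (is.null(grid_shape))
    grid_shape <- c(if (length(y)) max(y) + 1L else 0L,
                    if (length(x)) max(x) + 1L else 0L)
  grid_shape <- as.integer(grid_shape)
  if (length(x) && (any(x >= grid_shape[2]) || any(y >= grid_shape[1])))
    stop("coordinates fall outside grid_shape")
  if (length(history) == 0 && nrow(intensities) && any(intensities < 0))
    stop("raw intensities must be non-negative")
  structure(
    list(intensities = intensities, mz = mz,
         coords = list(x = x, y = y, grid = grid_shape),
         history = as.character(history)),
    class = "ims_cube")
}

#' @export
print.ims_cube <- function(x, ...) {
  cat(sprintf("ims_cube: %d pixels x %d peaks on a %d x %d grid\n",
              nrow(x$intensities), ncol(x$intensities),
              x$coords$grid[1], x$coords$grid[2]))
  if (length(x$mz))
    cat(sprintf("  m/z %.4f .. %.4f\n", min(x$mz), max(x$mz)))
  cat(sprintf("  processing: %s\n",
              if (length(x$history)) paste(x$history, collapse = " -> ")
              else "raw"))
  invisible(x)
}

#' @export
dim.ims_cube <- function(x) dim(x$intensities)

n_pixels <- function(cube) nrow(cube$intensities)

#' Fold a per-pixel vector into an image
#'
#' Reorganizes per-pixel values (e.g. a PCA score column) into the coordinate
#' system of the original image. Grid positions without a pixel are `NA`.
#'
#' @param values numeric vector, one value per pixel.
#' @param coords a coordinate index as stored in `ims_cube$coords`.
#' @return numeric `height x width` matrix with `img[y + 1, x + 1] = value`.
#' @seealso [image_to_vector()]
#' @export
vector_to_image <- function(values, coords) {
  if (length(values) != length(coords$x))
    stop("length(values) must equal the number of pixels")
  img <- matrix(NA_real_, coords$grid[1], coords$grid[2])
  img[cbind(coords$y + 1L, coords$x + 1L)] <- values
  img
}

#' Extract per-pixel values from an image
#'
#' Inverse of [vector_to_image()]: reads the image at each pixel coordinate,
#' in pixel (row) order.
#'
#' @param img numeric matrix of the grid shape.
#' @param coords a coordinate index as stored in `ims_cube$coords`.
#' @return numeric vector, one value per pixel.
#' @export
image_to_vector <- function(img, coords) {
  if (!all(dim(img)[1:2] == coords$grid))
    stop("image shape does not match coordinate grid")
  img[cbind(coords$y + 1L, coords$x + 1L)]
}

# internal: save/restore global RNG around seeded computations
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
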