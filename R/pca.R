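#' Mean-centered image PCA
#'
#' Principal component analysis of the pixels-by-peaks matrix. Data are mean
#' centered but not scaled; components are computed by a deterministic full
#' singular value decomposition (no randomized solver) and signed so that each
#' loading's largest-magnitude element is positive, making score images
#' reproducible. Each component's `r2x` is the fraction of the centered
#' matrix's total variance it captures.
#'
#' @param cube an [ims_cube()] or a numeric pixel-by-peak matrix.
#' @param n_components number of components to retain (default 25, capped at
#'   `min(n_pixels - 1, n_peaks, 30)`).
#' @return object of class `ims_pca`: `mean` (spectrum), `loadings`
#'   (`p x A`, orthonormal columns), `scores` (`n x A`), `r2x` (per-component
#'   explained fractions), `n_components`, plus `coords` and `mz` when the
#'   input was a cube.
#' @export
ims_pca <- function(cube, n_components = 25) {
  if (inherits(cube, "ims_cube")) {
    X <- cube$intensities; coords <- cube$coords; mz <- cube$mz
  } else {
    X <- as.matrix(cube); coords <- NULL; mz <- NULL
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 pixels")
  amax <- min(n - 1L, p, 30L)
  if (n_components < 1) stop("n_components must be >= 1")
  A <- min(as.integer(n_components), amax)
  if (n <= A) stop("n_pixels must exceed n_components")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  total <- sum(Xc^2)
  if (total <= 0) stop("constant matrix: zero variance, PCA undefined")
  sv <- svd(Xc, nu = A, nv = A)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(A)], A, A)
  # sign convention: largest-|element| of each loading is positive
  for (a in seq_len(A)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  structure(
    list(mean = mu, loadings = loadings, scores = scores,
         r2x = sv$d[seq_len(A)]^2 / total, n_components = A,
         coords = coords, mz = mz),
    class = "ims_pca")
}

#' @export
print.ims_pca <- function(x, ...) {
  cat(sprintf("ims_pca: %d components, %d pixels x %d peaks\n",
              x$n_components, nrow(x$scores), length(x$mean)))
  cat(sprintf("  cumulative R2X = %.4f\n", sum(x$r2x)))
  invisible(x)
}

#' @export
summary.ims_pca <- function(object, ...) {
  df <- data.frame(component = seq_len(object$n_components),
                   r2x = object$r2x, r2x_cum = cumsum(object$r2x))
  class(df) <- c("summary.ims_pca", "data.frame")
  df
}

#' Project new spectra onto a fitted PCA model
#' @param object an `ims_pca` model.
#' @param newdata an [ims_cube()] or matrix on the same peak axis.
#' @param ... unused.
#' @return score matrix `n x A`.
#' @export
predict.ims_pca <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "ims_cube")) newdata$intensities else as.matrix(newdata)
  if (ncol(X) != length(object$mean)) stop("peak-axis mismatch")
  sweep(X, 2L, object$mean) %*% object$loadings
}

#' Score image of one PCA component
#'
#' Folds a score column back into the image grid; the component's explained
#' variance fraction travels along as attributes for captioning.
#'
#' @param model an `ims_pca` fitted on a cube (has coordinates).
#' @param component component index (1-based).
#' @param coords coordinate index; defaults to the model's.
#' @return numeric image matrix with attributes `r2x` and `component`.
#' @export
score_image <- function(model, component, coords = model$coords) {
  stopifnot(inherits(model, "ims_pca"))
  if (is.null(coords)) stop("no coordinate index available")
  if (component < 1 || component > model$n_components)
    stop("component index out of range 1..", model$n_components)
  img <- vector_to_image(model$scores[, component], coords)
  attr(img, "r2x") <- model$r2x[component]
  attr(img, "component") <- as.integer(component)
  img
}

#' Multichannel stack of PCA score images
#'
#' Builds the `H x W x C` feature image consumed by active-contour
#' segmentation, channel `c` being the score image of `components[c]`.
#' With `standardize = TRUE` each channel is divided by its score standard
#' deviation so high-variance components do not dominate the segmentation
#' energy.
#'
#' @param model an `ims_pca`.
#' @param components integer vector of component indices.
#' @param coords coordinate index; defaults to the model's.
#' @param standardize scale each channel to unit score variance.
#' @return numeric array `H x W x length(components)`.
#' @export
score_stack <- function(model, components, coords = model$coords,
                        standardize = FALSE) {
  stopifnot(inherits(model, "ims_pca"))
  if (length(components) == 0) stop("components must be non-empty")
  if (any(components < 1 | components > model$n_components))
    stop("component index out of range 1..", model$n_components)
  if (is.null(coords)) stop("no coordinate index available")
  imgs <- lapply(components, function(a) {
    v <- model$scores[, a]
    if (standardize) {
      s <- stats::sd(v)
      if (s > 0) v <- v / s
    }
    vector_to_image(v, coords)
  })
  array(unlist(imgs), dim = c(coords$grid[1], coords$grid[2], length(imgs)))
}

#' @export
plot.ims_pca <- function(x, component = 1, ...) {
  img <- score_image(x, component)
  graphics::image(t(img)[, nrow(img):1], axes = FALSE, useRaster = TRUE,
                  main = sprintf("t%d (R2X = %.3f)", component,
                                 x$r2x[component]), ...)
  invisible(x)
}
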