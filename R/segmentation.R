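# Region-based (Chan-Vese) active-contour segmentation of multichannel
# feature images (PCA score stacks or microscopy images). The vector-valued
# Chan-Vese energy is
#   E(mask) = mu * Perimeter(mask)
#           + (1/C) * sum_c [ sum_in (u_c - c1_c)^2 + sum_out (u_c - c2_c)^2 ]
# with c1/c2 the inside/outside channel means, Perimeter counting 4-neighbour
# edges between in- and out-pixels, equal channel weights, and no area term.
# Pixels carrying NA in any channel (off-tissue positions) are excluded from
# means and perimeter and forced outside every mask.

as_feature_array <- function(img) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (length(dim(img)) != 3) stop("feature image must be H x W or H x W x C")
  img
}

valid_pixels <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  v <- matrix(TRUE, h, w)
  for (c in seq_len(dim(img)[3]))
    v <- v & !is.na(matrix(img[, , c], h, w))
  v
}

# count of 4-neighbour edges between TRUE/FALSE pixels, both ends valid
perimeter4 <- function(mask, valid) {
  h <- nrow(mask); w <- ncol(mask)
  per <- 0L
  if (w > 1) {
    ok <- valid[, -w, drop = FALSE] & valid[, -1, drop = FALSE]
    per <- per + sum(ok & (mask[, -w, drop = FALSE] != mask[, -1, drop = FALSE]))
  }
  if (h > 1) {
    ok <- valid[-h, , drop = FALSE] & valid[-1, , drop = FALSE]
    per <- per + sum(ok & (mask[-h, , drop = FALSE] != mask[-1, , drop = FALSE]))
  }
  per
}

channel_means <- function(img, where) {
  C <- dim(img)[3]
  h <- dim(img)[1]; w <- dim(img)[2]
  vapply(seq_len(C), function(c) mean(matrix(img[, , c], h, w)[where]),
         numeric(1))
}

# per-pixel mean squared distance to a channel-mean vector, averaged over C
dist2_to <- function(img, ctr) {
  C <- dim(img)[3]
  h <- dim(img)[1]; w <- dim(img)[2]
  d <- matrix(0, h, w)
  for (c in seq_len(C)) d <- d + (matrix(img[, , c], h, w) - ctr[c])^2
  d / C
}

#' Chan-Vese segmentation energy
#'
#' Evaluates the vector-valued Chan-Vese functional for a binary mask on a
#' multichannel feature image (see the formula in the package source header of
#' this file). `smooth_factor` is the weight of the boundary-length penalty.
#'
#' @param feature_image numeric `H x W` matrix or `H x W x C` array; `NA`
#'   pixels are excluded.
#' @param mask logical matrix of the same spatial shape.
#' @param smooth_factor non-negative perimeter weight.
#' @return the scalar energy.
#' @export
chan_vese_energy <- function(feature_image, mask, smooth_factor = 0.2) {
  img <- as_feature_array(feature_image)
  if (!all(dim(mask) == dim(img)[1:2])) stop("mask shape mismatch")
  valid <- valid_pixels(img)
  mask <- mask & valid
  inside <- mask; outside <- !mask & valid
  if (!any(inside) || !any(outside))
    stop("mask must have at least one valid pixel inside and outside")
  c1 <- channel_means(img, inside)
  c2 <- channel_means(img, outside)
  d1 <- dist2_to(img, c1); d2 <- dist2_to(img, c2)
  data_term <- sum(d1[inside]) + sum(d2[outside])
  smooth_factor * perimeter4(mask, valid) + data_term
}

#' Active-contour evolution parameters
#'
#' @param n_iterations maximum number of evolution iterations (the study
#'   design range is 5-50; default 30).
#' @param smooth_factor boundary-length weight, in squared feature-image units
#'   per boundary edge (design range 0.1-0.3 on unit-variance channels;
#'   default 0.2).
#' @param hole_fill fill interior holes of the converged mask (default TRUE).
#' @param convergence_tol stop when the fraction of pixels changing in an
#'   iteration drops to this value or below (default 0: stop only at a fixed
#'   point).
#' @return object of class `acs_params`.
#' @export
acs_params <- function(n_iterations = 30, smooth_factor = 0.2,
                       hole_fill = TRUE, convergence_tol = 0) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (smooth_factor < 0) stop("smooth_factor must be >= 0")
  if (convergence_tol < 0) stop("convergence_tol must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 smooth_factor = smooth_factor,
                 hole_fill = isTRUE(hole_fill),
                 convergence_tol = convergence_tol),
            class = "acs_params")
}

#' Evolve a seed contour by Chan-Vese energy descent
#'
#' Iteratively refines a rough initial region ("seed") into the segmentation
#' of the proximal region. Each iteration performs two checkerboard
#' half-sweeps: with the inside/outside means frozen, every pixel of one
#' parity whose flip strictly lowers the energy is flipped, then the means are
#' recomputed. Because 4-neighbours always have the opposite parity, the flip
#' gains are exact and additive, so the energy is non-increasing across
#' iterations by construction; evolution is deterministic and unbiased with
#' respect to shrinking or expanding.
#'
#' @param feature_image numeric `H x W` matrix or `H x W x C` array.
#' @param seed_mask logical matrix, non-empty and not covering every valid
#'   pixel.
#' @param params an [acs_params()].
#' @return the evolved logical mask, with attributes `energy_trace` (energy
#'   after each iteration, element 1 being the seed's energy) and
#'   `iterations`.
#' @export
evolve_contour <- function(feature_image, seed_mask, params = acs_params()) {
  img <- as_feature_array(feature_image)
  stopifnot(inherits(params, "acs_params"))
  if (!all(dim(seed_mask) == dim(img)[1:2])) stop("seed shape mismatch")
  valid <- valid_pixels(img)
  mask <- seed_mask & valid
  nv <- sum(valid)
  if (!any(mask)) stop("seed mask is empty (after removing off-tissue pixels)")
  if (sum(mask) == nv) stop("seed mask covers the whole valid image")
  mu <- params$smooth_factor
  h <- nrow(mask); w <- ncol(mask)
  parity <- (outer(seq_len(h), seq_len(w), "+")) %% 2L

  nbr_in <- function(m) {
    k <- matrix(0L, h, w)
    k[, -1] <- k[, -1] + m[, -w]
    k[, -w] <- k[, -w] + m[, -1]
    k[-1, ] <- k[-1, ] + m[-h, ]
    k[-h, ] <- k[-h, ] + m[-1, ]
    k
  }
  n_valid_nbr <- nbr_in(valid)

  trace <- numeric(params$n_iterations + 1L)
  trace[1] <- chan_vese_energy(img, mask, mu)
  it <- 0L
  warned <- FALSE
  for (iter in seq_len(params$n_iterations)) {
    changed <- 0L
    for (par in 0:1) {
      inside <- mask; outside <- !mask & valid
      if (!any(inside) || !any(outside)) break
      c1 <- channel_means(img, inside)
      c2 <- channel_means(img, outside)
      d1 <- dist2_to(img, c1); d2 <- dist2_to(img, c2)
      k_in <- nbr_in(mask)
      m_out <- n_valid_nbr - k_in
      delta <- ifelse(mask,
                      (d2 - d1) + mu * (k_in - m_out),
                      (d1 - d2) + mu * (m_out - k_in))
      flip <- valid & parity == par & delta < -1e-12
      if (!any(flip)) next
      new_mask <- xor(mask, flip)
      if (!any(new_mask) || sum(new_mask) == nv) {
        # degenerate collapse to empty/full: keep last valid mask
        if (!warned) {
          warning("contour collapsed to an empty or full mask; returning last valid mask")
          warned <- TRUE
        }
        next
      }
      mask <- new_mask
      changed <- changed + sum(flip)
    }
    it <- iter
    trace[iter + 1L] <- chan_vese_energy(img, mask, mu)
    if (changed / nv <= params$convergence_tol) break
  }
  if (params$hole_fill) {
    filled <- refine_mask(mask, hole_fill = TRUE) & valid
    if (any(filled != mask) && sum(filled) < nv) {
      e_filled <- chan_vese_energy(img, filled, mu)
      if (e_filled <= trace[it + 1L]) {
        mask <- filled
        trace[it + 1L] <- e_filled
      }
    }
  }
  attr(mask, "energy_trace") <- trace[seq_len(it + 1L)]
  attr(mask, "iterations") <- it
  mask
}

#' Refine a binary mask by hole-filling and small-object removal
#'
#' Interior holes — background connected components (4-connectivity) not
#' touching the image border — are filled when `hole_fill` is TRUE; foreground
#' connected components smaller than `min_object_px` pixels are removed. The
#' operation is idempotent.
#'
#' @param mask logical matrix.
#' @param hole_fill fill interior holes.
#' @param min_object_px minimum connected-component size to keep (0 keeps
#'   all).
#' @return refined logical matrix.
#' @export
refine_mask <- function(mask, hole_fill = TRUE, min_object_px = 0) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  if (hole_fill && any(mask)) {
    bg <- !mask
    reach <- matrix(FALSE, h, w)
    reach[1, ] <- bg[1, ]; reach[h, ] <- bg[h, ]
    reach[, 1] <- bg[, 1]; reach[, w] <- bg[, w]
    repeat {
      grown <- reach
      grown[, -1] <- grown[, -1] | reach[, -w]
      grown[, -w] <- grown[, -w] | reach[, -1]
      grown[-1, ] <- grown[-1, ] | reach[-h, ]
      grown[-h, ] <- grown[-h, ] | reach[-1, ]
      grown <- grown & bg
      if (identical(grown, reach)) break
      reach <- grown
    }
    mask <- mask | (bg & !reach)
  }
  if (min_object_px > 0 && any(mask)) {
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), h, w))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, h, w)
  }
  mask
}

#' Rasterize a polygon seed by even-odd fill
#'
#' Turns a "rough outline" given as polygon vertices into a binary seed mask:
#' a pixel is inside when its center satisfies the even-odd (ray crossing)
#' rule.
#'
#' @param vertices two-column matrix of `(x, y)` vertices in 0-based pixel
#'   coordinates.
#' @param grid_shape `(height, width)` of the target grid.
#' @return logical matrix.
#' @export
seed_from_polygon <- function(vertices, grid_shape) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  h <- grid_shape[1]; w <- grid_shape[2]
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- nrow(vertices)
  inside <- rep(FALSE, h * w)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, h, w)
}

#' Assemble a per-pixel class map from ROI masks
#'
#' A pixel lying in exactly one ROI mask gets that label; pixels in two or
#' more masks (ambiguous) or in none are treated as observations with missing
#' class assignment.
#'
#' @param rois named list of logical mask matrices (>= 2, unique names, equal
#'   shapes).
#' @return object of class `class_map`: `map` (integer matrix, `NA` =
#'   missing-class), `labels`, `counts`, `grid`.
#' @export
build_class_map <- function(rois) {
  if (!is.list(rois) || length(rois) < 2) stop("need at least 2 ROI masks")
  labs <- names(rois)
  if (is.null(labs) || any(labs == "") || anyDuplicated(labs))
    stop("ROI masks must carry unique non-empty labels")
  dims <- dim(rois[[1]])
  for (m in rois)
    if (!is.logical(m) || !identical(dim(m), dims))
      stop("all ROI masks must be logical matrices of identical shape")
  count <- Reduce(`+`, rois)
  map <- matrix(NA_integer_, dims[1], dims[2])
  for (k in seq_along(rois)) map[rois[[k]] & count == 1] <- k
  counts <- tabulate(map, nbins = length(rois))
  names(counts) <- labs
  structure(list(map = map, labels = labs, counts = counts, grid = dims),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("class_map on %d x %d grid: %s; %d unassigned grid positions\n",
              x$grid[1], x$grid[2],
              paste(sprintf("%s=%d", x$labels, x$counts), collapse = ", "),
              sum(is.na(x$map))))
  invisible(x)
}

#' Overlap ratio (Jaccard) of two binary masks
#'
#' Intersection over union; [dice_coefficient()] is also provided since the
#' reference definition of segmentation "overlap ratio" varies between
#' studies.
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return Jaccard index in `[0, 1]`.
#' @export
overlap_ratio <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shape mismatch")
  u <- sum(mask_a | mask_b, na.rm = TRUE)
  if (u == 0) stop("both masks are empty: overlap ratio undefined")
  sum(mask_a & mask_b, na.rm = TRUE) / u
}

#' Dice coefficient of two binary masks
#' @inheritParams overlap_ratio
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shape mismatch")
  s <- sum(mask_a, na.rm = TRUE) + sum(mask_b, na.rm = TRUE)
  if (s == 0) stop("both masks are empty: Dice undefined")
  2 * sum(mask_a & mask_b, na.rm = TRUE) / s
}
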