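# Synthetic cerebellum-like IMS phantom. Four anatomical layers are laid out
# as concentric curved bands (circle-band geometry around a center below the
# grid): white matter (WM) innermost, granular layer (GL), a thin Purkinje
# cell layer (PCL) band — the sensitivity challenge — and the molecular layer
# (ML) outermost. Off-band positions are background (no spectrum acquired).
# Each region has a peak signature with region-exclusive and shared markers;
# per-pixel multiplicative gain emulates matrix/ionization artifacts and
# multiplicative log-normal noise produces the heteroscedastic error
# structure of real MALDI data.

frac_part <- function(x) x - floor(x)

#' Phantom configuration
#'
#' All geometry, signature and noise parameters of the synthetic dataset.
#' Defaults define the package's reference study conditions: a 96 x 96 grid,
#' 120 peaks, a 2-pixel-wide PCL band, log-normal per-pixel gain with
#' `sigma_gain = 0.25`, multiplicative noise `sigma_mult = 0.3`, and a
#' half-normal additive noise floor far below the weakest analyte peak, as
#' for a TOF detector counting ~1e3-1e5 intensity units.
#'
#' @param grid_shape `(height, width)` in pixels.
#' @param n_peaks number of peaks (>= 40 so every marker block is non-empty).
#' @param w_pcl PCL band width in pixels (>= 1).
#' @param sigma_gain log-SD of the per-pixel multiplicative gain.
#' @param sigma_mult log-SD of the per-measurement multiplicative noise.
#' @param sigma_add additive half-normal noise scale; default
#'   `1e-5 * max(signatures)`.
#' @param center `(x, y)` center of the band geometry in 0-based pixel
#'   coordinates (may lie outside the grid).
#' @param radii increasing radii `(wm_inner, wm_outer, gl_outer, ml_outer)`;
#'   the PCL band occupies `[gl_outer, gl_outer + w_pcl)` and the ML band
#'   `[gl_outer + w_pcl, ml_outer)`.
#' @return object of class `phantom_config`, including the deterministic
#'   region-by-peak `signatures` matrix and the `markers` index list (peaks
#'   mirroring sulfatides shared by WM/GL, an ML-specific CerP-like marker,
#'   GL-specific PI-like markers, and a PCL-exclusive PI 38:4-like marker).
#' @export
phantom_config <- function(grid_shape = c(96L, 96L), n_peaks = 120L,
                           w_pcl = 2L, sigma_gain = 0.25, sigma_mult = 0.3,
                           sigma_add = NULL, center = c(47.5, 140),
                           radii = c(44, 70, 90, 118)) {
  n_peaks <- as.integer(n_peaks)
  if (n_peaks < 40) stop("n_peaks must be >= 40")
  if (w_pcl < 1) stop("w_pcl must be >= 1")
  if (any(diff(radii) <= 0) || length(radii) != 4)
    stop("radii must be 4 increasing values")
  if (sigma_gain < 0 || sigma_mult < 0) stop("noise parameters must be >= 0")

  # deterministic quasi-random base intensities (golden-ratio sequence)
  phi <- (sqrt(5) - 1) / 2
  base <- (20 + 80 * frac_part(seq_len(n_peaks) * phi)) * 100
  # peak role blocks (fractions of the axis)
  n_shared <- floor(0.75 * n_peaks)
  rest <- setdiff(seq_len(n_peaks), seq_len(n_shared))
  nb <- length(rest)
  cut <- function(f0, f1) rest[seq.int(max(1L, floor(f0 * nb) + 1L), floor(f1 * nb))]
  sulfatide <- cut(0, 0.4)        # high WM, elevated GL
  ml_marker <- cut(0.4, 0.6)      # CerP-like, ML-specific
  gl_marker <- cut(0.6, 0.8)      # PI 38:3/38:2-like, GL-specific
  pcl_marker <- cut(0.8, 1)       # PI 38:4-like, PCL-exclusive
  base[rest] <- (60 + 40 * frac_part(rest * phi)) * 100  # markers sit on strong peaks

  regions <- c("WM", "GL", "PCL", "ML")
  sig <- matrix(0, 4, n_peaks, dimnames = list(regions, NULL))
  jitter_const <- c(WM = 2, GL = 3, PCL = 5, ML = 7)
  for (r in seq_len(4)) {
    jit <- 0.7 + 0.6 * frac_part(seq_len(n_peaks) * phi * jitter_const[r])
    sig[r, ] <- base * jit
  }
  sig["WM", sulfatide] <- base[sulfatide] * 6
  sig["GL", sulfatide] <- base[sulfatide] * 4
  sig[c("PCL", "ML"), sulfatide] <- rep(base[sulfatide] * 0.5, each = 2)
  sig["ML", ml_marker] <- base[ml_marker] * 6
  sig[c("WM", "GL", "PCL"), ml_marker] <- rep(base[ml_marker] * 0.5, each = 3)
  sig["GL", gl_marker] <- base[gl_marker] * 5
  sig[c("WM", "PCL", "ML"), gl_marker] <- rep(base[gl_marker] * 0.7, each = 3)
  sig["PCL", pcl_marker] <- base[pcl_marker] * 8
  sig[c("WM", "GL", "ML"), pcl_marker] <- rep(base[pcl_marker] * 0.15, each = 3)

  if (is.null(sigma_add)) sigma_add <- 1e-5 * max(sig)
  structure(
    list(grid_shape = as.integer(grid_shape), n_peaks = n_peaks,
         w_pcl = as.integer(w_pcl), sigma_gain = sigma_gain,
         sigma_mult = sigma_mult, sigma_add = sigma_add,
         center = center, radii = radii, signatures = sig,
         markers = list(sulfatide = sulfatide, ml = ml_marker,
                        gl = gl_marker, pcl = pcl_marker),
         mz = round(seq(400, 999.5, length.out = n_peaks), 4)),
    class = "phantom_config")
}

phantom_region_masks <- function(config) {
  h <- config$grid_shape[1]; w <- config$grid_shape[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  r <- sqrt((xs - config$center[1])^2 + (ys - config$center[2])^2)
  ri <- config$radii
  pcl_outer <- ri[3] + config$w_pcl
  list(WM = r >= ri[1] & r < ri[2],
       GL = r >= ri[2] & r < ri[3],
       PCL = r >= ri[3] & r < pcl_outer,
       ML = r >= pcl_outer & r < ri[4])
}

#' Generate a synthetic IMS dataset with ground truth
#'
#' Pixel `i`, peak `j` intensity is
#' `g_i * mu[region(i), j] * exp(sigma_mult * eps_ij) + |sigma_add * eta_ij|`
#' with `eps`, `eta` standard normal and `g_i = exp(sigma_gain * zeta_i)`.
#' Deterministic given `seed`; the global RNG state is left untouched.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed for all phantom randomness.
#' @return list with `cube` (raw [ims_cube()]), `truth` (ground-truth
#'   `class_map`), `masks` (the true region masks), `config` and `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  masks <- phantom_region_masks(config)
  truth <- build_class_map(masks)
  tissue <- !is.na(truth$map)
  # pixel order: row-major over the grid (y, then x)
  pos <- which(tissue, arr.ind = TRUE)
  ord <- order(pos[, 1], pos[, 2])
  pos <- pos[ord, , drop = FALSE]
  region <- truth$map[pos]
  n <- nrow(pos); p <- config$n_peaks
  mu <- config$signatures[region, , drop = FALSE]
  inten <- with_seed(seed, {
    g <- exp(config$sigma_gain * stats::rnorm(n))
    eps <- matrix(stats::rnorm(n * p), n, p)
    eta <- matrix(stats::rnorm(n * p), n, p)
    g * mu * exp(config$sigma_mult * eps) + abs(config$sigma_add * eta)
  })
  cube <- ims_cube(inten, config$mz,
                   x = pos[, 2] - 1L, y = pos[, 1] - 1L,
                   grid_shape = config$grid_shape)
  list(cube = cube, truth = truth, masks = masks, config = config,
       seed = as.integer(seed))
}

#' Extract per-label masks from a class map
#' @param class_map a `class_map`.
#' @return named list of logical matrices.
#' @export
masks_from_class_map <- function(class_map) {
  stopifnot(inherits(class_map, "class_map"))
  out <- lapply(seq_along(class_map$labels), function(k) {
    m <- class_map$map == k
    m[is.na(m)] <- FALSE
    m
  })
  names(out) <- class_map$labels
  out
}

#' Degrade ground-truth regions into rough seed masks
#'
#' Emulates the "rough outline" seeds a user would draw: each true region is
#' eroded by a disc of radius `erosion_px` — per region, the largest radius
#' not exceeding `erosion_px` that leaves the seed non-empty is used, so thin
#' bands degrade gracefully — and then translated by a random integer offset
#' drawn uniformly from `[-shift_px, shift_px]` per axis. Deterministic given
#' `seed`.
#'
#' @param truth ground-truth `class_map`.
#' @param erosion_px erosion disc radius (pixels).
#' @param shift_px maximum absolute translation per axis (pixels).
#' @param seed integer seed.
#' @return named list of logical seed masks (an ROI set).
#' @export
perturb_seeds <- function(truth, erosion_px = 2L, shift_px = 2L, seed = 1L) {
  masks <- masks_from_class_map(truth)
  with_seed(seed, {
    out <- lapply(names(masks), function(lab) {
      m <- masks[[lab]]
      if (!any(m)) stop("region '", lab, "' is empty")
      r <- as.integer(erosion_px)
      er <- m
      while (r > 0) {
        cand <- EBImage::erode(matrix(as.numeric(m), nrow(m), ncol(m)),
                               EBImage::makeBrush(2L * r + 1L, "disc")) > 0.5
        if (any(cand)) { er <- cand; break }
        r <- r - 1L
      }
      dx <- sample.int(2L * shift_px + 1L, 1L) - shift_px - 1L
      dy <- sample.int(2L * shift_px + 1L, 1L) - shift_px - 1L
      sh <- shift_mask(er, dx, dy)
      if (!any(sh))
        stop("seed for '", lab,
             "' emptied by perturbation; use smaller erosion/shift")
      sh
    })
    names(out) <- names(masks)
    out
  })
}

# integer translation with zero padding
shift_mask <- function(mask, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}
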