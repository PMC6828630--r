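# Variance-stabilization diagnostics. MALDI-IMS intensities carry
# heteroscedastic noise (variance growing with mean), which logarithmic
# transformation is meant to stabilize; these helpers quantify the effect per
# anatomical ROI.

label_pixels <- function(cube, class_map, label) {
  stopifnot(inherits(cube, "ims_cube"), inherits(class_map, "class_map"))
  k <- match(label, class_map$labels)
  if (is.na(k)) stop("unknown ROI label '", label, "'")
  lab <- image_to_vector(class_map$map + 0, cube$coords)
  which(!is.na(lab) & lab == k)
}

#' Per-peak noise profile of an ROI
#'
#' Mean and sample standard deviation (n-1 denominator) of every peak over
#' the ROI's pixels, sorted by increasing mean — the SD-versus-mean view used
#' to judge heteroscedasticity.
#'
#' @param cube an [ims_cube()] (any processing state).
#' @param class_map a [build_class_map()] result.
#' @param label ROI label with at least 3 pixels.
#' @return data.frame (class `noise_profile`) with `peak`, `mz`, `mean`,
#'   `sd`, plus attributes `label` and `spec`.
#' @export
roi_noise_profile <- function(cube, class_map, label) {
  idx <- label_pixels(cube, class_map, label)
  if (length(idx) < 3) stop("ROI '", label, "' has fewer than 3 pixels")
  X <- cube$intensities[idx, , drop = FALSE]
  m <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  ord <- order(m)
  out <- data.frame(peak = ord, mz = cube$mz[ord], mean = m[ord], sd = s[ord])
  attr(out, "label") <- label
  attr(out, "spec") <- paste(cube$history, collapse = " -> ")
  class(out) <- c("noise_profile", "data.frame")
  out
}

#' Heteroscedasticity index of a noise profile
#'
#' Spearman rank correlation between per-peak mean and SD (zero-SD peaks
#' excluded). Near 1 for multiplicative noise on raw intensities; near 0
#' after a variance-stabilizing transformation. Rank-based, so invariant to
#' monotone re-scalings of either axis.
#'
#' @param profile a [roi_noise_profile()].
#' @param min_peaks minimum number of informative (nonzero-SD) peaks.
#' @return correlation in `[-1, 1]`.
#' @export
heteroscedasticity_index <- function(profile, min_peaks = 10L) {
  stopifnot(inherits(profile, "noise_profile"))
  keep <- profile$sd > 0
  if (sum(keep) < min_peaks)
    stop("fewer than ", min_peaks, " peaks with nonzero SD")
  stats::cor(profile$mean[keep], profile$sd[keep], method = "spearman")
}

#' Relative standard deviation of one peak within an ROI
#'
#' SD divided by the absolute mean over the ROI's pixels, on the cube's
#' current processing state.
#'
#' @param cube an [ims_cube()].
#' @param class_map a [build_class_map()] result.
#' @param label ROI label with at least 3 pixels.
#' @param peak_index peak (column) index.
#' @return the RSD.
#' @export
roi_rsd <- function(cube, class_map, label, peak_index) {
  idx <- label_pixels(cube, class_map, label)
  if (length(idx) < 3) stop("ROI '", label, "' has fewer than 3 pixels")
  if (peak_index < 1 || peak_index > ncol(cube$intensities))
    stop("peak index out of range")
  v <- cube$intensities[idx, peak_index]
  m <- mean(v)
  if (m == 0) stop("zero mean intensity: RSD undefined")
  stats::sd(v) / abs(m)
}

#' Hotelling T2 ellipse and outside fraction for a 2-D score plot
#'
#' The 95% confidence oval conventionally drawn on score plots: the
#' Hotelling T2 limit at level `alpha` with the F(2, n-2) critical value,
#' `T2_crit = 2 (n - 1) / (n - 2) * F_alpha(2, n - 2)`, applied to the
#' Mahalanobis T2 of each observation. Reports the fraction of observations
#' strictly outside.
#'
#' @param scores numeric `n x 2` matrix of score values (`n >= 10`).
#' @param alpha confidence level (default 0.95).
#' @return list with `center`, `cov`, `chol_cov`, `t2_limit`, `t2` (per
#'   observation) and `fraction_outside`.
#' @export
hotelling_outside_fraction <- function(scores, alpha = 0.95) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must have exactly 2 columns")
  n <- nrow(scores)
  if (n < 10) stop("need at least 10 observations")
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  if (any(diag(S) <= 0) || det(S) <= 0)
    stop("degenerate (zero-variance) scores: ellipse undefined")
  t2 <- stats::mahalanobis(scores, ctr, S)
  lim <- 2 * (n - 1) / (n - 2) * stats::qf(alpha, 2, n - 2)
  list(center = ctr, cov = S, chol_cov = t(chol(S)), t2_limit = lim, t2 = t2,
       fraction_outside = mean(t2 > lim))
}

#' Box-plot statistics of mean-centered ROI intensities
#'
#' Centers one peak's intensities by their ROI mean and returns Tukey
#' box-plot statistics: median and quartiles by linear interpolation
#' (quantile type 7), whiskers at the most extreme points within 1.5 IQR of
#' the quartiles, plus the sample SD.
#'
#' @param cube an [ims_cube()].
#' @param class_map a [build_class_map()] result.
#' @param label ROI label with at least 5 pixels.
#' @param peak_index peak (column) index.
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `sd`, `n`, `outliers`.
#' @export
roi_boxplot_stats <- function(cube, class_map, label, peak_index) {
  idx <- label_pixels(cube, class_map, label)
  if (length(idx) < 5) stop("ROI '", label, "' has fewer than 5 pixels")
  if (peak_index < 1 || peak_index > ncol(cube$intensities))
    stop("peak index out of range")
  v <- cube$intensities[idx, peak_index]
  v <- v - mean(v)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- v[v >= q[1] - 1.5 * iqr]
  hi <- v[v <= q[3] + 1.5 * iqr]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(lo), whisker_high = max(hi),
       sd = stats::sd(v), n = length(v),
       outliers = v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr])
}
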