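TRANSFORMS <- c("none", "log10", "ln", "sqrt")
NORMALIZATIONS <- c("none", "tic", "median", "mean", "rms", "max")

#' Preprocessing specification
#'
#' Pairs an intensity transformation with a per-spectrum normalization.
#' Transformations act elementwise and serve as variance stabilizers for the
#' multiplicative, heteroscedastic noise typical of MALDI imaging;
#' normalizations rescale each pixel spectrum to remove global artifacts such
#' as matrix inhomogeneity and ionization drift.
#'
#' @param transformation one of `"none"`, `"log10"`, `"ln"`, `"sqrt"`.
#' @param normalization one of `"none"`, `"tic"`, `"median"`, `"mean"`,
#'   `"rms"`, `"max"`.
#' @param log_offset positive constant added before `log10`/`ln` so zero
#'   intensities map to zero (default 1).
#' @param order `"transform_first"` (default) applies the transformation and
#'   then normalizes the transformed values; `"normalize_first"` reverses it.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(transformation = "none", normalization = "none",
                            log_offset = 1,
                            order = c("transform_first", "normalize_first")) {
  transformation <- match.arg(transformation, TRANSFORMS)
  normalization <- match.arg(normalization, NORMALIZATIONS)
  order <- match.arg(order)
  if (transformation %in% c("log10", "ln") && !(log_offset > 0))
    stop("log_offset must be > 0 for logarithmic transformations")
  structure(list(transformation = transformation,
                 normalization = normalization,
                 log_offset = log_offset, order = order),
            class = "preprocess_spec")
}

#' Parse a preprocessing name like "ln-median"
#'
#' Accepts the compact naming style used in figures and on the command line:
#' `"raw"`, a single transformation (`"ln"`, `"log10"`, `"sqrt"`), a single
#' normalization (`"tic"`, `"median"`, `"mean"`, `"rms"`, `"max"`), or a
#' hyphenated `"<transformation>-<normalization>"` pair.
#'
#' @param name specification string.
#' @param log_offset passed to [preprocess_spec()].
#' @return a `preprocess_spec`.
#' @export
parse_spec <- function(name, log_offset = 1) {
  parts <- strsplit(tolower(trimws(name)), "-", fixed = TRUE)[[1]]
  valid <- paste0(
    '"raw", transformations {', paste(TRANSFORMS[-1], collapse = ", "),
    '}, normalizations {', paste(NORMALIZATIONS[-1], collapse = ", "),
    '}, or "<transformation>-<normalization>"')
  bad <- function() stop(sprintf("unknown preprocessing spec '%s'; valid names: %s",
                                 name, valid), call. = FALSE)
  if (length(parts) == 1) {
    if (parts == "raw" || parts == "none") return(preprocess_spec())
    if (parts %in% TRANSFORMS)
      return(preprocess_spec(parts, "none", log_offset))
    if (parts %in% NORMALIZATIONS)
      return(preprocess_spec("none", parts, log_offset))
    bad()
  } else if (length(parts) == 2) {
    if (!(parts[1] %in% TRANSFORMS) || !(parts[2] %in% NORMALIZATIONS)) bad()
    return(preprocess_spec(parts[1], parts[2], log_offset))
  }
  bad()
}

#' @export
format.preprocess_spec <- function(x, ...) {
  t <- x$transformation; n <- x$normalization
  if (t == "none" && n == "none") "raw"
  else if (n == "none") t
  else if (t == "none") n
  else if (x$order == "transform_first") paste0(t, "-", n)
  else paste0(n, "-", t)
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("preprocess_spec:", format(x), "\n"); invisible(x)
}

#' Apply an intensity transformation
#'
#' Elementwise variance-stabilizing transformation: `sqrt(x)`,
#' `ln(x + log_offset)` or `log10(x + log_offset)`. With the default offset of
#' 1, zeros map to zero and the within-spectrum rank order is preserved.
#'
#' @param cube an [ims_cube()].
#' @param method one of `"none"`, `"log10"`, `"ln"`, `"sqrt"`.
#' @param log_offset positive offset for the logarithmic methods.
#' @return the transformed cube, with the step appended to its history.
#' @export
transform_intensities <- function(cube, method = "none", log_offset = 1) {
  stopifnot(inherits(cube, "ims_cube"))
  method <- match.arg(method, TRANSFORMS)
  if (any(cube$intensities < 0))
    stop("negative intensities: transformations require non-negative input")
  x <- cube$intensities
  cube$intensities <- switch(method,
    none = x,
    sqrt = sqrt(x),
    ln = log(x + log_offset),
    log10 = log10(x + log_offset))
  cube$history <- c(cube$history,
    if (method %in% c("ln", "log10"))
      sprintf("transform:%s(+%g)", method, log_offset)
    else paste0("transform:", method))
  cube
}

#' Normalize each pixel spectrum
#'
#' Divides each spectrum by a per-spectrum scale computed on its current
#' values: total ion current (sum), arithmetic mean, median of its strictly
#' positive values, root mean square, or maximum peak. Rows whose scale is
#' zero or undefined are left unchanged and reported via a warning and the
#' `"skipped_rows"` attribute.
#'
#' @param cube an [ims_cube()].
#' @param method one of `"none"`, `"tic"`, `"median"`, `"mean"`, `"rms"`,
#'   `"max"`.
#' @return the normalized cube, with the step appended to its history.
#' @export
normalize_spectra <- function(cube, method = "none") {
  stopifnot(inherits(cube, "ims_cube"))
  method <- match.arg(method, NORMALIZATIONS)
  if (method == "none") {
    cube$history <- c(cube$history, "normalize:none")
    return(cube)
  }
  x <- cube$intensities
  s <- switch(method,
    tic = rowSums(x),
    mean = rowMeans(x),
    rms = sqrt(rowMeans(x^2)),
    max = apply(x, 1L, max),
    median = apply(x, 1L, function(r) {
      pos <- r[r > 0]
      if (length(pos)) stats::median(pos) else NA_real_
    }))
  ok <- is.finite(s) & s != 0
  if (any(ok)) x[ok, ] <- x[ok, , drop = FALSE] / s[ok]
  if (!all(ok)) {
    skipped <- which(!ok)
    warning(sprintf("%s normalization skipped %d row(s) with zero/undefined scale",
                    method, length(skipped)))
    attr(cube, "skipped_rows") <- skipped
  }
  cube$intensities <- x
  cube$history <- c(cube$history, paste0("normalize:", method))
  cube
}

#' Apply a full preprocessing specification to a raw cube
#'
#' By default the transformation is applied first and the normalization scale
#' is computed on the transformed values; `order = "normalize_first"` in the
#' spec reverses this. Refuses cubes that already carry processing history.
#'
#' @param cube a raw [ims_cube()] (empty history).
#' @param spec a [preprocess_spec()] or a name accepted by [parse_spec()].
#' @return the processed cube.
#' @export
apply_preprocess <- function(cube, spec) {
  stopifnot(inherits(cube, "ims_cube"))
  if (is.character(spec)) spec <- parse_spec(spec)
  stopifnot(inherits(spec, "preprocess_spec"))
  if (length(cube$history))
    stop("cube is already processed (history: ",
         paste(cube$history, collapse = " -> "), ")")
  if (spec$order == "transform_first") {
    cube <- transform_intensities(cube, spec$transformation, spec$log_offset)
    cube <- normalize_spectra(cube, spec$normalization)
  } else {
    cube <- normalize_spectra(cube, spec$normalization)
    cube <- transform_intensities(cube, spec$transformation, spec$log_offset)
  }
  cube
}
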