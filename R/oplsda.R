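# OPLS-DA: orthogonal projections to latent structures discriminant analysis.
# The X-block is the processed pixel-by-peak matrix restricted to
# class-assigned pixels; the Y-block is the class indicator matrix. Orthogonal
# components capture systematic X variation uncorrelated with class, the
# predictive components the class-correlated remainder. Both blocks are mean
# centered but not scaled. Model quality: R2X/R2Y (cumulative explained
# fractions) and Q2Y (cumulative predicted fraction under deterministic
# venetian-blind cross-validation, 1 - PRESS/SS).

#' Build the class indicator Y-block from a class map
#'
#' One indicator column per class, one row per class-assigned pixel in pixel
#' (row) order. Missing-class pixels are excluded but their indices retained
#' so their scores can be predicted later.
#'
#' @param class_map a [build_class_map()] result.
#' @param coords coordinate index of the cube the classes refer to.
#' @param min_class_size smallest admissible class (default 14, i.e. twice
#'   the 7 cross-validation blocks).
#' @return object of class `yblock`: `Y` (indicator matrix), `labels`,
#'   `pixel_index` (rows of the cube used), `missing_index`, `col_means`.
#' @export
make_yblock <- function(class_map, coords, min_class_size = 14L) {
  stopifnot(inherits(class_map, "class_map"))
  if (!all(class_map$grid == coords$grid))
    stop("class map grid does not match coordinate grid")
  lab_per_pixel <- image_to_vector(class_map$map + 0, coords)
  assigned <- which(!is.na(lab_per_pixel))
  if (length(assigned) == 0) stop("all pixels are missing-class")
  present <- sort(unique(lab_per_pixel[assigned]))
  if (length(present) < 2) stop("need at least 2 classes with assigned pixels")
  labels <- class_map$labels[present]
  Y <- matrix(0, length(assigned), length(present))
  for (k in seq_along(present))
    Y[lab_per_pixel[assigned] == present[k], k] <- 1
  colnames(Y) <- labels
  sizes <- colSums(Y)
  if (any(sizes < min_class_size))
    stop(sprintf("class '%s' has %d pixels, below the minimum of %d",
                 labels[which.min(sizes)], min(sizes), min_class_size))
  structure(list(Y = Y, labels = labels, pixel_index = assigned,
                 missing_index = which(is.na(lab_per_pixel)),
                 col_means = colMeans(Y)),
            class = "yblock")
}

# one bilinear PLS2 component by NIPALS on centered X, Y
nipals_pls2 <- function(X, Y, tol = 1e-12, max_iter = 500L) {
  u <- Y[, which.max(colSums(Y^2))]
  t_old <- rep(0, nrow(X))
  for (i in seq_len(max_iter)) {
    w <- crossprod(X, u)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) stop("rank deficiency: weight vector is zero; use fewer components")
    w <- w / nw
    t <- X %*% w
    cc <- crossprod(Y, t) / sum(t^2)
    u <- Y %*% cc / sum(cc^2)
    if (sqrt(sum((t - t_old)^2)) <= tol * max(sqrt(sum(t^2)), 1)) break
    t_old <- t
  }
  p <- crossprod(X, t) / sum(t^2)
  list(w = drop(w), t = drop(t), p = drop(p), c = drop(cc))
}

#' Fit an OPLS-DA model
#'
#' First removes `n_orthogonal` Y-orthogonal components: for each, one
#' bilinear PLS2 component is fitted on the current X and Y, its X-loading is
#' projected onto the orthogonal complement of the column space of `X'Y`
#' (guaranteeing the orthogonal scores satisfy `t_o' Y = 0` by construction),
#' normalized to give the orthogonal weight, and X is deflated. The filtered X
#' then receives `n_predictive` bilinear PLS2 components (NIPALS, X and Y
#' deflation).
#'
#' @param X numeric matrix of class-assigned pixel spectra (rows match
#'   `Y$pixel_index` when `Y` is a `yblock`).
#' @param Y a [make_yblock()] result or an indicator matrix.
#' @param n_predictive number of predictive components (default
#'   `n_classes - 1`).
#' @param n_orthogonal number of orthogonal components (default 1).
#' @return object of class `oplsda` with weights `W`, loadings `P`, scores
#'   `T`, Y-weights `C`, orthogonal counterparts `W_o`, `P_o`, `T_o`, centers
#'   `x_mean`/`y_mean`, fitted values, and metrics `r2x_cum`, `r2y_cum`
#'   (Q2Y is added by [cross_validate_q2()] / [evaluate_preprocessing()]).
#' @export
fit_oplsda <- function(X, Y, n_predictive = NULL, n_orthogonal = 1L) {
  yb <- if (inherits(Y, "yblock")) Y else NULL
  Ym <- if (is.null(yb)) as.matrix(Y) else yb$Y
  X <- as.matrix(X)
  if (nrow(X) != nrow(Ym)) stop("X and Y must have the same number of rows")
  K <- ncol(Ym)
  if (K < 2) stop("Y must have at least 2 classes")
  if (is.null(n_predictive)) n_predictive <- K - 1L
  n_predictive <- as.integer(n_predictive); n_orthogonal <- as.integer(n_orthogonal)
  if (n_predictive < 1) stop("n_predictive must be >= 1")
  x_mean <- colMeans(X); y_mean <- colMeans(Ym)
  Xc <- sweep(X, 2L, x_mean); Yc <- sweep(Ym, 2L, y_mean)
  ssx <- sum(Xc^2); ssy <- sum(Yc^2)
  p <- ncol(X)

  W_o <- matrix(0, p, n_orthogonal); P_o <- matrix(0, p, n_orthogonal)
  T_o <- matrix(0, nrow(X), n_orthogonal)
  Xf <- Xc
  for (j in seq_len(n_orthogonal)) {
    comp <- nipals_pls2(Xf, Yc)
    V <- crossprod(Xf, Yc)                      # p x K, columns span X'Y
    qrv <- qr(V)
    proj <- qr.fitted(qrv, comp$p)              # projection of p onto col(V)
    w_o <- comp$p - proj
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-10 * max(sqrt(sum(comp$p^2)), 1))
      stop("no Y-orthogonal variation left; use fewer orthogonal components")
    w_o <- w_o / nw
    t_o <- drop(Xf %*% w_o)
    p_o <- drop(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o[, j] <- w_o; P_o[, j] <- p_o; T_o[, j] <- t_o
  }

  W <- matrix(0, p, n_predictive); P <- matrix(0, p, n_predictive)
  Tm <- matrix(0, nrow(X), n_predictive); Cm <- matrix(0, K, n_predictive)
  Xd <- Xf; Yd <- Yc
  for (a in seq_len(n_predictive)) {
    comp <- nipals_pls2(Xd, Yd)
    W[, a] <- comp$w; P[, a] <- comp$p
    Tm[, a] <- comp$t; Cm[, a] <- comp$c
    Xd <- Xd - tcrossprod(comp$t, comp$p)
    Yd <- Yd - tcrossprod(comp$t, comp$c)
  }
  fitted_yc <- Tm %*% t(Cm)
  r2y <- 1 - sum((Yc - fitted_yc)^2) / ssy
  r2x <- 1 - sum(Xd^2) / ssx   # explained by orthogonal + predictive together

  structure(
    list(W = W, P = P, T = Tm, C = Cm,
         W_o = W_o, P_o = P_o, T_o = T_o,
         n_predictive = n_predictive, n_orthogonal = n_orthogonal,
         x_mean = x_mean, y_mean = y_mean,
         labels = if (!is.null(yb)) yb$labels else colnames(Ym),
         Xc = Xc, Yc = Yc, ssx = ssx, ssy = ssy,
         fitted = sweep(fitted_yc, 2L, y_mean, `+`),
         r2x_cum = r2x, r2y_cum = r2y, q2y_cum = NA_real_),
    class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("oplsda: %d predictive + %d orthogonal components, %d obs x %d variables\n",
              x$n_predictive, x$n_orthogonal, nrow(x$T), length(x$x_mean)))
  cat(sprintf("  R2X = %.4f  R2Y = %.4f  Q2Y = %s\n", x$r2x_cum, x$r2y_cum,
              if (is.na(x$q2y_cum)) "not cross-validated" else sprintf("%.4f", x$q2y_cum)))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  cls <- colSums(object$Yc + matrix(object$y_mean, nrow(object$Yc),
                                    ncol(object$Yc), byrow = TRUE))
  cat(sprintf("OPLS-DA model: classes %s (n = %s)\n",
              paste(object$labels, collapse = ", "),
              paste(as.integer(cls), collapse = ", ")))
  print(object)
  invisible(object)
}

#' @export
coef.oplsda <- function(object, ...) {
  # regression coefficients mapping centered filtered X to centered Y
  Wstar <- object$W %*% solve(crossprod(object$P, object$W))
  B <- Wstar %*% t(object$C)
  colnames(B) <- object$labels
  B
}

#' @export
residuals.oplsda <- function(object, ...) {
  sweep(object$Yc, 2L, object$y_mean, `+`) - object$fitted
}

#' @export
fitted.oplsda <- function(object, ...) object$fitted

# internal: orthogonal-filter + project new (already centered) rows
oplsda_project <- function(model, Xc) {
  for (j in seq_len(model$n_orthogonal)) {
    t_o <- Xc %*% model$W_o[, j]
    Xc <- Xc - tcrossprod(drop(t_o), model$P_o[, j])
  }
  Tm <- matrix(0, nrow(Xc), model$n_predictive)
  for (a in seq_len(model$n_predictive)) {
    Tm[, a] <- Xc %*% model$W[, a]
    Xc <- Xc - tcrossprod(Tm[, a], model$P[, a])
  }
  Tm
}

#' Predict scores and class membership for new spectra
#'
#' Centers the rows by the training means, strips the Y-orthogonal variation
#' with the training orthogonal weights/loadings, and projects onto the
#' predictive components. Training rows reproduce the training scores; pixels
#' with missing class assignment obtain score values from the similarity of
#' their spectra to the class-assigned pixels.
#'
#' @param object a fitted `oplsda` model.
#' @param newdata matrix or [ims_cube()] on the training peak axis.
#' @param n_components how many predictive components' Y contribution to use
#'   for `y_pred` (default all).
#' @param ... unused.
#' @return list with `scores` (predictive score matrix), `y_pred` (predicted
#'   indicator values) and `class` (label of the largest predicted value).
#' @export
predict.oplsda <- function(object, newdata, n_components = NULL, ...) {
  X <- if (inherits(newdata, "ims_cube")) newdata$intensities else as.matrix(newdata)
  if (ncol(X) != length(object$x_mean))
    stop("peak-axis mismatch: newdata has ", ncol(X), " variables, model has ",
         length(object$x_mean))
  if (is.null(n_components)) n_components <- object$n_predictive
  Tm <- oplsda_project(object, sweep(X, 2L, object$x_mean))
  a <- seq_len(n_components)
  Yp <- Tm[, a, drop = FALSE] %*% t(object$C[, a, drop = FALSE])
  Yp <- sweep(Yp, 2L, object$y_mean, `+`)
  colnames(Yp) <- object$labels
  list(scores = Tm, y_pred = Yp,
       class = object$labels[max.col(Yp, ties.method = "first")])
}

#' Seven-block cross-validated Q2Y
#'
#' Deterministic venetian-blind assignment: row `i` (pixel order) goes to
#' block `((i - 1) mod n_blocks) + 1`. For each block the model is refitted on
#' the remaining rows, the held-out Y is predicted (orthogonal filtering
#' applied to held-out rows with training weights), and
#' `Q2Y = 1 - PRESS / SS` with SS the total sum of squares of Y centered by
#' the training means. Cumulative Q2Y is reported as predictive components
#' are added.
#'
#' @param X matrix of class-assigned spectra.
#' @param Y a `yblock` or indicator matrix.
#' @param n_predictive,n_orthogonal component counts, as in [fit_oplsda()].
#' @param n_blocks number of blocks (default 7; `nrow(X)` gives leave-one-out).
#' @return list with `q2_cum` (per component count), `q2_gains`, `q2y`
#'   (cumulative at all components), `press`, `ss`, `n_blocks`.
#' @export
cross_validate_q2 <- function(X, Y, n_predictive = NULL, n_orthogonal = 1L,
                              n_blocks = 7L) {
  Ym <- if (inherits(Y, "yblock")) Y$Y else as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(n_predictive)) n_predictive <- ncol(Ym) - 1L
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2 || n_blocks > n) stop("n_blocks must be in 2..n")
  if (any(colSums(Ym) < 2))
    stop("every class needs at least 2 members for cross-validation")
  block <- ((seq_len(n) - 1L) %% n_blocks) + 1L
  press <- numeric(n_predictive)
  ss <- 0
  for (b in seq_len(n_blocks)) {
    held <- block == b
    if (any(colSums(Ym[!held, , drop = FALSE]) == 0))
      stop(sprintf("cross-validation fold %d loses an entire class", b))
    fit <- fit_oplsda(X[!held, , drop = FALSE], Ym[!held, , drop = FALSE],
                      n_predictive, n_orthogonal)
    Yh <- sweep(Ym[held, , drop = FALSE], 2L, fit$y_mean)
    ss <- ss + sum(Yh^2)
    Th <- oplsda_project(fit, sweep(X[held, , drop = FALSE], 2L, fit$x_mean))
    cum <- matrix(0, sum(held), ncol(Ym))
    for (a in seq_len(n_predictive)) {
      cum <- cum + tcrossprod(Th[, a], fit$C[, a])
      press[a] <- press[a] + sum((Yh - cum)^2)
    }
  }
  q2_cum <- 1 - press / ss
  list(q2_cum = q2_cum, q2_gains = diff(c(0, q2_cum)),
       q2y = q2_cum[n_predictive], press = press, ss = ss,
       n_blocks = n_blocks)
}

#' Select the number of components by Q2 gain
#'
#' Returns the largest leading run of components whose individual Q2Y gain
#' meets the cutoff; the cutoff balances sensitivity to weakly expressed
#' classes against overfitting and may need lowering to admit components
#' carrying small regions.
#'
#' @param q2_gains per-component Q2Y gains (from [cross_validate_q2()]).
#' @param cutoff minimum admissible gain (default 0.01).
#' @return integer component count (0, with a warning, when even the first
#'   gain is below the cutoff).
#' @export
select_components <- function(q2_gains, cutoff = 0.01) {
  below <- which(q2_gains < cutoff)
  a <- if (length(below)) below[1] - 1L else length(q2_gains)
  if (a == 0L) warning("no component reaches the Q2 gain cutoff")
  as.integer(a)
}

#' S-plot coordinates for a predictive component
#'
#' For each variable, the covariance and correlation between its centered
#' training values and the chosen predictive score vector; the classical
#' loading visualization for spotting ROI-marker ions. Zero-variance
#' variables yield `NA`.
#'
#' @param model a fitted `oplsda`.
#' @param component predictive component index (default 1).
#' @return data.frame with `variable`, `mz` (if known), `covariance`,
#'   `correlation`.
#' @export
s_plot <- function(model, component = 1) {
  stopifnot(inherits(model, "oplsda"))
  if (component < 1 || component > model$n_predictive)
    stop("component index out of range")
  t <- model$T[, component]
  n <- length(t)
  covar <- drop(crossprod(model$Xc, t)) / (n - 1)
  sdx <- apply(model$Xc, 2L, stats::sd)
  corr <- ifelse(sdx > 0, covar / (stats::sd(t) * sdx), NA_real_)
  covar[sdx == 0] <- covar[sdx == 0]  # covariance is 0 there anyway
  data.frame(variable = seq_along(covar),
             mz = if (!is.null(attr(model, "mz"))) attr(model, "mz") else NA_real_,
             covariance = covar, correlation = corr)
}

#' @export
plot.oplsda <- function(x, components = c(1, 2), alpha = 0.95, ...) {
  s <- x$T[, components, drop = FALSE]
  cls <- max.col(x$Yc, ties.method = "first")
  graphics::plot(s[, 1], s[, 2], col = cls, pch = 16, cex = 0.6,
                 xlab = sprintf("t%d", components[1]),
                 ylab = sprintf("t%d", components[2]), ...)
  ho <- hotelling_outside_fraction(s, alpha)
  th <- seq(0, 2 * pi, length.out = 181)
  ell <- ho$center + t(ho$chol_cov %*% rbind(cos(th), sin(th)) * sqrt(ho$t2_limit))
  graphics::lines(ell[, 1], ell[, 2], lty = 2)
  invisible(x)
}

#' Rank preprocessing methods by OPLS-DA predictive quality
#'
#' Applies each preprocessing specification to the same raw cube, fits an
#' OPLS-DA model on the identically-labelled pixels with identical
#' cross-validation blocks, and tabulates the model metrics sorted by Q2Y
#' (descending). Per-spec failures are annotated, not fatal.
#'
#' @param raw_cube a raw [ims_cube()].
#' @param specs list of [preprocess_spec()]s or names for [parse_spec()].
#' @param class_map a [build_class_map()] result on the cube's grid.
#' @param n_predictive,n_orthogonal,n_blocks modeling/CV settings.
#' @return data.frame (class `preproc_ranking`) with columns `spec`, `r2x`,
#'   `r2y`, `q2y`, `a_p`, `a_o`, `q2_gains`, `note`.
#' @export
evaluate_preprocessing <- function(raw_cube, specs, class_map,
                                   n_predictive = NULL, n_orthogonal = 1L,
                                   n_blocks = 7L) {
  stopifnot(inherits(raw_cube, "ims_cube"), length(specs) >= 1)
  yb <- make_yblock(class_map, raw_cube$coords,
                    min_class_size = 2L * n_blocks)
  rows <- lapply(specs, function(sp) {
    if (is.character(sp)) sp <- parse_spec(sp)
    name <- format(sp)
    res <- tryCatch({
      cube_p <- suppressWarnings(apply_preprocess(raw_cube, sp))
      Xp <- cube_p$intensities[yb$pixel_index, , drop = FALSE]
      fit <- fit_oplsda(Xp, yb, n_predictive, n_orthogonal)
      cv <- cross_validate_q2(Xp, yb, n_predictive, n_orthogonal, n_blocks)
      data.frame(spec = name, r2x = fit$r2x_cum, r2y = fit$r2y_cum,
                 q2y = cv$q2y, a_p = fit$n_predictive, a_o = n_orthogonal,
                 q2_gains = paste(sprintf("%.4f", cv$q2_gains), collapse = ";"),
                 note = "")
    }, error = function(e) {
      data.frame(spec = name, r2x = NA_real_, r2y = NA_real_, q2y = NA_real_,
                 a_p = NA_integer_, a_o = n_orthogonal, q2_gains = "",
                 note = conditionMessage(e))
    })
    res
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-ifelse(is.na(tab$q2y), -Inf, tab$q2y)), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("preproc_ranking", "data.frame")
  tab
}

#' @export
print.preproc_ranking <- function(x, ...) {
  cat("Preprocessing ranking by cross-validated Q2Y:\n")
  df <- as.data.frame(x)
  df$r2x <- round(df$r2x, 4); df$r2y <- round(df$r2y, 4)
  df$q2y <- round(df$q2y, 4)
  print(df[, c("spec", "r2x", "r2y", "q2y", "a_p", "a_o", "note")])
  invisible(x)
}
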