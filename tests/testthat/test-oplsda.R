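test_that("Y-block construction tracks classes and missing pixels", {
  map <- matrix(NA_integer_, 2, 4)
  map[1, 1:3] <- 1L; map[2, 1:2] <- 2L
  cm <- structure(list(map = map, labels = c("A", "B"),
                       counts = c(A = 3, B = 2), grid = c(2L, 4L)),
                  class = "class_map")
  coords <- list(x = rep(0:3, each = 2), y = rep(0:1, 4), grid = c(2L, 4L))
  yb <- make_yblock(cm, coords, min_class_size = 2)
  expect_equal(dim(yb$Y), c(5, 2))
  expect_equal(unname(colSums(yb$Y)), c(3, 2))
  expect_equal(rowSums(yb$Y), rep(1, 5))
  expect_equal(length(yb$missing_index), 3)
  expect_error(make_yblock(cm, coords, min_class_size = 5), "below the minimum")
  # all pixels missing
  cm$map[] <- NA_integer_
  expect_error(make_yblock(cm, coords), "missing-class")
})

test_that("with zero orthogonal components the fit equals reference PLS2", {
  d <- toy_classes(seed = 2)
  fit <- fit_oplsda(d$X, d$Y, n_predictive = 2, n_orthogonal = 0)
  expect_equal(fit$fitted, oracle_pls2(d$X, d$Y, 2), tolerance = 1e-8)
})

test_that("orthogonal scores are orthogonal to Y and predictive scores", {
  ph <- generate_phantom(small_phantom_config(), seed = 3)
  yb <- make_yblock(ph$truth, ph$cube$coords)
  X <- log(ph$cube$intensities + 1)[yb$pixel_index, ]
  fit <- fit_oplsda(X, yb, n_predictive = 3, n_orthogonal = 2)
  Yc <- sweep(yb$Y, 2, colMeans(yb$Y))
  expect_lt(max(abs(crossprod(fit$T_o, Yc))), 1e-8 * sqrt(sum(yb$Y^2)))
  expect_lt(norm(crossprod(fit$T, fit$T_o), "F"),
            1e-8 * norm(fit$T, "F") * norm(fit$T_o, "F"))
  expect_equal(unname(colSums(fit$W^2)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(colSums(fit$W_o^2)), rep(1, 2), tolerance = 1e-12)
})

test_that("two separable classes reach R2Y ~ 1 with one component", {
  with_seed_test(7, {
    X <- cbind(c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01)),
               matrix(rnorm(40, 0, 0.01), 20, 2))
    Y <- cbind(rep(c(1, 0), each = 10), rep(c(0, 1), each = 10))
    fit <- fit_oplsda(X, Y, n_predictive = 1, n_orthogonal = 0)
    expect_gte(fit$r2y_cum, 0.99)
  })
})

test_that("Q2Y <= R2Y and CV is deterministic", {
  ph <- generate_phantom(small_phantom_config(), seed = 5)
  yb <- make_yblock(ph$truth, ph$cube$coords)
  X <- log(ph$cube$intensities + 1)[yb$pixel_index, ]
  fit <- fit_oplsda(X, yb, 3, 1)
  cv1 <- cross_validate_q2(X, yb, 3, 1)
  cv2 <- cross_validate_q2(X, yb, 3, 1)
  expect_identical(cv1, cv2)
  expect_lte(cv1$q2y, fit$r2y_cum)
  expect_lte(fit$r2y_cum, 1)
  expect_true(all(diff(cv1$q2_cum) >= -1e-9))  # gains are non-negative here
})

test_that("label permutation drives Q2Y to chance", {
  ph <- generate_phantom(small_phantom_config(), seed = 1)
  yb <- make_yblock(ph$truth, ph$cube$coords)
  keep <- seq(1, nrow(yb$Y), by = 6)
  X <- log(ph$cube$intensities + 1)[yb$pixel_index[keep], ]
  Y <- yb$Y[keep, ]
  for (s in 1:3) {
    perm <- with_seed_test(100 + s, sample(nrow(Y)))
    cv <- cross_validate_q2(X, Y[perm, ], 3, 1)
    expect_lte(cv$q2y, 0.05)
  }
})

test_that("n_blocks = n reproduces an independent leave-one-out", {
  d <- toy_classes(n_per = 7, p = 5, seed = 4)
  keep <- 1:20
  X <- d$X[keep, ]; Y <- d$Y[keep, ]
  cv <- cross_validate_q2(X, Y, n_predictive = 2, n_orthogonal = 1,
                          n_blocks = 20)
  # independent LOO: explicit loop, PRESS accumulated per left-out row
  press <- 0; ss <- 0
  for (i in keep) {
    fit <- fit_oplsda(X[-i, ], Y[-i, ], 2, 1)
    pr <- predict(fit, X[i, , drop = FALSE])
    press <- press + sum((Y[i, ] - pr$y_pred)^2)
    ss <- ss + sum((Y[i, ] - fit$y_mean)^2)
  }
  expect_equal(cv$q2y, 1 - press / ss, tolerance = 1e-10)
})

test_that("component selection applies the Q2 gain cutoff", {
  expect_equal(select_components(c(0.4, 0.2, 0.005), 0.01), 2)
  expect_equal(select_components(c(0.4, 0.2, 0.005), 0.001), 3)
  expect_warning(a <- select_components(c(0.005, 0.002), 0.01), "cutoff")
  expect_equal(a, 0)
})

test_that("prediction is self-consistent and centers to zero scores", {
  d <- toy_classes(seed = 6)
  fit <- fit_oplsda(d$X, d$Y, 2, 1)
  pr <- predict(fit, d$X)
  expect_equal(pr$scores, fit$T, tolerance = 1e-8, ignore_attr = TRUE)
  mean_row <- matrix(fit$x_mean, 1)
  expect_equal(drop(predict(fit, mean_row)$scores), c(0, 0), tolerance = 1e-10)
  expect_error(predict(fit, d$X[, 1:3]), "mismatch")
})

test_that("missing-class phantom pixels score nearest their true class", {
  ph <- generate_phantom(phantom_config(), seed = 2)
  # degrade the truth: relabel a band of PCL pixels as missing
  cm <- ph$truth
  pcl_idx <- which(cm$map == 3L)
  drop_idx <- pcl_idx[seq(1, length(pcl_idx), by = 4)]
  cm$map[drop_idx] <- NA_integer_
  cm$counts[3] <- cm$counts[3] - length(drop_idx)
  ln <- transform_intensities(ph$cube, "ln")
  yb <- make_yblock(cm, ln$coords)
  fit <- fit_oplsda(ln$intensities[yb$pixel_index, ], yb, 3, 1)
  # centroids of assigned pixels in score space
  cls <- max.col(yb$Y)
  cent <- t(vapply(1:4, function(k) colMeans(fit$T[cls == k, ]), numeric(3)))
  lab_img <- matrix(NA_integer_, cm$grid[1], cm$grid[2])
  lab_img[drop_idx] <- 3L
  held <- which(!is.na(image_to_vector(lab_img + 0, ln$coords)))
  sc <- predict(fit, ln$intensities[held, ])$scores
  d2 <- vapply(1:4, function(k)
    rowSums(sweep(sc, 2, cent[k, ])^2), numeric(nrow(sc)))
  expect_gte(mean(max.col(-d2) == 3), 0.9)
})

test_that("S-plot matches the direct covariance/correlation formulas", {
  d <- toy_classes(seed = 8)
  fit <- fit_oplsda(d$X, d$Y, 2, 0)
  sp <- s_plot(fit, 1)
  t1 <- fit$T[, 1]
  Xc <- sweep(d$X, 2, colMeans(d$X))
  for (j in seq_len(ncol(d$X))) {
    expect_equal(sp$covariance[j], cov(Xc[, j], t1), tolerance = 1e-10)
    expect_equal(sp$correlation[j], cor(Xc[, j], t1), tolerance = 1e-10)
  }
  # zero-variance variable yields a missing correlation and zero covariance
  X2 <- cbind(d$X, 7)
  fit2 <- fit_oplsda(X2, d$Y, 2, 0)
  sp2 <- s_plot(fit2, 1)
  expect_true(is.na(sp2$correlation[ncol(X2)]))
  expect_equal(sp2$covariance[ncol(X2)], 0, tolerance = 1e-12)
})

test_that("duplicate specs rank identically and failures annotate", {
  ph <- generate_phantom(small_phantom_config(), seed = 7)
  tab <- evaluate_preprocessing(ph$cube, list("ln", "ln"), ph$truth)
  expect_equal(tab$q2y[1], tab$q2y[2], tolerance = 0)
  expect_identical(tab$spec[1], tab$spec[2])
})
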