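two_region_cube <- function() {
  # 3-pixel ROI "A", 2-pixel ROI "B" on a 1 x 5 strip
  m <- rbind(c(1, 2), c(3, 2), c(2, 2), c(1, 5), c(3, 5))
  cube <- ims_cube(m, mz = c(100, 200), x = 0:4, y = rep(0L, 5))
  map <- matrix(c(1L, 1L, 1L, 2L, 2L), 1, 5)
  cm <- structure(list(map = map, labels = c("A", "B"),
                       counts = c(A = 3, B = 2), grid = c(1L, 5L)),
                  class = "class_map")
  list(cube = cube, cm = cm)
}

test_that("noise profiles report sorted per-peak mean and sample SD", {
  d <- two_region_cube()
  pr <- roi_noise_profile(d$cube, d$cm, "A")
  expect_equal(pr$mean, c(2, 2))
  expect_equal(pr$sd, c(1, 0))       # ties in mean keep peak order stable
  expect_true(all(diff(pr$mean) >= 0))
  # 2-pixel ROI with values (1, 3): mean 2, SD sqrt(2)
  cube2 <- ims_cube(rbind(1, 3), mz = 100, x = 0:1, y = c(0L, 0L))
  map2 <- matrix(1L, 1, 2)
  cm2 <- structure(list(map = map2, labels = "R", counts = c(R = 2),
                        grid = c(1L, 2L)), class = "class_map")
  cube3 <- ims_cube(rbind(c(1, 1), c(3, 3), c(2, 2)), mz = c(1, 2),
                    x = 0:2, y = rep(0L, 3))
  cm3 <- structure(list(map = matrix(1L, 1, 3), labels = "R",
                        counts = c(R = 3), grid = c(1L, 3L)),
                   class = "class_map")
  pr3 <- roi_noise_profile(cube3, cm3, "R")
  expect_equal(pr3$sd, rep(1, 2))
  expect_error(roi_noise_profile(d$cube, d$cm, "Z"), "unknown")
  expect_error(roi_noise_profile(cube2, cm2, "R"), "fewer than 3")
})

test_that("profile oracle: mean/SD agree with a direct two-pass computation", {
  ph <- generate_phantom(small_phantom_config(), seed = 1)
  pr <- roi_noise_profile(ph$cube, ph$truth, "GL")
  idx <- which(image_to_vector(ph$truth$map + 0, ph$cube$coords) == 2)
  X <- ph$cube$intensities[idx, ]
  for (j in c(1, 40, 120)) {
    row <- which(pr$peak == j)
    m <- sum(X[, j]) / nrow(X)
    expect_equal(pr$mean[row], m, tolerance = 1e-12)
    expect_equal(pr$sd[row], sqrt(sum((X[, j] - m)^2) / (nrow(X) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("heteroscedasticity index reads the mean-SD association", {
  mk <- function(mean, sd) {
    structure(data.frame(peak = seq_along(mean), mz = seq_along(mean),
                         mean = mean, sd = sd),
              class = c("noise_profile", "data.frame"))
  }
  m <- seq(1, 100, length.out = 50)
  expect_equal(heteroscedasticity_index(mk(m, 0.3 * m)), 1)
  with_seed_test(2, {
    idx <- heteroscedasticity_index(mk(seq_len(200), 1 + abs(rnorm(200, 0, 1e-3))))
    expect_lte(abs(idx), 0.1)
  })
  expect_error(heteroscedasticity_index(mk(1:5, rep(1, 5))), "fewer than")
})

test_that("RSD matches closed forms and scale invariance", {
  cube <- ims_cube(rbind(c(1, 2), c(1, 4), c(1, 3)), mz = c(1, 2),
                   x = 0:2, y = rep(0L, 3))
  cm <- structure(list(map = matrix(1L, 1, 3), labels = "R", counts = c(R = 3),
                       grid = c(1L, 3L)), class = "class_map")
  expect_equal(roi_rsd(cube, cm, "R", 1), 0)
  expect_equal(roi_rsd(cube, cm, "R", 2), 1 / 3)
  scaled <- cube; scaled$intensities <- cube$intensities * 50
  expect_equal(roi_rsd(scaled, cm, "R", 2), roi_rsd(cube, cm, "R", 2),
               tolerance = 1e-12)
  zero <- cube; zero$intensities[, 1] <- 0
  expect_error(roi_rsd(zero, cm, "R", 1), "zero mean")
})

test_that("ln transform halves the PCL marker RSD on the phantom", {
  ph <- generate_phantom(phantom_config(), seed = 1)
  pk <- ph$config$markers$pcl[1]
  raw_rsd <- roi_rsd(ph$cube, ph$truth, "PCL", pk)
  ln_rsd <- roi_rsd(transform_intensities(ph$cube, "ln"), ph$truth, "PCL", pk)
  expect_lte(ln_rsd, 0.5 * raw_rsd)
})

test_that("Hotelling ellipse excludes ~5% of a large normal sample", {
  sc <- with_seed_test(99, matrix(rnorm(10000), 5000, 2) %*%
                         matrix(c(2, 0.5, 0, 1), 2, 2))
  ho <- hotelling_outside_fraction(sc, 0.95)
  expect_lt(abs(ho$fraction_outside - 0.05), 0.02)
  # scale equivariance: doubling both columns changes nothing
  ho2 <- hotelling_outside_fraction(sc * 2, 0.95)
  expect_equal(ho2$fraction_outside, ho$fraction_outside)
  expect_equal(ho2$t2, ho$t2, tolerance = 1e-10)
  expect_error(hotelling_outside_fraction(cbind(rep(1, 20), rnorm(20))),
               "degenerate")
  expect_error(hotelling_outside_fraction(sc[1:5, ]), "at least 10")
})

test_that("box-plot statistics match the quantile oracle", {
  cube <- ims_cube(matrix(c(-2, -1, 0, 1, 2) + 10, 5, 1), mz = 1,
                   x = 0:4, y = rep(0L, 5))
  cm <- structure(list(map = matrix(1L, 1, 5), labels = "R", counts = c(R = 5),
                       grid = c(1L, 5L)), class = "class_map")
  bs <- roi_boxplot_stats(cube, cm, "R", 1)
  expect_equal(bs$median, 0)
  expect_equal(c(bs$q1, bs$q3), c(-1, 1))
  expect_equal(bs$whisker_low, -2); expect_equal(bs$whisker_high, 2)
  # centered by construction; quartiles equal type-7 quantiles on the phantom
  ph <- generate_phantom(small_phantom_config(), seed = 6)
  bs2 <- roi_boxplot_stats(ph$cube, ph$truth, "WM", 3)
  idx <- which(image_to_vector(ph$truth$map + 0, ph$cube$coords) == 1)
  v <- ph$cube$intensities[idx, 3]; v <- v - mean(v)
  expect_equal(mean(v), 0, tolerance = 1e-9)
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  expect_equal(c(bs2$q1, bs2$median, bs2$q3), q, tolerance = 1e-12)
  expect_equal(bs2$sd, sd(v), tolerance = 1e-12)
})
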