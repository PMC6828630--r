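test_that("energy reduces to the smoothness term on constant images", {
  img <- matrix(1, 5, 5)
  mask <- matrix(FALSE, 5, 5); mask[2:3, 2:4] <- TRUE
  per <- oracle_cv_energy(img, mask, 1)  # data term 0, so this is Perimeter
  expect_equal(chan_vese_energy(img, mask, 0.3), 0.3 * per)
  # exact two-level partition has zero energy at mu = 0
  img2 <- matrix(c(0, 10), 1, 2)
  m2 <- matrix(c(TRUE, FALSE), 1, 2)
  expect_equal(chan_vese_energy(img2, m2, 0), 0)
})

test_that("energy matches the brute-force oracle on random multichannel masks", {
  with_seed_test(8, {
    img <- array(rnorm(6 * 7 * 3), dim = c(6, 7, 3))
    img[1, 1, ] <- NA  # off-tissue pixel
    v <- !is.na(img[, , 1])
    for (i in 1:25) {
      mask <- matrix(runif(42) > 0.5, 6, 7)
      if (!any(mask & v) || !any(!mask & v)) next
      mu <- runif(1, 0, 0.5)
      expect_equal(chan_vese_energy(img, mask, mu),
                   oracle_cv_energy(img, mask, mu), tolerance = 1e-10)
    }
  })
})

test_that("energy requires pixels on both sides", {
  img <- matrix(rnorm(16), 4, 4)
  expect_error(chan_vese_energy(img, matrix(TRUE, 4, 4), 0.1), "inside and outside")
  expect_error(chan_vese_energy(img, matrix(FALSE, 4, 4), 0.1), "inside and outside")
})

test_that("contour evolution recovers a piecewise-constant region exactly", {
  img <- matrix(1, 16, 16)
  truth <- matrix(FALSE, 16, 16); truth[5:12, 4:13] <- TRUE
  img[truth] <- 5
  seed <- matrix(FALSE, 16, 16); seed[7:10, 6:11] <- TRUE  # eroded truth
  m <- evolve_contour(img, seed, acs_params(30, 0.2))
  expect_equal(unname(m == TRUE), truth, ignore_attr = TRUE)
})

test_that("a two-level energy minimum is a fixed point at mu = 0", {
  img <- matrix(c(0, 0, 10, 10), 2, 2)
  seed <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  m <- evolve_contour(img, seed, acs_params(10, 0, hole_fill = FALSE))
  expect_equal(unclass(m), seed, ignore_attr = TRUE)
})

test_that("energy is non-increasing across iterations", {
  with_seed_test(21, {
    img <- matrix(rnorm(400), 20, 20) + outer(1:20, 1:20, function(r, c) (c > 10) * 3)
    seed <- matrix(FALSE, 20, 20); seed[5:15, 12:18] <- TRUE
    m <- evolve_contour(img, seed, acs_params(25, 0.2))
    tr <- attr(m, "energy_trace")
    expect_true(all(diff(tr) <= 1e-9))
    expect_lte(tail(tr, 1), tr[1])
  })
})

test_that("evolution attains the brute-force global minimum on a 4x4 instance", {
  img <- matrix(0, 4, 4); img[2:4, 2:3] <- 10
  mu <- 0.5
  with_seed_test(13, {
    best <- Inf
    for (code in sample(1:65534, 400)) {  # spot-check energies; full sweep in acceptance
      m <- matrix(bitwAnd(code, 2^(0:15)) > 0, 4, 4)
      expect_equal(chan_vese_energy(img, m, mu), oracle_cv_energy(img, m, mu),
                   tolerance = 1e-10)
    }
  })
  seed <- matrix(FALSE, 4, 4); seed[3:4, 2] <- TRUE; seed[4, 3] <- TRUE
  ev <- evolve_contour(img, seed, acs_params(30, mu))
  # global optimum is the true region (perimeter 8, data term 0): E = 4
  expect_equal(chan_vese_energy(img, ev, mu), mu * 8)
  expect_equal(unname(sum(ev)), 6)
})

test_that("mask refinement fills holes and is idempotent", {
  ring <- matrix(TRUE, 5, 5); ring[2:4, 2:4] <- FALSE; ring[3, 3] <- FALSE
  filled <- refine_mask(ring, hole_fill = TRUE)
  expect_true(all(filled))
  solid <- matrix(FALSE, 6, 6); solid[2:4, 2:5] <- TRUE
  expect_identical(refine_mask(solid), solid)
  with_seed_test(4, {
    for (i in 1:10) {
      m <- matrix(runif(64) > 0.6, 8, 8)
      r1 <- refine_mask(m, TRUE, 3)
      expect_identical(refine_mask(r1, TRUE, 3), r1)
    }
  })
  # small-object removal
  m <- matrix(FALSE, 6, 6); m[1:3, 1:3] <- TRUE; m[6, 6] <- TRUE
  expect_equal(sum(refine_mask(m, FALSE, 2)), 9)
})

test_that("class map resolves ambiguity into missing class", {
  a <- matrix(FALSE, 2, 3); a[, 1] <- TRUE
  b <- matrix(FALSE, 2, 3); b[, 2:3] <- TRUE
  cm <- build_class_map(list(L = a, R = b))
  expect_equal(sum(is.na(cm$map)), 0)
  expect_equal(unname(cm$counts), c(2, 4))
  # fully overlapping masks: everything ambiguous
  cm2 <- build_class_map(list(L = b, R = b))
  expect_true(all(is.na(cm2$map)))
  # constructed 3-pixel overlap
  c1 <- matrix(FALSE, 4, 4); c1[1:3, 1:2] <- TRUE
  c2 <- matrix(FALSE, 4, 4); c2[1:3, 2:3] <- TRUE
  cm3 <- build_class_map(list(A = c1, B = c2))
  expect_equal(sum(is.na(cm3$map)) - sum(!(c1 | c2)), 3)
  expect_error(build_class_map(list(a)), "at least 2")
  expect_error(build_class_map(stats::setNames(list(a, b), c("X", "X"))),
               "unique")
})

test_that("overlap ratio is Jaccard and Dice is reported alongside", {
  a <- matrix(FALSE, 3, 3); a[1:2, 1:2] <- TRUE
  expect_equal(overlap_ratio(a, a), 1)
  b <- matrix(FALSE, 3, 3); b[3, 3] <- TRUE
  expect_equal(overlap_ratio(a, b), 0)
  c1 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  c2 <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  # |A ∩ B| = 2, |A ∪ B| = 4 -> 0.5; Dice = 2*2/6
  expect_equal(overlap_ratio(c1, c2), 0.5)
  expect_equal(dice_coefficient(c1, c2), 2 / 3)
  expect_error(overlap_ratio(b & !b, b & !b), "empty")
})

test_that("segmentation is equivariant to affine channel rescaling", {
  ph <- generate_phantom(small_phantom_config(), seed = 9)
  ln <- transform_intensities(ph$cube, "ln")
  fit <- ims_pca(ln, 5)
  st <- score_stack(fit, 1:4, standardize = TRUE)
  st2 <- st * 3 + 1   # affine rescale of every channel
  seeds <- perturb_seeds(ph$truth, 1, 1, seed = 9)
  m1 <- evolve_contour(st, seeds$GL, acs_params(15, 0.2))
  m2 <- evolve_contour(st2, seeds$GL, acs_params(15, 0.2 * 9))
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])
})

test_that("polygon seeds rasterize by the even-odd rule", {
  sq <- seed_from_polygon(rbind(c(0.5, 0.5), c(3.5, 0.5), c(3.5, 3.5),
                                c(0.5, 3.5)), c(5, 5))
  expect_equal(sum(sq), 9)
  expect_true(sq[2, 2] && sq[4, 4] && !sq[1, 1])
})
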