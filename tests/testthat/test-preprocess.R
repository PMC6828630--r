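analytic_cube <- function() {
  ims_cube(matrix(c(2, 4, 6, 8), 1, 4), mz = c(100, 200, 300, 400),
           x = 0, y = 0)
}

test_that("normalizations reproduce the closed-form vectors", {
  cube <- analytic_cube()
  expect_equal(normalize_spectra(cube, "tic")$intensities[1, ],
               c(0.1, 0.2, 0.3, 0.4))
  expect_equal(normalize_spectra(cube, "rms")$intensities[1, ],
               c(2, 4, 6, 8) / sqrt(30))
  expect_equal(normalize_spectra(cube, "max")$intensities[1, ],
               c(0.25, 0.5, 0.75, 1.0))
  expect_equal(normalize_spectra(cube, "median")$intensities[1, ],
               c(0.4, 0.8, 1.2, 1.6))
  expect_equal(normalize_spectra(cube, "mean")$intensities[1, ],
               c(2, 4, 6, 8) / 5)
})

test_that("transformations are elementwise and handle zero", {
  cube <- ims_cube(matrix(c(0, 1, 4, 9), 1, 4), mz = 1:4 * 100, x = 0, y = 0)
  expect_equal(transform_intensities(cube, "sqrt")$intensities[1, ],
               c(0, 1, 2, 3))
  expect_equal(transform_intensities(cube, "ln")$intensities[1, 1], 0)
  expect_equal(transform_intensities(cube, "log10")$intensities[1, ],
               log10(c(0, 1, 4, 9) + 1))
  neg <- cube; neg$intensities[1, 1] <- -1
  expect_error(transform_intensities(neg, "sqrt"), "negative")
})

test_that("transforms preserve within-spectrum rank order", {
  cube <- tiny_cube(n = 6, p = 20, seed = 11)
  for (m in c("sqrt", "ln", "log10")) {
    tr <- transform_intensities(cube, m)
    for (i in 1:6)
      expect_identical(order(tr$intensities[i, ]),
                       order(cube$intensities[i, ]))
  }
})

test_that("normalizations are scale-equivariant and hit unit statistics", {
  cube <- tiny_cube(n = 8, p = 15, seed = 5)
  scaled <- cube
  scaled$intensities <- cube$intensities * 37.5
  for (m in c("tic", "median", "mean", "rms", "max")) {
    a <- normalize_spectra(cube, m)$intensities
    b <- normalize_spectra(scaled, m)$intensities
    expect_equal(a, b, tolerance = 1e-12, label = m)
  }
  expect_equal(rowSums(normalize_spectra(cube, "tic")$intensities),
               rep(1, 8), tolerance = 1e-12)
  expect_equal(apply(normalize_spectra(cube, "max")$intensities, 1, max),
               rep(1, 8), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(normalize_spectra(cube, "rms")$intensities^2)),
               rep(1, 8), tolerance = 1e-12)
})

test_that("degenerate rows are skipped, not divided by zero", {
  cube <- ims_cube(matrix(c(0, 0, 0, 0,
                            2, 4, 6, 8), 2, 4, byrow = TRUE),
                   mz = 1:4 * 100, x = c(0, 1), y = c(0, 0))
  # empty spectrum: ln maps zeros to zeros, median of positives undefined
  expect_warning(out <- apply_preprocess(cube, preprocess_spec("ln", "median")),
                 "skipped")
  expect_equal(out$intensities[1, ], rep(0, 4))
  expect_equal(attr(out, "skipped_rows"), 1L)
  # max normalization of an all-zero row divides by zero scale: also skipped
  expect_warning(out2 <- normalize_spectra(cube, "max"), "skipped")
  expect_equal(out2$intensities[1, ], rep(0, 4))
})

test_that("apply_preprocess composes transform then normalize", {
  cube <- tiny_cube(n = 5, p = 12, seed = 9)
  spec <- preprocess_spec("ln", "median")
  composed <- apply_preprocess(cube, spec)
  manual <- normalize_spectra(transform_intensities(cube, "ln", 1), "median")
  expect_equal(composed$intensities, manual$intensities)
  expect_identical(composed$history, manual$history)
  # identity spec
  id <- apply_preprocess(cube, preprocess_spec())
  expect_equal(id$intensities, cube$intensities)
  # re-application refused
  expect_error(apply_preprocess(composed, spec), "already processed")
})

test_that("spec names parse in the compact style", {
  expect_identical(format(parse_spec("ln-median")), "ln-median")
  expect_identical(parse_spec("raw")$transformation, "none")
  expect_identical(parse_spec("tic")$normalization, "tic")
  expect_identical(parse_spec("sqrt")$transformation, "sqrt")
  expect_error(parse_spec("log2"), "valid names")
})
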