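# Independent oracles and small fixtures used across the test files. These
# deliberately take different computational routes from the package code they
# check.

# brute-force vector-valued Chan-Vese energy: explicit loops over channels
# and 4-neighbour pairs
oracle_cv_energy <- function(img, mask, mu) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  h <- dim(img)[1]; w <- dim(img)[2]; C <- dim(img)[3]
  valid <- !apply(img, c(1, 2), function(v) any(is.na(v)))
  mask <- mask & valid
  e_data <- 0
  for (c in seq_len(C)) {
    u <- img[, , c]
    c1 <- mean(u[mask & valid]); c2 <- mean(u[!mask & valid])
    e_data <- e_data + sum((u[mask & valid] - c1)^2) +
      sum((u[!mask & valid] - c2)^2)
  }
  per <- 0
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!valid[r, cc]) next
    if (cc < w && valid[r, cc + 1] && mask[r, cc] != mask[r, cc + 1])
      per <- per + 1
    if (r < h && valid[r + 1, cc] && mask[r, cc] != mask[r + 1, cc])
      per <- per + 1
  }
  mu * per + e_data / C
}

# independent bilinear PLS2: the dominant weight vector is computed by an
# eigendecomposition of X'YY'X (not by NIPALS iteration), with the same
# X- and Y-deflation scheme
oracle_pls2 <- function(X, Y, A) {
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xd <- sweep(X, 2, x_mean); Yd <- sweep(Y, 2, y_mean)
  Yhat <- matrix(0, nrow(X), ncol(Y))
  for (a in seq_len(A)) {
    M <- crossprod(crossprod(Xd, Yd))          # K x K: Y'XX'Y
    ev <- eigen(M, symmetric = TRUE)
    q <- ev$vectors[, 1]
    w <- crossprod(Xd, Yd %*% q)
    w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    cc <- drop(crossprod(Yd, t)) / sum(t^2)
    Yhat <- Yhat + tcrossprod(t, cc)
    Xd <- Xd - tcrossprod(t, p)
    Yd <- Yd - tcrossprod(t, cc)
  }
  sweep(Yhat, 2, y_mean, `+`)
}

# tiny deterministic raw cube for I/O and preprocessing tests
tiny_cube <- function(n = 10, p = 5, seed = 42) {
  with_seed_test(seed, {
    ims_cube(matrix(round(runif(n * p, 0, 100), 3), n, p),
             mz = round(seq(100, 500, length.out = p), 4),
             x = (seq_len(n) - 1) %% 4, y = (seq_len(n) - 1) %/% 4)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# small phantom configuration for fast model tests (identical physics,
# quarter-size geometry)
small_phantom_config <- function(...) {
  phantom_config(grid_shape = c(48L, 48L), center = c(23.5, 70),
                 radii = c(22, 35, 45, 59), w_pcl = 2L, ...)
}

# minimal processed-mode imzML writer for reader tests (per-spectrum m/z)
write_processed_imzml <- function(spectra, coords, path) {
  ibd <- sub("\\.imzML$", ".ibd", path)
  con <- file(ibd, "wb")
  writeBin(as.raw(rep(0L, 16L)), con)
  offset <- 16
  entries <- list()
  for (i in seq_along(spectra)) {
    mz <- spectra[[i]]$mz; int <- spectra[[i]]$intensity
    writeBin(as.double(mz), con, size = 8, endian = "little")
    writeBin(as.double(int), con, size = 8, endian = "little")
    entries[[i]] <- list(mz_off = offset, int_off = offset + 8 * length(mz),
                         len = length(mz))
    offset <- offset + 16 * length(mz)
  }
  close(con)
  bda <- function(ref, off, len) paste0(
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="', ref, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', off, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', len, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * len, '"/>',
    '<binary/></binaryDataArray>')
  specs <- vapply(seq_along(spectra), function(i) {
    e <- entries[[i]]
    paste0('<spectrum id="spectrum=', i, '" index="', i - 1, '" defaultArrayLength="0">',
           '<scanList count="1"><scan>',
           '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
           coords$x[i] + 1, '"/>',
           '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
           coords$y[i] + 1, '"/>',
           '</scan></scanList><binaryDataArrayList count="2">',
           bda("mzArray", e$mz_off, e$len), bda("intensityArray", e$int_off, e$len),
           '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup></referenceableParamGroupList>',
    '<run id="run0"><spectrumList count="', length(spectra), '">',
    paste(specs, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path, sep = "")
  path
}

# small interleaved 3-class dataset with two discriminant directions
toy_classes <- function(n_per = 10, p = 6, sep = 4, seed = 1) {
  with_seed_test(seed, {
    X <- matrix(rnorm(3 * n_per * p), 3 * n_per, p)
    g <- rep(1:3, each = n_per)
    X[, 1] <- X[, 1] + sep * (g == 1)
    X[, 2] <- X[, 2] + sep * (g == 2)
    Y <- matrix(0, 3 * n_per, 3)
    Y[cbind(seq_along(g), g)] <- 1
    # interleave classes so venetian-blind folds keep all classes
    ord <- order(rep(seq_len(n_per), 3), g)
    list(X = X[ord, ], Y = Y[ord, ])
  })
}
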