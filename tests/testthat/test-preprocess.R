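test_that("reflectance correction follows (L - B)/(W - B)", {
  mk <- function(v) hsi_cube(array(v, c(2, 2, 2)))
  L <- mk(150); B <- mk(50); W <- mk(250)
  expect_equal(as.vector(black_white_correct(L, B, W)$data), rep(0.5, 8))
  expect_equal(as.vector(black_white_correct(B, B, W)$data), rep(0, 8))
  expect_equal(as.vector(black_white_correct(W, B, W)$data), rep(1, 8))
  # affine invariance under a common positive gain
  g <- 3.7
  expect_equal(black_white_correct(mk(150 * g), mk(50 * g), mk(250 * g))$data,
               black_white_correct(L, B, W)$data)
  # vanishing dynamic range guarded
  expect_warning(z <- black_white_correct(L, B, B), "vanishing")
  expect_true(all(z$data == 0))
  expect_error(black_white_correct(L, B, hsi_cube(array(1, c(2, 2, 3)))),
               "shape")
})

test_that("cropping uses half-open 0-based ranges and tracks labels", {
  cube <- tiny_cube(10, 8, 4)
  lab <- label_map(matrix(rep(1:2, 40), 10, 8))
  full <- crop_cube(cube, NULL, c(0, 10), c(0, 8))
  expect_identical(full$data, cube$data)
  res <- crop_cube(cube, lab, c(2, 7), c(1, 5))
  expect_equal(dim(res$cube$data), c(5, 4, 4))
  expect_equal(dim(res$labels$labels), c(5, 4))
  expect_identical(res$cube$data[1, 1, ], cube$data[3, 2, ])
  expect_identical(res$labels$labels[1, 1], lab$labels[3, 2])
  # the published crop arithmetic: [0, 971) x [0, 841) from 1800 x 1538
  expect_equal(971 - 0, length(0:970))
  sub <- crop_cube(tiny_cube(18, 15, 3), NULL, c(0, 9), c(0, 8))
  expect_equal(dim(sub$data), c(9, 8, 3))
  expect_error(crop_cube(cube, NULL, c(5, 5), c(0, 8)), "row range")
  expect_error(crop_cube(cube, NULL, c(0, 11), c(0, 8)), "row range")
  expect_error(crop_cube(cube, NULL, c(0, 10), c(6, 2)), "col range")
})

test_that("band discrimination scores the worst-separated class pair", {
  # two constant-spectrum classes: every band separates them by 0.6
  arr <- array(0.2, c(4, 4, 3))
  arr[3:4, , ] <- 0.8
  lab <- label_map(matrix(c(1, 1, 2, 2), 4, 4))
  bd <- band_discrimination(hsi_cube(arr), lab)
  expect_equal(bd$scores, rep(0.6, 3))
  expect_equal(bd$best_band, 1L)
  # make the classes identical in band 2 only
  arr[3:4, , 2] <- 0.2
  bd2 <- band_discrimination(hsi_cube(arr), lab)
  expect_equal(bd2$scores[2], 0)
  expect_equal(bd2$best_band, 1L)
  expect_error(band_discrimination(hsi_cube(arr),
                                   label_map(matrix(1L, 4, 4))),
               "two labeled classes")
})

test_that("band discrimination matches an exhaustive pair scan on a 9-class scene", {
  sc <- simulate_scene(scene_spec(rows = 24, cols = 24, bands = 12,
                                  blob_size_range = c(3, 6), seed = 9))
  refl <- black_white_correct(sc$raw, sc$dark, sc$white)
  bd <- band_discrimination(refl, sc$truth)
  # brute force over all bands x class pairs
  lab <- as.vector(sc$truth$labels)
  X <- matrix(refl$data, 24 * 24, 12)
  cls <- sort(unique(lab))
  brute <- sapply(seq_len(12), function(b) {
    mins <- Inf
    for (a in seq_along(cls)) for (z in seq_along(cls)) if (a < z) {
      d <- abs(mean(X[lab == cls[a], b]) - mean(X[lab == cls[z], b]))
      mins <- min(mins, d)
    }
    mins
  })
  expect_equal(bd$scores, brute, tolerance = 1e-12)
  expect_equal(bd$best_band, which.max(brute))
})

test_that("standardization yields per-band mean 0 and population sd 1", {
  cube <- hsi_cube(array(c(1, 2, 3, 10, 20, 30), c(3, 1, 2)))
  st <- standardize_cube(cube)
  v <- sqrt(2 / 3)
  expect_equal(as.vector(st$cube$data[, 1, 1]), c(-1, 0, 1) / v,
               tolerance = 1e-12)
  big <- tiny_cube(8, 7, 5, seed = 3)
  st2 <- standardize_cube(big)
  M <- matrix(st2$cube$data, 56, 5)
  expect_true(all(abs(colMeans(M)) < 1e-6))
  expect_true(all(abs(sqrt(colMeans(M^2)) - 1) < 1e-6))
  # idempotence
  st3 <- standardize_cube(st2$cube)
  expect_equal(st3$cube$data, st2$cube$data, tolerance = 1e-6)
  # constant band maps to zero with a warning
  cb <- big
  cb$data[, , 2] <- 4.2
  expect_warning(st4 <- standardize_cube(cb), "constant band")
  expect_true(all(st4$cube$data[, , 2] == 0))
})

test_that("MSC exactly inverts noiseless affine spectral distortions", {
  ref <- seq(0.2, 0.9, length.out = 10)
  n_px <- 12
  set.seed(4)
  m_true <- runif(n_px, 0.5, 2)
  b_true <- runif(n_px, -0.5, 0.5)
  X <- outer(m_true, ref) + b_true
  cube <- hsi_cube(array(X, c(3, 4, 10)))
  res <- msc(cube, reference = ref)
  expect_equal(res$model$slope, m_true, tolerance = 1e-12)
  expect_equal(res$model$intercept, b_true, tolerance = 1e-12)
  corrected <- matrix(res$cube$data, n_px, 10)
  for (i in seq_len(n_px))
    expect_equal(corrected[i, ], ref, tolerance = 1e-10,
                 ignore_attr = TRUE)
  # input equal to its own reference is unchanged (m = 1, b = 0)
  same <- hsi_cube(array(rep(ref, each = 4), c(2, 2, 10)))
  res2 <- msc(same)
  expect_equal(res2$model$slope, rep(1, 4), tolerance = 1e-12)
  expect_equal(res2$model$intercept, rep(0, 4), tolerance = 1e-12)
  expect_equal(res2$cube$data, same$data, tolerance = 1e-12)
  expect_error(msc(cube, reference = ref[1:5]), "length")
})

test_that("MSC shrinks across-pixel variance on scatter-distorted spectra", {
  sc <- simulate_scene(scene_spec(rows = 16, cols = 16, bands = 16,
                                  n_classes = 2, blob_count = 0,
                                  noise_sd = 0.002, seed = 6))
  refl <- black_white_correct(sc$raw, sc$dark, sc$white)
  res <- msc(refl)
  before <- apply(matrix(refl$data, 256, 16), 2, var)
  after <- apply(matrix(res$cube$data, 256, 16), 2, var)
  expect_true(all(after < before))
})

test_that("PCA eigenstructure matches an independent SVD oracle", {
  cube <- tiny_cube(50, 50, 20, seed = 8)
  model <- pca_fit(cube, threshold = 1)
  X <- matrix(cube$data, 2500, 20)
  Xc <- scale(X, scale = FALSE)
  sv <- La.svd(Xc)
  lambda_oracle <- sv$d^2 / 2500
  expect_equal(model$eigenvalues, lambda_oracle, tolerance = 1e-8)
  # orthonormal loadings, descending eigenvalues
  W <- model$component_matrix
  expect_equal(crossprod(W), diag(ncol(W)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  # cumulative-variance rule against an exhaustive scan of p
  for (b in c(0.5, 0.9, 0.97, 0.999)) {
    p_rule <- pca_fit(cube, threshold = b)$retained
    ratio <- cumsum(lambda_oracle) / sum(lambda_oracle)
    p_scan <- min(which(ratio >= b))
    expect_equal(p_rule, p_scan)
  }
})

test_that("PCA handles rank-1 data, fixed p, and reconstruction error", {
  # all pixels on a line through band space -> one component suffices
  set.seed(2)
  t <- runif(30)
  dirv <- c(1, -2, 0.5, 3)
  X <- outer(t, dirv) + rep(c(0.1, 0.2, 0.3, 0.4), each = 30)
  cube <- hsi_cube(array(X, c(5, 6, 4)))
  m1 <- pca_fit(cube, threshold = 0.999)
  expect_equal(m1$retained, 1L)
  expect_true(all(m1$eigenvalues[-1] < 1e-12))
  red <- pca_apply(cube, m1)
  expect_equal(dim(red$data)[3], 1L)
  # lossless reconstruction at p = 1 for rank-1 data
  S <- matrix(red$data, 30, 1)
  recon <- S %*% t(m1$component_matrix) +
    rep(m1$center, each = 30)
  expect_equal(recon, X, tolerance = 1e-9, ignore_attr = TRUE)
  # two orthogonal axes with variances 9 and 1: b = 0.9 keeps one
  set.seed(3)
  Z <- cbind(rnorm(4000, sd = 3), rnorm(4000, sd = 1))
  czz <- hsi_cube(array(Z, c(80, 50, 2)))
  mz <- pca_fit(czz, threshold = 0.9)
  frac1 <- mz$eigenvalues[1] / sum(mz$eigenvalues)
  expect_equal(mz$retained, if (frac1 >= 0.9) 1L else 2L)
  # p = n is lossless; reconstruction SSE tracks the discarded eigenvalues
  cube2 <- tiny_cube(10, 10, 6, seed = 12)
  mfull <- pca_fit(cube2, n_comp = 6)
  sc <- pca_apply(cube2, mfull)
  X2 <- matrix(cube2$data, 100, 6)
  rec <- matrix(sc$data, 100, 6) %*% t(mfull$component_matrix) +
    rep(mfull$center, each = 100)
  expect_equal(rec, X2, tolerance = 1e-9, ignore_attr = TRUE)
  m3 <- pca_fit(cube2, n_comp = 3)
  s3 <- pca_apply(cube2, m3)
  rec3 <- matrix(s3$data, 100, 3) %*% t(m3$component_matrix) +
    rep(m3$center, each = 100)
  sse <- sum((rec3 - X2)^2)
  expect_equal(sse, 100 * sum(m3$eigenvalues[4:6]), tolerance = 1e-8)
  expect_error(pca_fit(cube2, n_comp = 7), "1..bands")
  expect_error(pca_fit(cube2), "exactly one")
  expect_error(pca_apply(tiny_cube(4, 4, 5), m3), "band count")
})

test_that("absorbance is -log10(I/I0)", {
  I0 <- c(2, 4, 8)
  cube <- hsi_cube(array(rep(I0, each = 4), c(2, 2, 3)))
  expect_equal(as.vector(absorbance(cube, I0)$data), rep(0, 12))
  cube10 <- hsi_cube(array(rep(I0 / 10, each = 4), c(2, 2, 3)))
  expect_equal(as.vector(absorbance(cube10, I0)$data), rep(1, 12))
  cubex <- hsi_cube(array(rep(I0 * 10, each = 4), c(2, 2, 3)))
  expect_equal(as.vector(absorbance(cubex, I0)$data), rep(-1, 12))
  neg <- hsi_cube(array(c(-1, rep(1, 11)), c(2, 2, 3)))
  expect_warning(absorbance(neg, I0), "clipped")
})

test_that("the preprocessing chain composes its stages in order", {
  sc <- simulate_scene(scene_spec(rows = 20, cols = 20, bands = 10,
                                  n_classes = 3, blob_count = 4,
                                  blob_size_range = c(3, 6), seed = 13))
  # all stages disabled: identity on the raw cube
  off <- chain_config(correct = FALSE, standardize = FALSE, msc = FALSE,
                      pca = FALSE)
  expect_identical(preprocess_chain(sc$raw, config = off)$cube$data,
                   sc$raw$data)
  # full chain equals the hand-composed stages
  cfgc <- chain_config(pca_n = 4)
  res <- preprocess_chain(sc$raw, sc$dark, sc$white, cfgc,
                          labels = sc$truth)
  refl <- black_white_correct(sc$raw, sc$dark, sc$white)
  st <- standardize_cube(refl, scope = "global")
  mc <- msc(st$cube)
  pm <- pca_fit(mc$cube, n_comp = 4)
  byhand <- pca_apply(mc$cube, pm)
  expect_equal(res$cube$data, byhand$data, tolerance = 1e-10)
  expect_equal(dim(res$cube$data)[3], 4L)
  # fitted models reused on a second cube reproduce the same transform
  res2 <- preprocess_chain(sc$raw, sc$dark, sc$white, cfgc,
                           models = res$models)
  expect_equal(res2$cube$data, res$cube$data, tolerance = 1e-10)
})

test_that("a noise-free scene becomes linearly separable after the chain", {
  spec <- scene_spec(rows = 24, cols = 24, bands = 16, n_classes = 4,
                     blob_count = 8, blob_size_range = c(4, 7),
                     scatter_mult_sd = 0, scatter_add_sd = 0, noise_sd = 0,
                     seed = 21)
  sc <- simulate_scene(spec)
  res <- preprocess_chain(sc$raw, sc$dark, sc$white,
                          chain_config(msc = FALSE, pca_n = 3),
                          labels = sc$truth)
  X <- matrix(res$cube$data, 24 * 24, 3)
  lab <- as.vector(res$labels$labels)
  mus <- rowsum(X, lab) / as.vector(table(lab))
  spread <- max(sapply(sort(unique(lab)), function(c)
    mean(sqrt(rowSums((X[lab == c, , drop = FALSE] -
                         rep(mus[as.character(c), ],
                             each = sum(lab == c)))^2)))))
  dmin <- min(dist(mus))
  expect_gt(dmin, spread)
})

test_that("a 328-band cube reduces to the 16-band working depth", {
  set.seed(30)
  cube <- hsi_cube(array(rnorm(8 * 8 * 328), c(8, 8, 328)))
  res <- preprocess_chain(cube, config = chain_config(correct = FALSE,
                                                      msc = TRUE,
                                                      pca_n = 16))
  expect_equal(dim(res$cube$data), c(8, 8, 16))
})
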