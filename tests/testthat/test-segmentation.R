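test_that("rank-1 cubes put essentially all variance on PC1", {
  set.seed(10)
  s <- runif(6)
  coef <- matrix(runif(64, 0.2, 1), 8, 8)
  arr <- array(as.vector(outer(as.vector(coef), s)), c(8, 8, 6))
  cube <- hyper_cube(arr, seq(470, 720, length.out = 6), "raw_dn")
  p <- pca_spectral(cube, k = 3)
  expect_gt(p$explained_variance[1] / sum(p$explained_variance), 1 - 1e-9)
})

test_that("PCA scores match the brute-force covariance eigensolver", {
  set.seed(11)
  cube <- toy_cube(8, 8, 5, seed = 11)
  p <- pca_spectral(cube, k = 5)
  # oracle: eigendecomposition of the band covariance of centered data
  x <- matrix(cube$data, 64, 5)
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  oracle <- xc %*% ev$vectors
  for (k in 1:5) {
    # sign is arbitrary per component; compare up to sign
    err <- min(max(abs(p$scores[, , k] - matrix(oracle[, k], 8, 8))),
               max(abs(p$scores[, , k] + matrix(oracle[, k], 8, 8))))
    expect_lt(err, 1e-8)
  }
  expect_equal(p$explained_variance, ev$values[1:5], tolerance = 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
})

test_that("PC1 separates two spectrally distinct regions almost perfectly", {
  s1 <- seq(0.8, 0.6, length.out = 6)   # background
  s2 <- seq(0.3, 0.5, length.out = 6)   # inner region
  cube <- two_region_cube(24, 24, s1, s2)
  truth <- matrix(FALSE, 24, 24); truth[8:15, 8:15] <- TRUE
  p <- pca_spectral(cube, k = 3)
  sc <- abs(p$scores[, , 1] - median(p$scores[, , 1]))
  expect_gt(roc_auc(as.vector(sc), as.vector(truth)), 0.99)
})

test_that("pca_spectral guards degenerate inputs", {
  expect_error(pca_spectral(hyper_cube(array(1, c(2, 2, 2)), 1:2)))
  cube <- toy_cube(2, 2, 5)
  cube$valid <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_error(pca_spectral(cube, k = 3))
})

test_that("normalize_pc maps linearly onto [0, 1] and flags constants", {
  n <- normalize_pc(matrix(c(0, 5, 10, 5), 2, 2))
  expect_equal(as.vector(n$image), c(0, 0.5, 1, 0.5))
  expect_false(n$degenerate)
  con <- normalize_pc(matrix(3, 2, 2))
  expect_true(con$degenerate)
  expect_equal(as.vector(con$image), rep(0, 4))
  # idempotent on an already-normalized image
  m <- matrix(c(0, 0.25, 1, 0.5), 2, 2)
  expect_equal(normalize_pc(m)$image, m)
})

test_that("difference image follows PC2n - PC1n with the stated range", {
  a <- normalize_pc(matrix(runif(16), 4))
  expect_equal(difference_image(a, a), matrix(0, 4, 4))
  one <- normalize_pc(matrix(c(0, 1, rep(0.5, 14)), 4))
  zero <- normalize_pc(matrix(c(1, 0, rep(0.5, 14)), 4))
  d <- difference_image(normalize_pc(matrix(0, 4, 4) + c(1, 0)),
                        normalize_pc(matrix(0, 4, 4) + c(0, 1)))
  expect_true(all(d >= -1 & d <= 1))
  b <- normalize_pc(matrix(runif(9), 3))
  expect_error(difference_image(a, b), class = "hsinuc_dimension_error")
})

test_that("orientation fixes signs so nuclei are minority-positive", {
  sp <- scene_spec(shape = c(96L, 96L), n_nuclei = 6L, seed = 31L,
                   n_distractors = 0L, blur_fraction = 0)
  sc <- generate_scene(sp)
  cube <- calibrate_transmittance(sc$raw, reference_pair(sc$white, sc$dark))
  p0 <- pca_spectral(cube, k = 3)
  base <- orient_components(p0)
  dif <- difference_image(normalize_pc(base$scores[, , 1]),
                          normalize_pc(base$scores[, , 2]))
  f <- mean(dif > 0)
  expect_lte(f, 0.5)
  expect_gt(f, 0)
  # nucleus pixels are the positive ones
  expect_gt(mean(dif[sc$truth$mask]), 0)
  # flipping any input sign leaves the oriented output identical
  for (flip in list(1L, 2L, c(1L, 2L))) {
    pf <- p0
    for (k in flip) {
      pf$scores[, , k] <- -pf$scores[, , k]
      pf$rotation[, k] <- -pf$rotation[, k]
    }
    ori <- orient_components(pf)
    expect_equal(ori$scores[, , 1:2], base$scores[, , 1:2])
  }
})

test_that("all-background scenes flag orientation degeneracy", {
  sp <- scene_spec(shape = c(64L, 64L), n_nuclei = 0L, seed = 32L,
                   n_distractors = 0L, background_fraction = 1)
  sc <- generate_scene(sp)
  cube <- calibrate_transmittance(sc$raw, reference_pair(sc$white, sc$dark))
  m <- segment_nuclei(cube)
  expect_equal(nrow(m$centroids), 0L)
})

test_that("mask_nuclei applies the strict threshold and area filter", {
  diff <- matrix(-0.5, 40, 40)
  diff[disc_mask(40, 40, cbind(10, 10), 2)] <- 0.5    # area ~13
  diff[disc_mask(40, 40, cbind(28, 28), 7)] <- 0.5    # area ~150
  m <- mask_nuclei(diff, threshold = 0, min_area = 50)
  expect_equal(nrow(m$centroids), 1L)
  expect_equal(round(m$centroids$row), 28)
  empty <- mask_nuclei(matrix(-1, 10, 10))
  expect_equal(nrow(empty$centroids), 0L)
  expect_false(any(empty$binary))
})

test_that("labeling is 8-connective and centroids land within 2 px", {
  centers <- rbind(c(12, 12), c(12, 36), c(36, 12), c(36, 36),
                   c(24, 24))
  diff <- matrix(-1, 48, 48)
  diff[disc_mask(48, 48, centers, rep(4, 5))] <- 1
  m <- mask_nuclei(diff, min_area = 20)
  expect_equal(nrow(m$centroids), 5L)
  match <- match_centroids(tibble::tibble(row = centers[, 1],
                                          col = centers[, 2]),
                           m$centroids, radius = 2)
  expect_equal(match$recall, 1)
  # diagonal-touching pixels form one component under 8-connectivity
  z <- matrix(-1, 6, 6); z[2, 2] <- 1; z[3, 3] <- 1; z[4, 4] <- 1
  m8 <- mask_nuclei(z, min_area = 1)
  expect_equal(max(m8$labels), 1L)
})

test_that("watershed splits touching discs but leaves singletons alone", {
  # two overlapping discs, centers 1.2 radii apart
  r <- 9
  diff <- matrix(-1, 60, 60)
  diff[disc_mask(60, 60, rbind(c(30, 24), c(30, 24 + 1.2 * r)), c(r, r))] <- 1
  m <- mask_nuclei(diff, min_area = 30)
  expect_equal(nrow(m$centroids), 1L)       # merged before splitting
  split <- split_touching(m, diff)
  expect_equal(nrow(split$centroids), 2L)
  # isolated disc stays one label
  solo <- mask_nuclei(local({
    d <- matrix(-1, 40, 40); d[disc_mask(40, 40, cbind(20, 20), 8)] <- 1; d
  }), min_area = 30)
  expect_equal(nrow(split_touching(solo)$centroids), 1L)
  # three-lobed blob from three seeds
  tri <- matrix(-1, 70, 70)
  tri[disc_mask(70, 70, rbind(c(25, 25), c(25, 45), c(43, 35)),
                c(9, 9, 9))] <- 1
  mt <- split_touching(mask_nuclei(tri, min_area = 30))
  expect_equal(nrow(mt$centroids), 3L)
})

test_that("extract_patches enforces window fit, margin rule and odd size", {
  sp <- scene_spec(shape = c(120L, 120L), n_nuclei = 5L, seed = 33L,
                   n_distractors = 0L, blur_fraction = 0, margin_px = 30)
  sc <- generate_scene(sp)
  cube <- sc$transmittance
  rgb <- synthesize_rgb(cube)
  mask <- structure(list(binary = sc$truth$mask, labels = sc$truth$labels,
                         centroids = sc$truth$nuclei[, c("label", "row",
                                                         "col", "area")],
                         min_area = 0), class = "nuclei_mask")
  recs <- extract_patches(cube, rgb, mask, size = 41L, label = "normal",
                          patient_id = "P1", image_id = "I1")
  expect_gt(nrow(recs), 0)
  expect_equal(dim(recs$hsi_patch[[1]]), c(41L, 41L, 87L))
  expect_equal(dim(recs$rgb_patch[[1]]), c(41L, 41L, 3L))
  # window boundary arithmetic: centroid at (50, 50) with size 101 in a
  # large frame covers rows/cols 0..100 (1-based 1..101)
  big <- hyper_cube(array(0.5, c(200, 200, 3)),
                    seq(500, 600, length.out = 3), "transmittance")
  mk <- structure(list(binary = matrix(TRUE, 200, 200),
                       labels = matrix(1L, 200, 200),
                       centroids = tibble::tibble(label = 1L, row = 51,
                                                  col = 51, area = 10),
                       min_area = 0), class = "nuclei_mask")
  r1 <- extract_patches(big, NULL, mk, size = 101L)
  expect_equal(nrow(r1), 1L)
  # centroid 10 px from the edge is dropped
  mk$centroids <- tibble::tibble(label = 1L, row = 10, col = 100, area = 10)
  expect_equal(nrow(extract_patches(big, NULL, mk, size = 101L)), 0L)
  # margin-overlapping windows are dropped
  margin <- matrix(FALSE, 120, 120); margin[1:60, ] <- TRUE
  recs_m <- extract_patches(cube, list(image = rgb, margin = margin),
                            mask, size = 41L)
  expect_true(all(recs_m$row > 60 + 20 - 1))
  expect_error(extract_patches(cube, rgb, mask, size = 40L),
               class = "hsinuc_config_error")
})

test_that("lymphocyte-scale distractors never reach the mask", {
  sp <- scene_spec(shape = c(160L, 160L), n_nuclei = 8L, seed = 34L,
                   n_distractors = 10L, blur_fraction = 0)
  sc <- generate_scene(sp)
  cube <- calibrate_transmittance(sc$raw, reference_pair(sc$white, sc$dark))
  m <- segment_nuclei(cube)
  expect_true(all(m$centroids$area >= 200))
  match <- match_centroids(sc$truth$nuclei, m$centroids, radius = 5)
  expect_equal(match$precision, 1)
})
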