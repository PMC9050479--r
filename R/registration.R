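#' Affine transform between camera frames
#'
#' A 2x3 matrix mapping moving-image coordinates into fixed-image
#' coordinates, in `(x = col, y = row)` order with 0-based pixel centers:
#' `c(xf, yf) = M[, 1:2] %*% c(xm, ym) + M[, 3]`. Storage indexing in this
#' package is 1-based `(row, col)`; the conversion is handled internally
#' by [apply_affine()].
#'
#' @param matrix numeric 2x3 matrix; the 2x2 linear block must be
#'   invertible.
#' @param meta optional named list (estimation provenance).
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, meta = list()) {
  matrix <- base::matrix(as.numeric(matrix), 2, 3)
  if (abs(det(matrix[, 1:2])) < 1e-12)
    abort("linear block of affine transform is singular")
  structure(list(matrix = matrix, meta = meta), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> (x=col, y=row, 0-based)\n")
  print(round(x$matrix, 6))
  if (!is.null(x$meta$inlier_ratio))
    cat(sprintf("  inliers: %.0f%% of %d matches\n",
                100 * x$meta$inlier_ratio, x$meta$n_matches))
  invisible(x)
}

#' Apply an affine transform to 0-based (x, y) points
#' @param t an [affine_transform()].
#' @param xy n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
affine_points <- function(t, xy) {
  xy <- base::matrix(xy, ncol = 2)
  sweep(xy %*% t(t$matrix[, 1:2]), 2, t$matrix[, 3], `+`)
}

#' Invert an affine transform
#' @param t an [affine_transform()].
#' @return the inverse [affine_transform()].
#' @export
affine_invert <- function(t) {
  A <- t$matrix[, 1:2]
  Ai <- solve(A)
  affine_transform(cbind(Ai, -Ai %*% t$matrix[, 3]))
}

#' Save / load an affine transform as JSON
#' @param t an [affine_transform()].
#' @param path JSON file path.
#' @return `path` (save) or an [affine_transform()] (load).
#' @export
save_affine <- function(t, path) {
  jsonlite::write_json(
    list(matrix = t$matrix,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         meta = t$meta[setdiff(names(t$meta), "matches")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_affine
#' @export
load_affine <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(j$matrix, meta = as.list(j$meta))
}

#' Convert an image to grayscale
#'
#' RGB arrays are reduced with luminance weights 0.299/0.587/0.114;
#' hyperspectral cubes are averaged over bands. Output is clipped to
#' `[0, 1]` (8-bit RGB inputs are scaled by 1/255 first).
#'
#' @param image RGB array `[rows, cols, 3]`, 2-D matrix, or [hyper_cube()].
#' @return numeric matrix in `[0, 1]`.
#' @export
to_grayscale <- function(image) {
  if (inherits(image, "hyper_cube")) {
    g <- rowMeans(image$data, dims = 2)
  } else if (is.matrix(image)) {
    g <- image
  } else if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] == 3L) {
      g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    } else g <- rowMeans(image, dims = 2)
  } else abort("unsupported image type", class = "hsinuc_dimension_error")
  if (length(g) == 0) abort("empty image", class = "hsinuc_dimension_error")
  if (!is.matrix(g)) g <- matrix(g, dim(image)[1], dim(image)[2])
  if (max(g, na.rm = TRUE) > 1.5) g <- g / 255
  pmin(pmax(g, 0), 1)
}

# ---- Harris corners ----------------------------------------------------

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  outer(k, k) / sum(k)^2
}

conv2 <- function(im, k) {
  # zero-padded 'same' convolution via EBImage (FFT-based)
  EBImage::filter2(im, k, boundary = 0)
}

harris_corners <- function(gray, n_max = 400, sigma = 1.5, min_dist = 5) {
  sob <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- conv2(gray, sob)
  gy <- conv2(gray, t(sob))
  g <- gaussian_kernel(sigma)
  sxx <- conv2(gx * gx, g); syy <- conv2(gy * gy, g); sxy <- conv2(gx * gy, g)
  R <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  h <- nrow(R); w <- ncol(R)
  # non-max suppression over a (2r+1)^2 neighborhood by shifting
  r <- 2L
  is_max <- matrix(TRUE, h, w)
  for (dc in -r:r) for (dr in -r:r) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, h, w)
    rs <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 - dc):min(w, w - dc)
    shifted[rs, cs] <- R[rs + dr, cs + dc]
    is_max <- is_max & (R >= shifted)
  }
  b <- r + 6L  # stay clear of the border for descriptors
  is_max[c(seq_len(b), h - seq_len(b) + 1L), ] <- FALSE
  is_max[, c(seq_len(b), w - seq_len(b) + 1L)] <- FALSE
  thr <- 0.005 * max(R)
  cand <- which(is_max & R > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(cbind(row = numeric(0), col = numeric(0)))
  ord <- order(R[cand], decreasing = TRUE)
  cand <- cand[head(ord, n_max), , drop = FALSE]
  # sub-pixel refinement: quadratic fit of the response surface
  refine <- function(rc) {
    i <- rc[1]; j <- rc[2]
    dx <- (R[i, j + 1] - R[i, j - 1]) / 2
    dy <- (R[i + 1, j] - R[i - 1, j]) / 2
    dxx <- R[i, j + 1] - 2 * R[i, j] + R[i, j - 1]
    dyy <- R[i + 1, j] - 2 * R[i, j] + R[i - 1, j]
    dxy <- (R[i + 1, j + 1] - R[i + 1, j - 1] -
            R[i - 1, j + 1] + R[i - 1, j - 1]) / 4
    H <- matrix(c(dxx, dxy, dxy, dyy), 2, 2)
    off <- tryCatch(-solve(H, c(dx, dy)), error = function(e) c(0, 0))
    off[!is.finite(off)] <- 0
    off <- pmax(pmin(off, 0.5), -0.5)
    c(i + off[2], j + off[1])
  }
  out <- t(apply(cand, 1, refine))
  colnames(out) <- c("row", "col")
  out
}

patch_descriptors <- function(gray, pts, half = 7L) {
  n <- nrow(pts)
  d <- matrix(0, (2 * half + 1)^2, n)
  for (i in seq_len(n)) {
    r0 <- round(pts[i, 1]); c0 <- round(pts[i, 2])
    p <- gray[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
    p <- p - mean(p)
    nrm <- sqrt(sum(p^2))
    d[, i] <- if (nrm > 0) as.vector(p) / nrm else 0
  }
  d
}

#' Estimate the affine transform between two grayscale frames
#'
#' Detects Harris corners in both images, matches them by normalized
#' cross-correlation of local patches with mutual-best and ratio checks,
#' and estimates the moving-to-fixed affine map by RANSAC (3-point
#' samples, 3 px reprojection threshold) followed by a least-squares
#' refit over the inliers. Intended for the calibration-target pair; the
#' resulting transform is then reused for all slide images of a session.
#'
#' @param fixed_gray,moving_gray grayscale matrices in `[0, 1]`.
#' @param min_features minimum usable feature count (default 50).
#' @param n_max corners retained per image.
#' @param ransac_iter RANSAC iterations.
#' @param reproj_thresh inlier reprojection threshold in px.
#' @return an [affine_transform()] with `meta$inlier_ratio` and
#'   `meta$n_matches`.
#' @export
estimate_affine <- function(fixed_gray, moving_gray, min_features = 50,
                            n_max = 400, ransac_iter = 1000,
                            reproj_thresh = 3) {
  pf <- harris_corners(fixed_gray, n_max)
  pm <- harris_corners(moving_gray, n_max)
  if (nrow(pf) < min_features || nrow(pm) < min_features)
    abort(sprintf(
      "too few features: %d in fixed, %d in moving (need %d)",
      nrow(pf), nrow(pm), min_features), class = "hsinuc_registration_error")
  df <- patch_descriptors(fixed_gray, pf)
  dm <- patch_descriptors(moving_gray, pm)
  ncc <- crossprod(dm, df)               # moving x fixed
  best_f <- apply(ncc, 1, which.max)
  best_m <- apply(ncc, 2, which.max)
  mutual <- which(best_m[best_f] == seq_len(nrow(pm)))
  score1 <- ncc[cbind(mutual, best_f[mutual])]
  keep <- mutual[score1 > 0.5]
  if (length(keep) < 3)
    abort(sprintf("too few matches: %d mutual matches from %d x %d features",
                  length(keep), nrow(pf), nrow(pm)),
          class = "hsinuc_registration_error")
  # (x, y) = (col, row), 0-based
  src <- cbind(pm[keep, "col"] - 1, pm[keep, "row"] - 1)
  dst <- cbind(pf[best_f[keep], "col"] - 1, pf[best_f[keep], "row"] - 1)
  n <- nrow(src)
  best_inl <- integer(0)
  for (it in seq_len(ransac_iter)) {
    s <- sample.int(n, 3)
    M <- tryCatch(t(qr.solve(cbind(src[s, , drop = FALSE], 1),
                             dst[s, , drop = FALSE])),
                  error = function(e) NULL)
    if (is.null(M)) next
    pred <- sweep(src %*% t(M[, 1:2]), 2, M[, 3], `+`)
    err <- sqrt(rowSums((pred - dst)^2))
    inl <- which(err < reproj_thresh)
    if (length(inl) > length(best_inl)) best_inl <- inl
  }
  if (length(best_inl) < 3)
    abort(sprintf("RANSAC found no consensus among %d matches", n),
          class = "hsinuc_registration_error")
  # least-squares refit on inliers, then one re-selection pass
  for (pass in 1:2) {
    M <- t(qr.solve(cbind(src[best_inl, , drop = FALSE], 1),
                    dst[best_inl, , drop = FALSE]))
    pred <- sweep(src %*% t(M[, 1:2]), 2, M[, 3], `+`)
    err <- sqrt(rowSums((pred - dst)^2))
    best_inl <- which(err < reproj_thresh)
  }
  affine_transform(M, meta = list(inlier_ratio = length(best_inl) / n,
                                  n_matches = n))
}

#' Warp an RGB image into the fixed (hyperspectral) frame
#'
#' Inverse-maps every output pixel through the transform and samples the
#' moving image bilinearly. Output pixels whose preimage falls outside the
#' moving image are black and recorded in the margin mask; nuclei whose
#' patch window intersects that margin are later excluded by
#' [extract_patches()].
#'
#' @param moving_rgb array `[rows, cols, channels]` (or matrix).
#' @param t an [affine_transform()] mapping moving to fixed coordinates.
#' @param out_shape `c(rows, cols)` of the fixed frame.
#' @return list with `image` (warped array) and `margin` (logical matrix).
#' @export
apply_affine <- function(moving_rgb, t, out_shape) {
  stopifnot(inherits(t, "affine_transform"))
  if (is.matrix(moving_rgb))
    moving_rgb <- array(moving_rgb, c(dim(moving_rgb), 1L))
  d <- dim(moving_rgb)
  inv <- affine_invert(t)$matrix
  res <- cpp_warp_affine(as.numeric(moving_rgb), d[1], d[2], d[3],
                         as.numeric(t(inv))[c(1, 2, 3, 4, 5, 6)],
                         as.integer(out_shape[1]), as.integer(out_shape[2]))
  img <- res$image
  img[is.na(img)] <- 0
  list(image = img, margin = res$margin)
}
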