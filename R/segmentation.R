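#' Spectral principal component analysis of a cube
#'
#' Reshapes the cube to a pixels x bands matrix, mean-centers the bands
#' and computes principal-component score images. Components are sorted
#' by explained variance. Invalid pixels (from calibration) are excluded
#' from the decomposition and receive score 0.
#'
#' For large images the component directions are estimated on a regular
#' pixel subsample (every pixel when the image has at most `fit_max`
#' pixels, which covers any oracle-scale input exactly) and the scores
#' are then projected for every pixel.
#'
#' @param cube a [hyper_cube()] with at least 3 bands.
#' @param k number of components to retain (default 3).
#' @param fit_max maximum number of pixels used to fit the rotation
#'   (default 60000); larger images are strided.
#' @return object of class `pca_result`: list with `scores`
#'   (`[rows, cols, k]`), `explained_variance`, `rotation`, `center`.
#' @export
pca_spectral <- function(cube, k = 3L, fit_max = 60000L) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (d[3] < 3L) abort("cube must have at least 3 bands")
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  use <- if (is.null(cube$valid)) rep(TRUE, nrow(flat)) else as.vector(cube$valid)
  if (sum(use) < k)
    abort(sprintf("only %d valid pixels for %d components", sum(use), k))
  fit_idx <- which(use)
  if (length(fit_idx) > fit_max)
    fit_idx <- fit_idx[seq(1L, length(fit_idx),
                           by = ceiling(length(fit_idx) / fit_max))]
  pc <- prcomp(flat[fit_idx, , drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  scores <- matrix(0, nrow(flat), k)
  scores[use, ] <- sweep(flat[use, , drop = FALSE], 2, pc$center) %*%
    pc$rotation[, seq_len(k), drop = FALSE]
  structure(list(
    scores = array(scores, c(d[1], d[2], k)),
    explained_variance = pc$sdev[seq_len(k)]^2,
    total_variance = sum(pc$sdev^2),
    rotation = pc$rotation[, seq_len(k), drop = FALSE],
    center = pc$center,
    valid = cube$valid),
    class = "pca_result")
}

#' Min-max normalize a principal-component image
#'
#' `(pc - min) / (max - min)`, mapping the image onto `[0, 1]`. A
#' constant image maps to all zeros with `degenerate = TRUE` rather than
#' raising an error.
#'
#' @param pc 2-D numeric matrix (finite).
#' @return object of class `normalized_pc`: list with `image` and
#'   `degenerate` flag.
#' @export
normalize_pc <- function(pc) {
  if (!all(is.finite(pc))) abort("pc must be finite")
  rng <- range(pc)
  if (diff(rng) == 0)
    return(structure(list(image = pc * 0, degenerate = TRUE),
                     class = "normalized_pc"))
  structure(list(image = (pc - rng[1]) / diff(rng), degenerate = FALSE),
            class = "normalized_pc")
}

#' Fix principal-component sign ambiguity for nuclei segmentation
#'
#' PCA scores are defined only up to sign. The segmentation convention
#' wants nuclei low in PC1 and high in PC2 so the normalized difference
#' image is positive on nuclei (the minority class). All four sign
#' assignments of (PC1, PC2) are evaluated: candidates whose difference
#' image has a positive fraction in `(0, 0.5]` are kept, and among them
#' the orientation whose positive set is darkest wins — nuclei are the
#' hematoxylin-dense, least-transmitting structures, and the broadband
#' brightness deviation of each pixel is recovered from the PCA itself
#' (scores times the band sums of the rotation, a sign-invariant
#' quantity). Ties fall back to the higher mean boundary gradient on the
#' positive set. This makes the final mask invariant to any input sign
#' flip. With no positive pixels in any orientation the result is flagged
#' degenerate and left unchanged (blank scene).
#'
#' @param pca a `pca_result` with >= 2 components.
#' @param threshold difference-image threshold used downstream (default 0).
#' @param min_structure minimum fraction of total spectral variance the
#'   two leading components must carry; below it the scene is treated as
#'   blank (degenerate) rather than thresholded noise.
#' @return the `pca_result` with signs fixed and a `degenerate` flag.
#' @export
orient_components <- function(pca, threshold = 0, min_structure = 0.2) {
  stopifnot(inherits(pca, "pca_result"))
  if (dim(pca$scores)[3] < 2L) abort("need at least 2 components")
  # blank glass: the top components carry only noise-level variance and
  # the difference image is structureless; flag instead of thresholding
  if (!is.null(pca$total_variance) &&
      sum(pca$explained_variance[1:2]) / pca$total_variance <
        min_structure) {
    pca$degenerate <- TRUE
    return(pca)
  }
  p1 <- pca$scores[, , 1]; p2 <- pca$scores[, , 2]
  # broadband brightness deviation per pixel, invariant to sign flips
  # (score and rotation flip together)
  k <- dim(pca$scores)[3]
  bright <- matrix(0, nrow(p1), ncol(p1))
  for (i in seq_len(k))
    bright <- bright + pca$scores[, , i] * sum(pca$rotation[, i])
  best <- NULL
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    n1 <- normalize_pc(s1 * p1); n2 <- normalize_pc(s2 * p2)
    dif <- difference_image(n1, n2)
    pos <- dif > threshold
    f <- mean(pos)
    if (f == 0 || f > 0.5) next
    darkness <- -mean(bright[pos])
    cand <- list(s1 = s1, s2 = s2, f = f, darkness = darkness, dif = dif)
    if (is.null(best) || cand$darkness > best$darkness + 1e-12 ||
        (abs(cand$darkness - best$darkness) <= 1e-12 &&
         boundary_gradient(cand$dif, threshold) >
           boundary_gradient(best$dif, threshold))) best <- cand
  }
  if (is.null(best)) {
    pca$degenerate <- TRUE
    return(pca)
  }
  pca$scores[, , 1] <- best$s1 * p1
  pca$scores[, , 2] <- best$s2 * p2
  pca$rotation[, 1] <- best$s1 * pca$rotation[, 1]
  pca$rotation[, 2] <- best$s2 * pca$rotation[, 2]
  pca$degenerate <- FALSE
  pca
}

boundary_gradient <- function(dif, threshold) {
  pos <- dif > threshold
  if (!any(pos)) return(-Inf)
  gx <- dif[, -1] - dif[, -ncol(dif)]
  gy <- dif[-1, ] - dif[-nrow(dif), ]
  g <- matrix(0, nrow(dif), ncol(dif))
  g[, -1] <- abs(gx); g[-1, ] <- g[-1, ] + abs(gy)
  mean(g[pos])
}

#' Difference image of the two leading normalized components
#'
#' `PC2_norm - PC1_norm`; under the segmentation sign convention nucleus
#' pixels come out positive and cytoplasm negative.
#'
#' @param pc1n,pc2n `normalized_pc` objects (same shape).
#' @return numeric matrix with values in `[-1, 1]`.
#' @export
difference_image <- function(pc1n, pc2n) {
  stopifnot(inherits(pc1n, "normalized_pc"), inherits(pc2n, "normalized_pc"))
  if (!identical(dim(pc1n$image), dim(pc2n$image)))
    abort("normalized components differ in shape",
          class = "hsinuc_dimension_error")
  pc2n$image - pc1n$image
}

#' Threshold the difference image into a nuclei mask
#'
#' Binary mask is `diff > threshold` (strict); 8-connected components
#' smaller than `min_area` px (lymphocytes, debris) are removed. The
#' default `min_area` of 200 px corresponds to a disc of roughly 2.2 um
#' diameter at the instrument's 139 nm/px sampling.
#'
#' @param diff difference image.
#' @param threshold hard threshold (default 0).
#' @param min_area minimum component area in px (default 200).
#' @return object of class `nuclei_mask`: list with `binary`, `labels`,
#'   and `centroids` tibble (`label`, `row`, `col`, `area`).
#' @export
mask_nuclei <- function(diff, threshold = 0, min_area = 200) {
  if (!all(is.finite(diff))) abort("diff must be finite")
  binary <- diff > threshold
  labels <- cpp_label8(binary)
  relabel_mask(labels, min_area)
}

relabel_mask <- function(labels, min_area) {
  if (max(labels) > 0) {
    areas <- tabulate(labels)
    keep <- which(areas >= min_area)
    remap <- integer(length(areas))
    remap[keep] <- seq_along(keep)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  binary <- labels > 0
  cent <- centroid_table(labels)
  structure(list(binary = binary, labels = labels, centroids = cent,
                 min_area = min_area), class = "nuclei_mask")
}

centroid_table <- function(labels) {
  if (max(labels) == 0)
    return(tibble(label = integer(0), row = numeric(0), col = numeric(0),
                  area = integer(0)))
  idx <- which(labels > 0, arr.ind = TRUE)
  l <- labels[labels > 0]
  tibble(label = sort(unique(l))) %>%
    mutate(
      row = unname(tapply(idx[, 1], l, mean)[as.character(.data$label)]),
      col = unname(tapply(idx[, 2], l, mean)[as.character(.data$label)]),
      area = as.integer(table(l)[as.character(.data$label)]))
}

#' Split touching nuclei with a marker-controlled watershed
#'
#' Runs a watershed on the distance transform of the binary mask (seeds
#' are distance-map maxima with a 5 px minimum separation and at least
#' `tolerance` depth over their merging saddle), splitting merged blobs
#' into individual nuclei. Fragments that fall below the mask's
#' `min_area` after splitting are removed.
#'
#' @param mask a `nuclei_mask`.
#' @param diff the difference image (accepted for interface symmetry; the
#'   distance transform drives the split).
#' @param seed_sep minimum seed separation in px (default 5).
#' @param tolerance minimum seed-over-saddle depth in px (default 0.5;
#'   deep enough to ignore pixelation ripples on a single nucleus, small
#'   enough to cut overlapped pairs).
#' @return a `nuclei_mask` with updated labels and centroids.
#' @export
split_touching <- function(mask, diff = NULL, seed_sep = 5,
                           tolerance = 0.5) {
  stopifnot(inherits(mask, "nuclei_mask"))
  if (!any(mask$binary)) return(mask)
  dm <- EBImage::distmap(EBImage::Image(mask$binary * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = seed_sep)
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(mask$binary))
  relabel_mask(labels, mask$min_area)
}

#' Extract nucleus-centered patches from the cube and registered RGB
#'
#' One record per segmented nucleus whose `size` x `size` window fits
#' entirely inside the image and does not intersect the registration
#' margin (the black fill of the warped RGB frame); nuclei failing either
#' rule are dropped, as their RGB patch would be incomplete.
#'
#' @param cube transmittance [hyper_cube()].
#' @param rgb list with `image` (`[rows, cols, 3]`) and optional `margin`
#'   logical matrix, as returned by [apply_affine()]; or a bare array.
#' @param mask a `nuclei_mask` in the same frame.
#' @param size odd patch edge in px (default 101).
#' @param label class label for all records (`"cancerous"`, `"normal"`,
#'   `"unknown"`).
#' @param patient_id,image_id provenance identifiers.
#' @return tibble with one row per retained nucleus: `nucleus_id`,
#'   `patient_id`, `image_id`, `label`, `row`, `col`, `area`, and
#'   list-columns `hsi_patch` (`size x size x bands`), `rgb_patch`,
#'   `mask_patch`.
#' @export
extract_patches <- function(cube, rgb, mask, size = 101L,
                            label = "unknown", patient_id = NA_character_,
                            image_id = NA_character_) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "nuclei_mask"))
  size <- as.integer(size)
  if (size %% 2L == 0L)
    abort("patch size must be odd", class = "hsinuc_config_error")
  if (is.list(rgb)) { margin <- rgb$margin; rgb_img <- rgb$image }
  else { margin <- NULL; rgb_img <- rgb }
  d <- dim(cube$data)
  if (!is.null(rgb_img) && !identical(dim(rgb_img)[1:2], d[1:2]))
    abort("cube and RGB image differ in spatial shape",
          class = "hsinuc_dimension_error")
  half <- (size - 1L) %/% 2L
  cent <- mask$centroids
  recs <- purrr::pmap(cent, function(label, row, col, area) {
    lab_id <- label
    r0 <- round(row) - half; r1 <- round(row) + half
    c0 <- round(col) - half; c1 <- round(col) + half
    if (r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2]) return(NULL)
    if (!is.null(margin) && any(margin[r0:r1, c0:c1])) return(NULL)
    list(label_id = lab_id, row = row, col = col, area = area,
         hsi = cube$data[r0:r1, c0:c1, , drop = FALSE],
         rgb = if (!is.null(rgb_img)) rgb_img[r0:r1, c0:c1, , drop = FALSE],
         msk = mask$labels[r0:r1, c0:c1] == lab_id)
  })
  recs <- purrr::compact(recs)
  if (!length(recs))
    return(tibble(nucleus_id = character(0), patient_id = character(0),
                  image_id = character(0), label = character(0),
                  row = numeric(0), col = numeric(0), area = integer(0),
                  hsi_patch = list(), rgb_patch = list(), mask_patch = list()))
  tibble(
    nucleus_id = sprintf("%s_%s_n%03d", patient_id, image_id,
                         vapply(recs, function(r) r$label_id, 1)),
    patient_id = patient_id, image_id = image_id, label = label,
    row = vapply(recs, function(r) r$row, 1),
    col = vapply(recs, function(r) r$col, 1),
    area = vapply(recs, function(r) as.integer(r$area), 1L),
    hsi_patch = purrr::map(recs, "hsi"),
    rgb_patch = purrr::map(recs, "rgb"),
    mask_patch = purrr::map(recs, "msk"))
}

#' Full PCA-based segmentation of a transmittance cube
#'
#' Convenience wrapper: spectral PCA, sign orientation, normalized
#' difference image, hard threshold with small-object removal, and
#' watershed splitting of touching nuclei.
#'
#' @inheritParams pca_spectral
#' @inheritParams mask_nuclei
#' @param split split touching nuclei by watershed (default TRUE).
#' @return a `nuclei_mask`; the difference image is attached as
#'   `attr(, "diff")`.
#' @export
segment_nuclei <- function(cube, threshold = 0, min_area = 200,
                           split = TRUE) {
  pca <- orient_components(pca_spectral(cube, k = 3L), threshold)
  if (isTRUE(pca$degenerate)) {
    empty <- relabel_mask(matrix(0L, dim(cube$data)[1], dim(cube$data)[2]),
                          min_area)
    attr(empty, "diff") <- matrix(0, dim(cube$data)[1], dim(cube$data)[2])
    return(empty)
  }
  dif <- difference_image(normalize_pc(pca$scores[, , 1]),
                          normalize_pc(pca$scores[, , 2]))
  m <- mask_nuclei(dif, threshold, min_area)
  if (split) m <- split_touching(m, dif)
  attr(m, "diff") <- dif
  m
}
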