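# deterministic fixture builders shared across test files

toy_cube <- function(h = 4, w = 4, b = 3, seed = 1, units = "raw_dn",
                     wavelengths = seq(500, 600, length.out = b)) {
  set.seed(seed)
  hyper_cube(array(runif(h * w * b, 10, 100), c(h, w, b)),
             wavelengths, units)
}

# references with constant white/dark levels
toy_refs <- function(h = 4, w = 4, b = 3, white = 100, dark = 10,
                     wavelengths = seq(500, 600, length.out = b)) {
  reference_pair(
    hyper_cube(array(white, c(h, w, b)), wavelengths, "raw_dn"),
    hyper_cube(array(dark, c(h, w, b)), wavelengths, "raw_dn"))
}

# two-region cube: rectangle of spectrum s2 on background s1 (+ noise)
two_region_cube <- function(h = 24, w = 24, s1, s2, noise = 0.005,
                            seed = 1) {
  set.seed(seed)
  b <- length(s1)
  arr <- array(rep(s1, each = h * w), c(h, w, b))
  rs <- 8:15; cs <- 8:15
  for (k in seq_len(b)) arr[rs, cs, k] <- s2[k]
  arr <- arr + array(rnorm(h * w * b, sd = noise), c(h, w, b))
  hyper_cube(pmin(pmax(arr, 0), 1.5), seq(470, 720, length.out = b),
             "transmittance")
}

# binary image with discs at given centers/radii
disc_mask <- function(h, w, centers, radii) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(centers))) {
    rr <- outer(seq_len(h) - centers[i, 1], rep(1, w))
    cc <- outer(rep(1, h), seq_len(w) - centers[i, 2])
    m <- m | (rr^2 + cc^2 <= radii[i]^2)
  }
  m
}

# centroid matching: recall/precision of detected vs true centers
match_centroids <- function(truth, detected, radius = 5) {
  if (!nrow(truth) || !nrow(detected))
    return(list(recall = as.numeric(nrow(truth) == 0),
                precision = as.numeric(nrow(detected) == 0)))
  d2 <- outer(truth$row, detected$row, "-")^2 +
    outer(truth$col, detected$col, "-")^2
  list(recall = mean(apply(d2, 1, min) <= radius^2),
       precision = mean(apply(d2, 2, min) <= radius^2))
}

# small patch-record tibble for CNN unit tests (53 px desk-scale input)
toy_patch_records <- function(n, patient_id, mu = 0.2, size = 53L,
                              channels = 3L, seed = 1) {
  set.seed(seed)
  lab <- rep(c("cancerous", "normal"), length.out = n)
  tibble::tibble(
    nucleus_id = paste0(patient_id, "_", seq_len(n)),
    patient_id = patient_id,
    image_id = paste0(patient_id, "_I1"),
    label = lab,
    hsi_patch = lapply(seq_len(n), function(i)
      array(runif(size * size * channels, 0, 0.3) +
              ifelse(lab[i] == "cancerous", mu, 0),
            c(size, size, channels))))
}
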