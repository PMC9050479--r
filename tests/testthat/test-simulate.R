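test_that("scenes are bit-reproducible from their seed", {
  sp <- scene_spec(shape = c(64L, 64L), n_nuclei = 4L, seed = 41L)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$truth$labels, b$truth$labels)
  # different seeds give different layouts
  sp2 <- scene_spec(shape = c(64L, 64L), n_nuclei = 4L, seed = 42L)
  expect_false(identical(generate_scene(sp2)$truth$labels,
                         a$truth$labels))
})

test_that("empty scenes calibrate to the flat background spectrum", {
  sp <- scene_spec(shape = c(48L, 48L), n_nuclei = 0L, n_distractors = 0L,
                   background_fraction = 1, noise_sd = 0.002, seed = 43L)
  sc <- generate_scene(sp)
  expect_false(any(sc$truth$mask))
  cube <- calibrate_transmittance(sc$raw, reference_pair(sc$white, sc$dark))
  # blank glass: transmittance ~= thickness multiplier (1) in every band
  spec <- mean_nucleus_spectrum(cube$data, matrix(TRUE, 48, 48))
  expect_true(all(abs(spec - 1) < 0.01))
})

test_that("class mean spectra cross exactly once between 640 and 650 nm", {
  # matched pair: same seed and morphology, so the scenes differ only in
  # the class tilt and the crossing is the generator systematic, not
  # finite-sample staining noise
  mk <- function(cls) {
    pset <- tibble::tibble(patient_id = "P01",
                           image_id = paste0("I_", cls), class = cls,
                           spec = list(scene_spec(
                             shape = c(128L, 128L), n_nuclei = 10L,
                             class = cls, seed = 44L, blur_fraction = 0,
                             nucleus_area_mean = 400, nucleus_area_sd = 80,
                             ecc_sdlog = 0.2, n_distractors = 0L)))
    simulate_spectrum_records(pset)
  }
  recs <- dplyr::bind_rows(mk("cancerous"), mk("normal"))
  cm <- class_mean_spectra(recs, which = "raw")
  wide <- tidyr::pivot_wider(cm, names_from = "label",
                             values_from = "mean_value")
  d <- wide$cancerous - wide$normal
  signs <- sign(d)
  crossings <- which(diff(signs) != 0)
  expect_equal(length(crossings), 1L)
  cross_wl <- wide$wavelength[crossings[1]]
  expect_gte(cross_wl, 640)
  expect_lte(wide$wavelength[crossings[1] + 1], 652)
  # cancerous transmits more below the crossover, less above
  expect_true(all(d[wide$wavelength < 630] > 0))
  expect_true(all(d[wide$wavelength > 660] < 0))
})

test_that("calibrating a generated cube recovers ground truth within noise", {
  sp <- scene_spec(shape = c(64L, 64L), n_nuclei = 5L, noise_sd = 0.01,
                   blur_fraction = 0, seed = 45L)
  sc <- generate_scene(sp)
  cube <- calibrate_transmittance(sc$raw, reference_pair(sc$white, sc$dark))
  err <- cube$data - sc$transmittance$data
  expect_lt(sd(err), 0.015)
  expect_lt(abs(mean(err)), 0.002)
})

test_that("patient sets respect the reversed count and carry effects", {
  pset <- generate_patient_set(6L, images_per_patient = 4L,
                               reversed_fraction = 1 / 6, seed = 46L,
                               shape = c(48L, 48L), n_nuclei = 3L)
  expect_equal(nrow(pset), 24L)
  expect_equal(length(unique(pset$patient_id[pset$reversed_trend])), 1L)
  # one multiplier pair per patient
  eff <- dplyr::distinct(pset[, c("patient_id", "staining_mult",
                                  "thickness_mult")])
  expect_equal(nrow(eff), 6L)
  expect_error(generate_patient_set(1L))
  expect_error(generate_patient_set(4L, reversed_fraction = 2))
})

test_that("thickness scaling darkens raw spectra but not normalized shape", {
  base <- scene_spec(shape = c(96L, 96L), n_nuclei = 6L, seed = 47L,
                     noise_sd = 0, blur_fraction = 0, n_distractors = 0L)
  thick <- base; thick$thickness_mult <- 0.5
  mk <- function(sp, id) {
    pset <- tibble::tibble(patient_id = id, image_id = id,
                           class = sp$class, spec = list(sp))
    simulate_spectrum_records(pset)
  }
  r1 <- mk(base, "A"); r2 <- mk(thick, "B")
  raw1 <- spectra_matrix(r1, "raw"); raw2 <- spectra_matrix(r2, "raw")
  expect_true(all(rowMeans(raw2) < rowMeans(raw1)))
  expect_equal(rowMeans(raw2) * 2, rowMeans(raw1), tolerance = 1e-6)
  n1 <- spectra_matrix(r1); n2 <- spectra_matrix(r2)
  expect_equal(n1, n2, tolerance = 1e-6)
})

test_that("two seeds differ in layout but agree in summary statistics", {
  areas <- function(seed) {
    sp <- scene_spec(shape = c(128L, 128L), n_nuclei = 12L, seed = seed,
                     n_distractors = 0L)
    generate_scene(sp)$truth$nuclei$area
  }
  a <- areas(48L); b <- areas(49L)
  expect_false(identical(a, b))
  expect_lt(abs(mean(a) - mean(b)), 200)
})
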