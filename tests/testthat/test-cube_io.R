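test_that("ENVI round trip is bit-exact for raw counts in all interleaves", {
  cube <- toy_cube(4, 5, 3, seed = 2)
  for (il in c("bsq", "bil", "bip")) {
    path <- file.path(withr::local_tempdir(), paste0("c_", il))
    write_envi_cube(cube, path, interleave = il)
    back <- read_envi_cube(paste0(path, ".hdr"))
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths, cube$wavelengths)
    expect_equal(back$units, "raw_dn")
  }
})

test_that("87-band header round trip keeps the default band grid", {
  set.seed(4)
  cube <- hyper_cube(array(runif(2 * 2 * 87), c(2, 2, 87)),
                     units = "transmittance")
  path <- file.path(withr::local_tempdir(), "t87")
  write_envi_cube(cube, path)
  back <- read_envi_cube(paste0(path, ".hdr"))
  expect_equal(dim(back)[3], 87L)
  expect_equal(back$wavelengths, default_wavelengths())
  expect_equal(back$units, "transmittance")  # units tag preserved
  expect_equal(back$data, cube$data, tolerance = 1e-12)
})

test_that("inconsistent or missing ENVI companions are format/io errors", {
  dir <- withr::local_tempdir()
  cube <- toy_cube(3, 3, 3)
  path <- file.path(dir, "c")
  write_envi_cube(cube, path)
  # header declaring 87 bands over a 3-plane binary
  hdr <- readLines(paste0(path, ".hdr"))
  hdr <- sub("bands = 3", "bands = 87", hdr)
  writeLines(hdr, paste0(path, ".hdr"))
  expect_error(read_envi_cube(paste0(path, ".hdr")),
               class = "hsinuc_format_error")
  # missing binary
  file.remove(path)
  writeLines(sub("bands = 87", "bands = 3", hdr), paste0(path, ".hdr"))
  expect_error(read_envi_cube(paste0(path, ".hdr")),
               class = "hsinuc_io_error")
  expect_error(read_envi_cube(file.path(dir, "absent.hdr")),
               class = "hsinuc_io_error")
})

test_that("zero-size cubes are rejected at construction or write", {
  expect_error(hyper_cube(array(0, c(0, 4, 3)), 1:3))
  cube <- toy_cube()
  cube$data <- cube$data[, , integer(0), drop = FALSE]
  expect_error(write_envi_cube(cube, tempfile()))
})

test_that("valid-pixel mask survives an ENVI round trip via sidecar", {
  cube <- toy_cube(4, 4, 3)
  cube$valid <- matrix(TRUE, 4, 4); cube$valid[2, 3] <- FALSE
  path <- file.path(withr::local_tempdir(), "m")
  write_envi_cube(cube, path)
  expect_true(file.exists(paste0(path, ".mask.json")))
  back <- read_envi_cube(paste0(path, ".hdr"))
  expect_identical(back$valid, cube$valid)
})

test_that("calibration satisfies the white/dark/midpoint identities", {
  refs <- toy_refs(4, 4, 3)
  w <- refs$white; d <- refs$dark
  mid <- hyper_cube((w$data + d$data) / 2, w$wavelengths, "raw_dn")
  expect_equal(unique(as.vector(
    calibrate_transmittance(w, refs)$data)), 1)
  expect_equal(unique(as.vector(
    calibrate_transmittance(d, refs)$data)), 0)
  expect_equal(unique(as.vector(
    calibrate_transmittance(mid, refs)$data)), 0.5)
})

test_that("calibration is invariant to affine detector rescaling", {
  raw <- toy_cube(5, 5, 4, seed = 3,
                  wavelengths = seq(470, 700, length.out = 4))
  set.seed(5)
  wl <- raw$wavelengths
  white <- hyper_cube(raw$data + array(runif(100, 5, 50), dim(raw$data)),
                      wl, "raw_dn")
  dark <- hyper_cube(raw$data * 0 + 5, wl, "raw_dn")
  t1 <- calibrate_transmittance(raw, reference_pair(white, dark))
  a <- 3.7; b <- 12
  resc <- function(cb) hyper_cube(a * cb$data + b, wl, "raw_dn")
  t2 <- calibrate_transmittance(resc(raw),
                                reference_pair(resc(white), resc(dark)))
  expect_equal(t1$data, t2$data, tolerance = 1e-12)
})

test_that("degenerate denominators are masked, not propagated", {
  refs <- toy_refs(4, 4, 3)
  refs$white$data[2, 2, 1] <- refs$dark$data[2, 2, 1]  # one bad band/pixel
  raw <- refs$white
  out <- calibrate_transmittance(raw, refs)
  expect_false(out$valid[2, 2])
  expect_equal(sum(!out$valid), 1L)
  expect_true(all(is.finite(out$data)))
  # fully degenerate references are a calibration error
  bad <- reference_pair(refs$dark, refs$dark)
  expect_error(calibrate_transmittance(raw, bad),
               class = "hsinuc_calibration_error")
})

test_that("shape mismatch between raw and references errors", {
  refs <- toy_refs(4, 4, 3)
  raw <- toy_cube(5, 4, 3)
  expect_error(calibrate_transmittance(raw, refs),
               class = "hsinuc_dimension_error")
})

test_that("transmittance clips at clip_max and a blank slide is flat 1", {
  refs <- toy_refs(3, 3, 3)
  hot <- hyper_cube(refs$white$data * 2, refs$white$wavelengths, "raw_dn")
  out <- calibrate_transmittance(hot, refs, clip_max = 1.5)
  expect_true(all(out$data <= 1.5))
  blank <- calibrate_transmittance(refs$white, refs)
  spec <- mean_nucleus_spectrum(blank$data, matrix(TRUE, 3, 3))
  expect_equal(spec, rep(1, 3))
})
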