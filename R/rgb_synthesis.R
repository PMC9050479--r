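#' Cosine-lobe channel weights for display RGB synthesis
#'
#' Builds the three channel weight vectors used to collapse a
#' transmittance cube into a display RGB image. Each channel is a raised
#' cosine lobe evaluated at the band centers, modelled on the human
#' photopic response but adapted to a camera that starts at 470 nm: the
#' red channel receives an auxiliary short-wavelength lobe (380--500 nm)
#' and a gentle boost over 500--720 nm (compensating the halogen lamp's
#' red-heavy irradiance removed by calibration), and the blue lobe is
#' extended up to 550 nm. Each channel is renormalized to unit sum so a
#' blank slide renders neutral.
#'
#' Lobe centers/half-widths default to 450/60 (B), 550/60 (G), 600/80 (R)
#' nm; all are overridable since only the qualitative lobe shape is fixed.
#'
#' @param wavelengths band centers in nm, within `[380, 780]`.
#' @param brightness scalar multiplier applied at synthesis (default 2).
#' @param params named list overriding lobe parameters: `centers`,
#'   `half_widths` (named r/g/b), `red_aux` (`center`, `half_width`,
#'   `gain`), `blue_extend_half_width`, `red_boost_gain`.
#' @return object of class `band_weights`: tibble with columns
#'   `wavelength`, `w_r`, `w_g`, `w_b` plus a `brightness` attribute.
#' @export
build_default_weights <- function(wavelengths, brightness = 2,
                                  params = list()) {
  if (!length(wavelengths)) abort("empty wavelength vector")
  if (min(wavelengths) < 380 || max(wavelengths) > 780)
    abort("wavelengths must lie within [380, 780] nm")
  p <- modifyList(list(
    centers = c(r = 600, g = 550, b = 450),
    half_widths = c(r = 80, g = 60, b = 60),
    red_aux = list(center = 440, half_width = 60, gain = 0.4),
    blue_extend_half_width = 100,
    red_boost_gain = 0.08), params)
  wl <- as.numeric(wavelengths)
  w_r <- raised_cosine(wl, p$centers[["r"]], p$half_widths[["r"]]) +
    p$red_aux$gain * raised_cosine(wl, p$red_aux$center, p$red_aux$half_width) +
    p$red_boost_gain * raised_cosine(wl, 610, 110)
  w_g <- raised_cosine(wl, p$centers[["g"]], p$half_widths[["g"]])
  w_b <- raised_cosine(wl, p$centers[["b"]], p$blue_extend_half_width)
  norm1 <- function(w) {
    s <- sum(w)
    if (s <= 0) {
      # lobe support misses all bands: fall back to the nearest band
      w[which.min(abs(wl - p$centers[["b"]]))] <- 1
      s <- 1
    }
    w / s
  }
  out <- tibble(wavelength = wl, w_r = norm1(w_r), w_g = norm1(w_g),
                w_b = norm1(w_b))
  structure(out, brightness = brightness, class = c("band_weights",
                                                    class(out)))
}

#' Raised-cosine lobe
#'
#' `0.5 * (1 + cos(pi * (x - center) / half_width))` inside
#' `|x - center| <= half_width`, zero outside.
#' @param x evaluation points (nm).
#' @param center,half_width lobe center and half-width (nm).
#' @return numeric vector.
#' @export
raised_cosine <- function(x, center, half_width) {
  ifelse(abs(x - center) <= half_width,
         0.5 * (1 + cos(pi * (x - center) / half_width)), 0)
}

#' Synthesize a display RGB image from a transmittance cube
#'
#' Each channel is `brightness * sum_lambda w(lambda) * T(lambda)`,
#' clipped to `[0, 1]`. With unit-sum weights a blank slide (T = 1 in all
#' bands) maps to pure white after the brightness doubling and clip.
#'
#' @param cube transmittance [hyper_cube()].
#' @param weights a `band_weights` object from [build_default_weights()];
#'   defaults to the standard lobes on the cube's wavelengths.
#' @return RGB array `[rows, cols, 3]` in `[0, 1]`.
#' @export
synthesize_rgb <- function(cube, weights = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (cube$units != "transmittance")
    abort("synthesize_rgb requires a transmittance cube")
  if (is.null(weights))
    weights <- build_default_weights(cube$wavelengths)
  if (length(weights$wavelength) != length(cube$wavelengths) ||
      max(abs(weights$wavelength - cube$wavelengths)) > 1e-9)
    abort("weight wavelengths do not match cube wavelengths",
          class = "hsinuc_dimension_error")
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  W <- cbind(weights$w_r, weights$w_g, weights$w_b)
  rgb <- flat %*% W * attr(weights, "brightness")
  array(pmin(pmax(rgb, 0), 1), c(d[1], d[2], 3L))
}

#' Write channel weights to CSV
#' @param weights `band_weights` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.csv(as.data.frame(weights), path, row.names = FALSE)
  invisible(path)
}
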