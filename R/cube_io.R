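#' Hyperspectral cube container
#'
#' A `hyper_cube` wraps a rows x cols x bands array of nonnegative
#' intensities together with its band-center wavelengths. Cubes are either
#' raw detector counts (`units = "raw_dn"`) or normalized transmittance
#' (`units = "transmittance"`), the latter obtained from
#' [calibrate_transmittance()]. An optional logical `valid` matrix marks
#' pixels whose calibration denominator was degenerate; downstream
#' operations skip invalid pixels rather than propagating NaN.
#'
#' @param data numeric array `[rows, cols, bands]`, nonnegative.
#' @param wavelengths strictly increasing band centers in nm; length must
#'   equal `dim(data)[3]`. Defaults to the instrument's 87-band grid over
#'   470--720 nm when the cube has 87 bands.
#' @param units `"raw_dn"` or `"transmittance"`.
#' @param valid optional logical matrix `[rows, cols]`; `NULL` means all
#'   pixels valid.
#' @param meta free-form named list of acquisition metadata.
#' @param clip_max maximum admissible transmittance (values above are a
#'   validity error). Default 1.5.
#' @return object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths = NULL,
                       units = c("raw_dn", "transmittance"),
                       valid = NULL, meta = list(), clip_max = 1.5) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-D array [rows, cols, bands]")
  if (any(dim(data) == 0L)) abort("cube dimensions must be positive")
  nb <- dim(data)[3]
  if (is.null(wavelengths)) {
    if (nb == 87L) wavelengths <- default_wavelengths()
    else abort("`wavelengths` must be given for non-87-band cubes")
  }
  if (length(wavelengths) != nb)
    abort(sprintf("wavelength count (%d) does not match band count (%d)",
                  length(wavelengths), nb))
  if (is.unsorted(wavelengths, strictly = TRUE))
    abort("`wavelengths` must be strictly increasing")
  if (units == "transmittance") {
    v <- if (is.null(valid)) data else data[rep_len(as.vector(valid), length(data))]
    rng <- suppressWarnings(range(v, finite = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > clip_max + 1e-12))
      abort("transmittance values must lie in [0, clip_max] on valid pixels")
  }
  structure(
    list(data = data, wavelengths = as.numeric(wavelengths), units = units,
         valid = valid, meta = meta, clip_max = clip_max),
    class = "hyper_cube")
}

#' Default 87-band wavelength grid (470--720 nm)
#' @return numeric vector of 87 band centers in nm.
#' @export
default_wavelengths <- function() seq(470, 720, length.out = 87)

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d px, %d bands (%.0f-%.0f nm), units %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$units))
  if (!is.null(x$valid))
    cat(sprintf("  invalid pixels: %d\n", sum(!x$valid)))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' White/dark reference pair
#'
#' Bundles the white (blank slide) and dark (blocked light path) reference
#' cubes used by [calibrate_transmittance()]. Both must be raw counts with
#' identical geometry, and the white counts must exceed the dark counts on
#' the valid-pixel set.
#'
#' @param white,dark `hyper_cube`s with `units = "raw_dn"`.
#' @return object of class `reference_pair`.
#' @export
reference_pair <- function(white, dark) {
  stopifnot(inherits(white, "hyper_cube"), inherits(dark, "hyper_cube"))
  if (white$units != "raw_dn" || dark$units != "raw_dn")
    abort("reference cubes must have units raw_dn")
  if (!identical(dim(white$data), dim(dark$data)))
    abort("white and dark references differ in shape")
  if (max(abs(white$wavelengths - dark$wavelengths)) > 1e-9)
    abort("white and dark references differ in wavelengths")
  structure(list(white = white, dark = dark), class = "reference_pair")
}

# ---- ENVI header + raw binary I/O -------------------------------------

envi_dtypes <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE))

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*ENVI", lines[1]))
    abort(sprintf("'%s' is not an ENVI header", path), class = "hsinuc_format_error")
  txt <- paste(lines[-1], collapse = "\n")
  # fold multi-line { ... } blocks onto one line
  br <- gregexpr("\\{[^}]*\\}", txt)
  regmatches(txt, br) <- lapply(regmatches(txt, br),
                                function(x) gsub("\n", " ", x))
  fields <- list()
  # split on lines that look like "key = value", allowing brace blocks
  pat <- gregexpr("(?m)^\\s*([a-zA-Z ][a-zA-Z 0-9_]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)
  m <- regmatches(txt, pat)[[1]]
  for (kv in m) {
    key <- tolower(trimws(sub("=.*", "", kv)))
    val <- trimws(sub("^[^=]*=", "", kv))
    if (grepl("^\\{", val)) {
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
    }
    fields[[key]] <- val
  }
  fields
}

#' Read a hyperspectral cube in ENVI format
#'
#' Reads an ENVI header (`.hdr`) and its companion raw binary. BSQ, BIL
#' and BIP interleaves and data types 1 (uint8), 2 (int16), 4 (float32),
#' 5 (float64) and 12 (uint16) are supported. Wavelengths are taken from
#' the header's `wavelength` block (assumed nm when unlabeled); a
#' `units = transmittance` header tag restores transmittance units. A JSON
#' sidecar `<binary>.mask.json`, when present, restores the valid-pixel
#' mask.
#'
#' @param header_path path to the `.hdr` file.
#' @return a [hyper_cube()].
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path))
    abort(sprintf("header '%s' not found", header_path), class = "hsinuc_io_error")
  hdr <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    abort(paste("header missing fields:", paste(miss, collapse = ", ")),
          class = "hsinuc_format_error")
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  dtype <- envi_dtypes[[hdr$`data type`]]
  if (is.null(dtype))
    abort(sprintf("unsupported ENVI data type %s", hdr$`data type`),
          class = "hsinuc_format_error")
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    abort(sprintf("unsupported interleave '%s'", interleave),
          class = "hsinuc_format_error")
  bin_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(bin_path)) {
    alt <- paste0(bin_path, ".dat")
    if (file.exists(alt)) bin_path <- alt
    else abort(sprintf("binary companion of '%s' not found", header_path),
               class = "hsinuc_io_error")
  }
  nexp <- as.numeric(ns) * nl * nb
  fsz <- file.info(bin_path)$size
  if (fsz != nexp * dtype$size)
    abort(sprintf("binary size %d does not match %d x %d x %d of type %s",
                  fsz, nl, ns, nb, hdr$`data type`),
          class = "hsinuc_format_error")
  endian <- if (!is.null(hdr$`byte order`) && hdr$`byte order` == "1")
    "big" else "little"
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, dtype$what, n = nexp, size = dtype$size,
               signed = dtype$signed, endian = endian)
  v <- as.numeric(v)
  # storage orders: BSQ band-major row-within-band; file is row-major
  arr <- switch(interleave,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3, 2, 1)))
  wl <- if (!is.null(hdr$wavelength)) as.numeric(hdr$wavelength)
        else if (nb == 87L) default_wavelengths()
        else abort("header lacks wavelengths", class = "hsinuc_format_error")
  if (length(wl) != nb)
    abort(sprintf("header declares %d wavelengths for %d bands",
                  length(wl), nb), class = "hsinuc_format_error")
  units <- if (!is.null(hdr$units) && tolower(hdr$units) == "transmittance")
    "transmittance" else "raw_dn"
  valid <- NULL
  mask_path <- paste0(bin_path, ".mask.json")
  if (file.exists(mask_path)) {
    mj <- jsonlite::read_json(mask_path, simplifyVector = TRUE)
    valid <- matrix(TRUE, nl, ns)
    if (length(mj$invalid_row))
      valid[cbind(mj$invalid_row, mj$invalid_col)] <- FALSE
  }
  hyper_cube(arr, wl, units, valid = valid,
             meta = list(header = hdr, path = bin_path))
}

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<path>.hdr` plus the raw binary at `<path>`. Raw-count cubes
#' round-trip bit-exactly (float64 storage by default); transmittance
#' cubes record a `units` tag. When the cube carries a valid-pixel mask a
#' JSON sidecar `<path>.mask.json` stores the invalid pixel indices.
#'
#' @param cube a [hyper_cube()].
#' @param path output path for the binary (header gets `.hdr` appended).
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data-type code (default 5, float64).
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path, interleave = "bsq", data_type = 5L) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (any(d == 0L)) abort("cannot write a zero-size cube")
  interleave <- tolower(interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    abort(sprintf("unsupported interleave '%s'", interleave))
  dtype <- envi_dtypes[[as.character(data_type)]]
  if (is.null(dtype)) abort(sprintf("unsupported data type %d", data_type))
  nl <- d[1]; ns <- d[2]; nb <- d[3]
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(conditionMessage(e),
                                            class = "hsinuc_io_error"))
  on.exit(close(con))
  if (dtype$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = dtype$size, endian = "little")
  hdr <- c(
    "ENVI",
    "description = {hsinuc cube}",
    sprintf("samples = %d", ns),
    sprintf("lines = %d", nl),
    sprintf("bands = %d", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("units = %s", cube$units),
    sprintf("wavelength = {%s}",
            paste(sprintf("%.12g", cube$wavelengths), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  if (!is.null(cube$valid) && any(!cube$valid)) {
    inv <- which(!cube$valid, arr.ind = TRUE)
    jsonlite::write_json(list(invalid_row = inv[, 1], invalid_col = inv[, 2]),
                         paste0(path, ".mask.json"))
  }
  invisible(path)
}

#' Calibrate raw counts to normalized transmittance
#'
#' Converts a raw cube to normalized transmittance with the white and
#' dark references, per band and pixel:
#' \deqn{T(\lambda) = \frac{I_{raw}(\lambda) - I_{dark}(\lambda)}
#'                        {I_{white}(\lambda) - I_{dark}(\lambda)}.}
#' Values are clipped to `[0, clip_max]`; slight excursions above 1 from
#' noise are deliberately retained up to `clip_max` so blank-region
#' statistics stay unbiased. Pixels whose denominator vanishes in any band
#' are flagged invalid in the output's `valid` mask instead of producing
#' NaN.
#'
#' @param raw raw-count [hyper_cube()].
#' @param refs a [reference_pair()] matching `raw` in shape/wavelengths.
#' @param clip_max upper clip for transmittance (default 1.5).
#' @return transmittance [hyper_cube()].
#' @export
calibrate_transmittance <- function(raw, refs, clip_max = 1.5) {
  stopifnot(inherits(raw, "hyper_cube"), inherits(refs, "reference_pair"))
  if (!identical(dim(raw$data), dim(refs$white$data)))
    abort("raw cube and references differ in shape",
          class = "hsinuc_dimension_error")
  if (max(abs(raw$wavelengths - refs$white$wavelengths)) > 1e-9)
    abort("raw cube and references differ in wavelengths",
          class = "hsinuc_dimension_error")
  den <- refs$white$data - refs$dark$data
  bad <- den == 0
  if (all(bad))
    abort("white and dark references are identical everywhere",
          class = "hsinuc_calibration_error")
  den[bad] <- 1
  t <- (raw$data - refs$dark$data) / den
  t[bad] <- 0
  t <- pmin(pmax(t, 0), clip_max)
  d <- dim(bad)
  valid <- matrix(rowSums(matrix(bad, d[1] * d[2], d[3])) == 0, d[1], d[2])
  if (!is.null(raw$valid)) valid <- valid & raw$valid
  if (all(valid)) valid <- NULL
  hyper_cube(t, raw$wavelengths, "transmittance", valid = valid,
             meta = raw$meta, clip_max = clip_max)
}
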