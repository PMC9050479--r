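#' Average spectrum of a nucleus
#'
#' Per-band mean of the transmittance over the masked nucleus pixels of a
#' patch.
#'
#' @param hsi_patch array `[h, w, bands]`.
#' @param nucleus_mask logical matrix `[h, w]`; must select at least one
#'   pixel.
#' @return numeric vector of length `bands`.
#' @export
mean_nucleus_spectrum <- function(hsi_patch, nucleus_mask) {
  d <- dim(hsi_patch)
  stopifnot(length(d) == 3L)
  if (!any(nucleus_mask)) abort("empty nucleus mask")
  flat <- matrix(hsi_patch, d[1] * d[2], d[3])
  colMeans(flat[as.vector(nucleus_mask), , drop = FALSE])
}

#' Sum-normalize a spectrum
#'
#' Divides the spectrum by its sum over all wavelengths,
#' \eqn{S_N(\lambda) = S(\lambda) / \sum_\lambda S(\lambda)}, removing the
#' overall amplitude differences caused by section-thickness variation.
#' The result is scale-invariant and lies on the unit simplex.
#'
#' @param s numeric vector with positive sum.
#' @return normalized vector summing to 1.
#' @export
normalize_spectrum <- function(s) {
  tot <- sum(s)
  if (!is.finite(tot) || tot <= 0)
    abort("spectrum sum must be positive")
  s / tot
}

#' Build spectrum records from extracted nucleus patches
#'
#' Computes the raw mean spectrum (over the segmentation mask patch, or a
#' caller-supplied mask column) and its sum-normalized form for every
#' nucleus record.
#'
#' @param patches tibble from [extract_patches()] (needs `hsi_patch` and
#'   `mask_patch` list-columns).
#' @param mask_column name of the list-column holding the nucleus mask;
#'   defaults to the segmentation `mask_patch`, but externally delineated
#'   masks can be supplied in another column.
#' @return tibble of class `spectrum_records`: identifiers, `label`, and
#'   list-columns `raw` and `normalized` (band vectors).
#' @export
spectrum_records <- function(patches, mask_column = "mask_patch") {
  stopifnot(mask_column %in% names(patches))
  raw <- purrr::map2(patches$hsi_patch, patches[[mask_column]],
                     mean_nucleus_spectrum)
  out <- patches %>%
    select(dplyr::any_of(c("nucleus_id", "patient_id", "image_id",
                           "label"))) %>%
    mutate(raw = raw, normalized = purrr::map(raw, normalize_spectrum))
  class(out) <- c("spectrum_records", class(out))
  out
}

#' Spectrum records as a feature matrix
#' @param records `spectrum_records` tibble.
#' @param which `"normalized"` (default) or `"raw"`.
#' @return numeric matrix, one row per record.
#' @export
spectra_matrix <- function(records, which = "normalized") {
  do.call(rbind, records[[which]])
}

#' Write spectrum records to CSV (one band per column)
#' @param records `spectrum_records` tibble.
#' @param path CSV path.
#' @param wavelengths band centers for column names.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(records, path,
                              wavelengths = default_wavelengths()) {
  m <- spectra_matrix(records)
  colnames(m) <- sprintf("nm%.1f", wavelengths)
  df <- cbind(as.data.frame(records[setdiff(names(records),
                                            c("raw", "normalized"))]), m)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mean class spectra of a record set
#'
#' @param records `spectrum_records` tibble with labels.
#' @param which `"normalized"` or `"raw"`.
#' @param wavelengths band centers.
#' @return tibble `label`, `wavelength`, `mean_value`.
#' @export
class_mean_spectra <- function(records, which = "normalized",
                               wavelengths = default_wavelengths()) {
  records %>%
    group_by(.data$label) %>%
    summarise(spec = list(colMeans(do.call(rbind, .data[[which]]))),
              .groups = "drop") %>%
    tidyr::unnest_longer(col = "spec", values_to = "mean_value") %>%
    group_by(.data$label) %>%
    mutate(wavelength = wavelengths) %>%
    ungroup() %>%
    select("label", "wavelength", "mean_value")
}

#' Plot mean class spectra
#' @param records `spectrum_records` tibble.
#' @param which `"normalized"` or `"raw"`.
#' @param wavelengths band centers.
#' @return a ggplot object.
#' @export
plot_class_spectra <- function(records, which = "normalized",
                               wavelengths = default_wavelengths()) {
  df <- class_mean_spectra(records, which, wavelengths)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength,
                                   y = .data$mean_value,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = sprintf("%s transmittance", which),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
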