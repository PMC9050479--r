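#' Stain absorbance model
#'
#' Unit-peak Gaussian absorbance curves for the two H&E dyes. Peak
#' positions/widths are free parameters with documented defaults (eosin
#' 525/40 nm, hematoxylin 600/60 nm), matching the qualitative placement
#' of the two dyes' absorbance maxima in transmitted-light H&E spectra.
#'
#' @param wavelengths band centers in nm.
#' @param eosin_peak,eosin_width eosin absorbance peak and Gaussian sd (nm).
#' @param hematoxylin_peak,hematoxylin_width hematoxylin counterparts.
#' @return object of class `stain_model` with unit-peak `eosin` and
#'   `hematoxylin` absorbance vectors.
#' @export
stain_model <- function(wavelengths = default_wavelengths(),
                        eosin_peak = 525, eosin_width = 40,
                        hematoxylin_peak = 600, hematoxylin_width = 60) {
  g <- function(p, w) exp(-(wavelengths - p)^2 / (2 * w^2))
  structure(list(wavelengths = as.numeric(wavelengths),
                 eosin = g(eosin_peak, eosin_width),
                 hematoxylin = g(hematoxylin_peak, hematoxylin_width)),
            class = "stain_model")
}

#' Scene specification for the stain-physics simulator
#'
#' Defines one synthetic field of view: elliptical hematoxylin-rich
#' nuclei on an eosin-rich cytoplasm sheet over a blank background.
#' Cancerous scenes draw larger, more variably elongated nuclei (nuclear
#' enlargement and pleomorphism of squamous cell carcinoma) and apply a
#' multiplicative spectral tilt to nucleus transmittance that crosses
#' unity at `crossover_nm`, putting cancerous transmittance above normal
#' below the crossover and below it above — unless `reversed_trend`
#' flips the tilt (the occasional reversed-signature patient).
#'
#' @param shape `c(rows, cols)` (default 256 x 256).
#' @param n_nuclei nuclei to place (default 40).
#' @param class `"cancerous"` or `"normal"`.
#' @param nucleus_area_mean,nucleus_area_sd per-class area distribution
#'   (px); defaults 550/150 cancerous, 300/60 normal.
#' @param ecc_sdlog log-sd of the axis-ratio distribution; defaults 0.35
#'   cancerous, 0.15 normal.
#' @param tilt_amplitude fractional transmittance tilt across the band
#'   range (default 0.12; 0 disables the spectral class difference).
#' @param crossover_nm wavelength where the class spectra cross (645).
#' @param staining_mult,thickness_mult patient-level effects: overall
#'   stain absorbance scale and wavelength-flat transmittance scale.
#' @param hem_mult,eos_mult per-dye absorbance multipliers (independent
#'   per-patient hematoxylin/eosin concentration variation).
#' @param reversed_trend reverse the spectral tilt for this patient.
#' @param noise_sd Gaussian shot-noise sd as a fraction of the dynamic
#'   range (default 0.01).
#' @param blur_fraction fraction of nuclei rendered out of focus (0.1).
#' @param n_distractors lymphocyte-scale distractor objects (default
#'   `round(0.3 * n_nuclei)`); small (~30 px) and hematoxylin-rich, they
#'   must be rejected by the segmentation area filter.
#' @param min_gap_px minimum boundary gap between nuclei (default 6;
#'   nuclei never touch unless `allow_touching`).
#' @param allow_touching permit overlapping nuclei (exercises watershed).
#' @param margin_px keep-out margin from the image edge for nucleus
#'   centers.
#' @param background_fraction approximate blank (glass) area fraction.
#' @param seed integer seed; scenes are bit-reproducible given the spec.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(256L, 256L), n_nuclei = 40L,
                       class = c("normal", "cancerous"),
                       nucleus_area_mean = NULL, nucleus_area_sd = NULL,
                       ecc_sdlog = NULL, tilt_amplitude = 0.12,
                       crossover_nm = 645, staining_mult = 1,
                       thickness_mult = 1, hem_mult = 1, eos_mult = 1,
                       reversed_trend = FALSE,
                       noise_sd = 0.01, blur_fraction = 0.1,
                       n_distractors = NULL, min_gap_px = 6,
                       allow_touching = FALSE, margin_px = 14,
                       background_fraction = 0.12, seed = 1L) {
  class <- match.arg(class)
  if (is.null(nucleus_area_mean))
    nucleus_area_mean <- if (class == "cancerous") 550 else 300
  if (is.null(nucleus_area_sd))
    nucleus_area_sd <- if (class == "cancerous") 150 else 60
  if (is.null(ecc_sdlog))
    ecc_sdlog <- if (class == "cancerous") 0.35 else 0.15
  if (is.null(n_distractors)) n_distractors <- round(0.3 * n_nuclei)
  structure(as.list(environment()), class = "scene_spec")
}

smooth_field <- function(h, w, sigma) {
  f <- matrix(rnorm(h * w), h, w)
  # cap the kernel so it fits small scenes
  r <- min(ceiling(3 * sigma), (min(h, w) - 1) %/% 2)
  x <- -r:r
  k1 <- exp(-x^2 / (2 * sigma^2))
  g <- conv2(f, outer(k1, k1) / sum(k1)^2)
  (g - mean(g)) / sd(g)
}

#' Generate a synthetic hyperspectral H&E scene
#'
#' Renders the scene of a [scene_spec()] under Beer-Lambert (base-10)
#' stain physics: the absorbance field is
#' `A(p, lambda) = staining_mult * (c_hem(p) hem(lambda) + c_eos(p) eos(lambda))`,
#' transmittance is `10^-A` times the wavelength-flat thickness factor
#' and, inside cancerous nuclei, the spectral class tilt; the raw cube is
#' `dark + T * (white - dark)` plus Gaussian shot noise, with a smooth
#' halogen-like white reference. A `blur_fraction` of nuclei is locally
#' defocused. Nuclei that cannot be placed within the overlap rules after
#' bounded retries are dropped (the realized count is in the truth table).
#'
#' @param spec a [scene_spec()].
#' @param stains a [stain_model()].
#' @return list with raw/white/dark [hyper_cube()]s, `transmittance`
#'   (noise-free ground-truth cube), and `truth` (list: `mask`, `labels`,
#'   `nuclei` tibble with centroids/areas, `class`).
#' @export
generate_scene <- function(spec, stains = stain_model()) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  h <- spec$shape[1]; w <- spec$shape[2]
  wl <- stains$wavelengths; nb <- length(wl)

  # tissue sheet: smooth random field thresholded for the blank fraction
  fld <- smooth_field(h, w, 12)
  tissue <- fld > quantile(fld, spec$background_fraction)
  c_eos <- ifelse(tissue, 0.45 * (1 + 0.15 * smooth_field(h, w, 4)), 0)
  c_eos <- pmax(c_eos, 0)
  c_hem <- matrix(0, h, w)

  # place nuclei (and small distractors) inside the tissue sheet
  labels <- matrix(0L, h, w)
  placed <- list()
  occupied_r <- numeric(0); occupied_c <- numeric(0); occupied_rad <- numeric(0)
  place_one <- function(area, sdlog, id, is_distractor) {
    for (try in 1:60) {
      r0 <- runif(1, spec$margin_px + 1, h - spec$margin_px)
      c0 <- runif(1, spec$margin_px + 1, w - spec$margin_px)
      if (!tissue[round(r0), round(c0)]) next
      req <- sqrt(area / pi)
      if (!spec$allow_touching && length(occupied_r)) {
        dmin <- min(sqrt((occupied_r - r0)^2 + (occupied_c - c0)^2) -
                      occupied_rad)
        if (dmin < req + spec$min_gap_px) next
      }
      q <- rlnorm(1, log(1.3), sdlog)        # axis ratio a/b
      a <- req * sqrt(q); b <- req / sqrt(q)
      th <- runif(1, 0, pi)
      bb_r <- max(1, floor(r0 - a - 2)):min(h, ceiling(r0 + a + 2))
      bb_c <- max(1, floor(c0 - a - 2)):min(w, ceiling(c0 + a + 2))
      rr <- outer(bb_r - r0, rep(1, length(bb_c)))
      cc <- outer(rep(1, length(bb_r)), bb_c - c0)
      u <- cc * cos(th) + rr * sin(th)
      v <- -cc * sin(th) + rr * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      if (!is_distractor && !spec$allow_touching &&
          any(labels[bb_r, bb_c][inside] > 0)) next
      sel <- cbind(rep(bb_r, length(bb_c))[inside],
                   rep(bb_c, each = length(bb_r))[inside])
      if (!is_distractor) labels[sel] <<- id
      c_hem[sel] <<- pmax(c_hem[sel],
                          (if (is_distractor) 1.1 else 0.85) *
                            (1 + 0.08 * rnorm(1)))
      occupied_r <<- c(occupied_r, r0); occupied_c <<- c(occupied_c, c0)
      occupied_rad <<- c(occupied_rad, a)
      return(list(row = r0, col = c0, area = sum(inside),
                  is_distractor = is_distractor))
    }
    NULL
  }
  nid <- 0L
  for (i in seq_len(spec$n_nuclei)) {
    area <- max(60, rnorm(1, spec$nucleus_area_mean, spec$nucleus_area_sd))
    res <- place_one(area, spec$ecc_sdlog, nid + 1L, FALSE)
    if (!is.null(res)) { nid <- nid + 1L; placed[[nid]] <- res }
  }
  for (i in seq_len(spec$n_distractors))
    place_one(runif(1, 25, 45), 0.1, 0L, TRUE)

  nuclei <- if (nid)
    bind_rows(lapply(placed, as_tibble)) %>%
      mutate(label = row_number(), class = spec$class,
             is_blurred = FALSE) else
    tibble(row = numeric(0), col = numeric(0), area = integer(0),
           is_distractor = logical(0), label = integer(0),
           class = character(0), is_blurred = logical(0))

  # Beer-Lambert transmittance with class tilt and patient effects
  tilt_dir <- if (spec$class == "cancerous")
    (if (spec$reversed_trend) 1 else -1) else 0
  tilt <- 1 + tilt_dir * spec$tilt_amplitude *
    (wl - spec$crossover_nm) / diff(range(wl))
  A_flat <- outer(as.vector(spec$hem_mult * c_hem), stains$hematoxylin) +
    outer(as.vector(spec$eos_mult * c_eos), stains$eosin)
  Tm <- 10^(-spec$staining_mult * A_flat) * spec$thickness_mult
  in_nucleus <- as.vector(labels > 0)
  if (tilt_dir != 0 && any(in_nucleus))
    Tm[in_nucleus, ] <- Tm[in_nucleus, ] %*% diag(tilt)
  Tarr <- array(Tm, c(h, w, nb))

  # defocus a fraction of nuclei
  if (spec$blur_fraction > 0 && nid > 0) {
    nblur <- floor(spec$blur_fraction * nid)
    if (nblur > 0) {
      for (id in sample.int(nid, nblur)) {
        px <- which(labels == id, arr.ind = TRUE)
        r <- (max(px[, 1]) - min(px[, 1])) %/% 2 + 6
        rr <- max(1, min(px[, 1]) - 6):min(h, max(px[, 1]) + 6)
        cc <- max(1, min(px[, 2]) - 6):min(w, max(px[, 2]) + 6)
        for (b in seq_len(nb))
          Tarr[rr, cc, b] <- conv2(Tarr[rr, cc, b], gaussian_kernel(2))
        nuclei$is_blurred[nuclei$label == id] <- TRUE
      }
    }
  }

  # acquisition: smooth flat-field x halogen-like lamp spectrum
  lamp <- 1500 * (0.55 + 0.45 * (wl - min(wl)) / diff(range(wl)))
  flat <- 1 - 0.15 * ((row(labels) - h / 2)^2 + (col(labels) - w / 2)^2) /
    ((h / 2)^2 + (w / 2)^2)
  white_arr <- outer(flat, lamp) + 80
  dim(white_arr) <- c(h, w, nb)
  dark_arr <- array(100, c(h, w, nb))
  gain <- white_arr - dark_arr
  raw_arr <- dark_arr + Tarr * gain +
    array(rnorm(h * w * nb, sd = spec$noise_sd), c(h, w, nb)) * gain
  raw_arr <- pmax(raw_arr, 0)

  list(
    raw = hyper_cube(raw_arr, wl, "raw_dn"),
    white = hyper_cube(white_arr, wl, "raw_dn"),
    dark = hyper_cube(dark_arr, wl, "raw_dn"),
    transmittance = hyper_cube(pmin(Tarr, 1.5), wl, "transmittance"),
    truth = list(mask = labels > 0, labels = labels, nuclei = nuclei,
                 class = spec$class, spec = spec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a multi-patient synthetic dataset
#'
#' Draws per-patient effects once per patient — overall staining scale,
#' section thickness, and independent hematoxylin/eosin concentration
#' multipliers (log-normal with sd-logs `staining_sdlog`,
#' `thickness_sdlog`, `dye_sdlog`) — flags `round(reversed_fraction *
#' n_patients)` patients as reversed-trend, and lays out
#' `images_per_patient` scenes per patient alternating cancerous and
#' normal fields. Scene specs (not rendered cubes) are returned so
#' callers can realize scenes one at a time; every spec carries its own
#' deterministic seed derived from `seed`.
#'
#' @param n_patients number of patients (>= 2).
#' @param images_per_patient scenes per patient (half cancerous).
#' @param reversed_fraction fraction of patients with the reversed
#'   spectral trend, in `[0, 1]`.
#' @param seed master seed.
#' @param staining_sdlog,thickness_sdlog,dye_sdlog sd-logs of the
#'   per-patient effect distributions (defaults 0.15, 0.20, 0.15).
#' @param ... overrides passed to every [scene_spec()] (e.g. `shape`,
#'   `n_nuclei`, `tilt_amplitude`).
#' @return tibble with one row per image: `patient_id`, `image_id`,
#'   `class`, the per-patient effect columns, `reversed_trend`, and a
#'   `spec` list-column of [scene_spec()]s.
#' @export
generate_patient_set <- function(n_patients, images_per_patient = 4L,
                                 reversed_fraction = 0, seed = 1L,
                                 staining_sdlog = 0.15,
                                 thickness_sdlog = 0.20,
                                 dye_sdlog = 0.15, ...) {
  if (n_patients < 2L) abort("need at least 2 patients")
  if (reversed_fraction < 0 || reversed_fraction > 1)
    abort("reversed_fraction must lie in [0, 1]")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  n_rev <- round(reversed_fraction * n_patients)
  rev_ids <- sample.int(n_patients, n_rev)
  stain <- rlnorm(n_patients, 0, staining_sdlog)
  thick <- rlnorm(n_patients, 0, thickness_sdlog)
  hem <- rlnorm(n_patients, 0, dye_sdlog)
  eos <- rlnorm(n_patients, 0, dye_sdlog)
  dots <- list(...)
  rows <- list()
  for (p in seq_len(n_patients)) {
    for (im in seq_len(images_per_patient)) {
      cls <- if (im %% 2L == 1L) "cancerous" else "normal"
      args <- modifyList(list(
        class = cls, staining_mult = stain[p], thickness_mult = thick[p],
        hem_mult = hem[p], eos_mult = eos[p],
        reversed_trend = p %in% rev_ids,
        seed = as.integer((as.numeric(seed) * 1009 + p * 131 + im * 7) %%
                            2147483647)),
        dots)
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = sprintf("P%02d", p),
        image_id = sprintf("P%02d_I%02d", p, im),
        class = cls, staining_mult = stain[p], thickness_mult = thick[p],
        hem_mult = hem[p], eos_mult = eos[p],
        reversed_trend = p %in% rev_ids,
        spec = list(do.call(scene_spec, args)))
    }
  }
  bind_rows(rows)
}

#' Realize spectrum records for a simulated patient set
#'
#' Renders each scene, calibrates it with its own references, and
#' computes the truth-masked average nucleus spectra — the fast path for
#' spectral-classifier studies that needs no segmentation.
#'
#' @param pset tibble from [generate_patient_set()].
#' @param stains a [stain_model()].
#' @return `spectrum_records` tibble.
#' @export
simulate_spectrum_records <- function(pset, stains = stain_model()) {
  out <- purrr::pmap(pset, function(patient_id, image_id, class, spec, ...) {
    sc <- generate_scene(spec, stains)
    cube <- calibrate_transmittance(sc$raw, reference_pair(sc$white, sc$dark))
    nuc <- sc$truth$nuclei
    if (!nrow(nuc)) return(NULL)
    flat <- matrix(cube$data, prod(spec$shape), length(cube$wavelengths))
    raw <- lapply(nuc$label, function(id)
      colMeans(flat[as.vector(sc$truth$labels == id), , drop = FALSE]))
    tibble(nucleus_id = sprintf("%s_n%03d", image_id, nuc$label),
           patient_id = patient_id, image_id = image_id, label = class,
           raw = raw, normalized = lapply(raw, normalize_spectrum))
  })
  out <- bind_rows(purrr::compact(out))
  class(out) <- c("spectrum_records", class(out))
  out
}

#' Realize nucleus patch records for a simulated patient set
#'
#' Renders each scene, calibrates it, synthesizes the paired RGB image,
#' and extracts truth-centered patches (window centered on each true
#' nucleus centroid), giving CNN-ready records without segmentation
#' noise. Patch storage is the transmittance cube subwindow.
#'
#' @param pset tibble from [generate_patient_set()].
#' @param size odd patch edge (px). Scenes must be large enough for the
#'   window to fit; nuclei too close to the border are dropped.
#' @param stains a [stain_model()].
#' @return patch-record tibble as from [extract_patches()].
#' @export
simulate_patch_records <- function(pset, size = 101L,
                                   stains = stain_model()) {
  out <- purrr::pmap(pset, function(patient_id, image_id, class, spec, ...) {
    sc <- generate_scene(spec, stains)
    cube <- calibrate_transmittance(sc$raw, reference_pair(sc$white, sc$dark))
    rgb <- synthesize_rgb(cube)
    mask <- structure(list(binary = sc$truth$mask, labels = sc$truth$labels,
                           centroids = sc$truth$nuclei %>%
                             select("label", "row", "col", "area"),
                           min_area = 0), class = "nuclei_mask")
    extract_patches(cube, rgb, mask, size = size, label = class,
                    patient_id = patient_id, image_id = image_id)
  })
  bind_rows(out)
}

#' Synthetic calibration-target image pair for registration
#'
#' A grid of randomly shaded squares (distinct corner neighborhoods)
#' rendered as the fixed frame, plus the same pattern warped by a known
#' affine transform as the moving frame.
#'
#' @param shape `c(rows, cols)`.
#' @param transform an [affine_transform()] (moving -> fixed); default a
#'   modest translation/rotation/scale.
#' @param cell_px grid cell edge.
#' @param seed integer seed.
#' @return list with `fixed`, `moving` (grayscale matrices) and
#'   `transform` (the ground truth).
#' @export
simulate_calibration_pair <- function(shape = c(320L, 320L),
                                      transform = NULL, cell_px = 16L,
                                      seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  if (is.null(transform)) {
    th <- 2 * pi / 180; s <- 1.02
    transform <- affine_transform(cbind(s * matrix(c(cos(th), sin(th),
                                                     -sin(th), cos(th)), 2),
                                        c(8, -5)))
  }
  h <- shape[1]; w <- shape[2]
  gr <- matrix(runif((h %/% cell_px + 2) * (w %/% cell_px + 2)),
               h %/% cell_px + 2)
  fixed <- gr[cbind(rep(1 + (seq_len(h) - 1) %/% cell_px, w),
                    rep(1 + (seq_len(w) - 1) %/% cell_px, each = h))]
  dim(fixed) <- c(h, w)
  fixed <- fixed + 0.01 * matrix(rnorm(h * w), h)
  fixed <- pmin(pmax(fixed, 0), 1)
  # moving frame shows the scene as seen by the other camera:
  # moving(p) = fixed(transform(p)), i.e. warp fixed by the forward map
  inv <- transform$matrix
  warped <- cpp_warp_affine(array(fixed, c(h, w, 1L)), h, w, 1L,
                            as.numeric(t(inv)), h, w)
  moving <- matrix(warped$image, h, w)
  list(fixed = fixed, moving = moving, transform = transform)
}
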