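#' Run configuration for the end-to-end pipeline
#'
#' Validates and normalizes the configuration driving [run_pipeline()].
#' Patient partitions must be pairwise disjoint: records of one patient
#' never appear in more than one of train/validation/test.
#'
#' @param config named list (or YAML path read with [read_run_config()]):
#'   \describe{
#'     \item{simulate}{list of arguments for [generate_patient_set()]
#'       (`n_patients`, `images_per_patient`, ...); the pipeline runs on
#'       simulated scenes.}
#'     \item{segmentation}{`threshold`, `min_area`, `patch_size`.}
#'     \item{classifier}{`"svm"`, `"cnn-rgb"` or `"cnn-hsi"`.}
#'     \item{partition}{`train`, `validation`, `test` patient-id vectors
#'       (CNN), or `lopo = TRUE` (SVM).}
#'     \item{imagewise}{`candidates` fraction thresholds.}
#'     \item{cnn}{overrides for [cnn_config()] (e.g. `width_multiplier`,
#'       `lr`, `max_epochs`).}
#'     \item{seed}{integer master seed.}
#'   }
#' @return validated config (class `run_config`).
#' @export
run_config <- function(config) {
  defaults <- list(
    simulate = list(n_patients = 4L, images_per_patient = 4L,
                    reversed_fraction = 0),
    segmentation = list(threshold = 0, min_area = 200, patch_size = 101L),
    classifier = "svm",
    partition = list(lopo = TRUE),
    imagewise = list(candidates = c(.01, .05, .10, .20, .30)),
    cnn = list(),
    seed = 1L)
  cfg <- modifyList(defaults, config)
  if (!cfg$classifier %in% c("svm", "cnn-rgb", "cnn-hsi"))
    abort("classifier must be one of svm, cnn-rgb, cnn-hsi")
  parts <- cfg$partition[intersect(names(cfg$partition),
                                   c("train", "validation", "test"))]
  if (length(parts) > 1) {
    for (i in seq_along(parts)) for (j in seq_along(parts)) {
      if (i >= j) next
      ov <- intersect(parts[[i]], parts[[j]])
      if (length(ov))
        abort(sprintf("partitions '%s' and '%s' share patients: %s",
                      names(parts)[i], names(parts)[j],
                      paste(ov, collapse = ", ")))
    }
  }
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) run_config(yaml::read_yaml(path))

#' @rdname read_run_config
#' @param config a [run_config()] (or plain list) to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the pipeline end-to-end
#'
#' Executes simulate -> calibrate -> register -> segment -> extract ->
#' classify -> image-wise on a simulated patient set, writing result
#' tables (CSV) and a versioned JSON run manifest (config hash, seed,
#' stage timings, record counts) under `out_dir`. Any stage failure
#' aborts with a stage-tagged error; tables written before the failure
#' are retained.
#'
#' @param config a [run_config()] (or plain list passed through it).
#' @param out_dir output directory (created if needed).
#' @return list with `manifest`, `nuclei` (per-nucleus predictions),
#'   `images` (per-image results tibble).
#' @export
run_pipeline <- function(config, out_dir = tempfile("hsinuc_run_")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = list())
  t_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "hsinuc_stage_error"))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  pset <- t_stage("simulate", function()
    do.call(generate_patient_set,
            c(cfg$simulate, list(seed = cfg$seed))))
  manifest$stages$simulate$n_images <- nrow(pset)

  # one session-level registration transform from a calibration target
  target <- t_stage("register", function()
    simulate_calibration_pair(seed = cfg$seed))
  reg <- estimate_affine(target$fixed, target$moving)
  save_affine(reg, file.path(out_dir, "registration.json"))
  manifest$stages$register$inlier_ratio <- reg$meta$inlier_ratio

  seg <- cfg$segmentation
  records <- t_stage("segment_extract", function() {
    purrr::pmap(pset, function(patient_id, image_id, class, spec, ...) {
      sc <- generate_scene(spec)
      cube <- calibrate_transmittance(sc$raw,
                                      reference_pair(sc$white, sc$dark))
      rgb_native <- synthesize_rgb(cube)
      # the paired camera sees the scene through the session transform
      moving <- apply_affine(rgb_native, affine_invert(reg),
                             dim(cube$data)[1:2])$image
      registered <- apply_affine(moving, reg, dim(cube$data)[1:2])
      m <- segment_nuclei(cube, seg$threshold, seg$min_area)
      extract_patches(cube, registered, m, size = seg$patch_size,
                      label = class, patient_id = patient_id,
                      image_id = image_id)
    }) %>% bind_rows()
  })
  manifest$stages$segment_extract$n_nuclei <- nrow(records)
  if (!nrow(records))
    abort(paste("stage 'segment_extract' produced no nucleus records;",
                "scenes may be too small for the patch size and",
                "registration margin"), class = "hsinuc_stage_error")

  preds <- t_stage("classify", function() {
    if (cfg$classifier == "svm") {
      spectra <- spectrum_records(records)
      cv <- lopo_cv(spectra)
      cv$predictions %>%
        mutate(decision = .data$prediction)
    } else {
      col <- if (cfg$classifier == "cnn-hsi") "hsi_patch" else "rgb_patch"
      ch <- if (cfg$classifier == "cnn-hsi") 87L else 3L
      part <- cfg$partition
      tr <- records %>% filter(.data$patient_id %in% part$train)
      va <- records %>% filter(.data$patient_id %in% part$validation)
      te <- records %>% filter(.data$patient_id %in% part$test)
      ccfg <- do.call(cnn_config, modifyList(
        list(input_channels = ch, input_size = seg$patch_size,
             seed = cfg$seed), cfg$cnn))
      model <- train(build_model(ccfg), tr, va, patch_column = col)
      vp <- predict_cnn(model, va, col)
      thr <- select_threshold(vp$probability, va$label)
      bind_rows(
        predict_cnn(model, va, col, threshold = thr) %>%
          mutate(patient_id = va$patient_id, image_id = va$image_id,
                 truth = va$label, partition = "validation"),
        predict_cnn(model, te, col, threshold = thr) %>%
          mutate(patient_id = te$patient_id, image_id = te$image_id,
                 truth = te$label, partition = "test"))
    }
  })
  utils::write.csv(as.data.frame(preds %>% select(-dplyr::any_of(
    c("hsi_patch", "rgb_patch", "mask_patch")))),
    file.path(out_dir, "nucleus_predictions.csv"), row.names = FALSE)

  images <- t_stage("imagewise", function() {
    by_img <- preds %>% group_by(.data$image_id) %>%
      summarise(fraction = mean(.data$decision == "cancerous"),
                n_total = n(), .groups = "drop") %>%
      left_join(pset %>% select("image_id", truth_img = "class"),
                by = "image_id")
    thr <- select_image_threshold(
      by_img %>% mutate(truth = .data$truth_img),
      cfg$imagewise$candidates)
    res <- purrr::map2(split(preds, preds$image_id),
                       names(split(preds, preds$image_id)),
                       function(df, id)
                         classify_image(df, thr, image_id = id)) %>%
      bind_rows() %>%
      left_join(pset %>% select("image_id", truth = "class"),
                by = "image_id")
    attr(res, "threshold") <- thr
    res
  })
  utils::write.csv(as.data.frame(images),
                   file.path(out_dir, "imagewise_results.csv"),
                   row.names = FALSE)

  manifest$stages$imagewise$threshold <- attr(images, "threshold")
  manifest$stages$imagewise$n_images <- nrow(images)
  manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, nuclei = preds, images = images,
       out_dir = out_dir)
}
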