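#' Hyperparameter grid for the spectral SVM
#'
#' The canonical grid spans `log2 C` and `log2 g` over `{-1, 0, ..., 4}`,
#' 36 candidate pairs in total. `g` is the RBF kernel scale:
#' `K(u, v) = exp(-||u - v||^2 / g^2)`, i.e. the kernel width in units of
#' feature-space distance (the convention of MATLAB's `KernelScale`); the
#' equivalent libsvm `gamma` is `1 / g^2`.
#'
#' @param log2_C,log2_g integer exponent sets.
#' @return tibble with columns `C` and `g` (one row per pair).
#' @export
svm_grid <- function(log2_C = -1:4, log2_g = -1:4) {
  tidyr::expand_grid(C = 2^log2_C, g = 2^log2_g)
}

#' Fit the RBF-kernel SVM on normalized spectra
#'
#' Thin wrapper over [e1071::svm()] (C-classification, radial kernel,
#' feature standardization on). `g` is the kernel scale (see
#' [svm_grid()]); deterministic given the data and `(C, g)`.
#'
#' @param x numeric feature matrix (rows = nuclei).
#' @param y factor or character labels with both classes present.
#' @param C cost parameter.
#' @param g RBF kernel scale; libsvm `gamma = 1 / g^2`.
#' @return fitted `svm` object.
#' @export
fit_svm <- function(x, y, C = 1, g = 1) {
  y <- factor(as.character(y))
  if (nlevels(y) < 2L)
    abort("training set must contain both classes")
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = 1 / g^2, scale = TRUE)
}

# deterministic stratified k-fold assignment: records are put in a stable
# order first, so fold membership is invariant to input permutation
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in unique(y)) {
    i <- which(y == lv)
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

#' Leave-one-patient-out cross-validation of the spectral SVM
#'
#' For each patient, all of that patient's records are held out; the
#' `(C, gamma)` pair is chosen by stratified `inner_folds`-fold
#' cross-validated accuracy on the training partition only (ties broken
#' toward smaller C, then smaller gamma), the winner is refit on the full
#' training partition and evaluated on the held-out patient. No record of
#' the held-out patient ever influences training or model selection.
#'
#' @param records `spectrum_records` tibble (needs `patient_id`, `label`,
#'   `normalized`).
#' @param grid tibble of `(C, gamma)` candidates from [svm_grid()].
#' @param inner_folds folds for inner model selection (default 5).
#' @return object of class `lopo_cv`: list with `per_patient` tibble
#'   (`patient_id`, `n`, `C`, `gamma`, `accuracy`, `sensitivity`,
#'   `specificity`), `grid`, and `predictions` tibble.
#' @export
lopo_cv <- function(records, grid = svm_grid(), inner_folds = 5L) {
  stopifnot(all(c("patient_id", "label", "normalized") %in% names(records)))
  records <- records %>%
    arrange(.data$patient_id, .data$image_id, .data$nucleus_id)
  patients <- unique(records$patient_id)
  if (length(patients) < 2L) abort("need at least 2 patients")
  x_all <- spectra_matrix(records)
  y_all <- factor(records$label)
  if (nlevels(y_all) < 2L) abort("corpus must contain both classes")
  rows <- list(); preds <- list()
  for (p in patients) {
    hold <- records$patient_id == p
    if (!any(hold)) {
      warn(sprintf("patient %s has zero records; skipped", p))
      next
    }
    xtr <- x_all[!hold, , drop = FALSE]; ytr <- droplevels(y_all[!hold])
    xte <- x_all[hold, , drop = FALSE]; yte <- y_all[hold]
    fold <- stratified_folds(as.character(ytr), inner_folds)
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      ok <- 0L
      for (f in seq_len(inner_folds)) {
        tr <- fold != f
        if (length(unique(ytr[tr])) < 2L) next
        fit <- fit_svm(xtr[tr, , drop = FALSE], ytr[tr],
                       grid$C[i], grid$g[i])
        ok <- ok + sum(predict(fit, xtr[!tr, , drop = FALSE]) == ytr[!tr])
      }
      ok / length(ytr)
    }, numeric(1))
    best <- order(-acc, grid$C, grid$g)[1]
    fit <- fit_svm(xtr, ytr, grid$C[best], grid$g[best])
    pred <- predict(fit, xte)
    cc <- confusion_counts(pred == "cancerous", yte == "cancerous")
    met <- compute_metrics(cc)
    rows[[p]] <- tibble(
      patient_id = p, n = sum(hold),
      C = grid$C[best], g = grid$g[best],
      inner_accuracy = acc[best],
      accuracy = met$accuracy, sensitivity = met$sensitivity,
      specificity = met$specificity)
    preds[[p]] <- tibble(nucleus_id = records$nucleus_id[hold],
                         patient_id = p,
                         image_id = records$image_id[hold],
                         truth = as.character(yte),
                         prediction = as.character(pred))
  }
  structure(list(per_patient = bind_rows(rows),
                 predictions = bind_rows(preds), grid = grid),
            class = "lopo_cv")
}

#' @export
print.lopo_cv <- function(x, ...) {
  cat(sprintf("<lopo_cv> %d patients, grid of %d (C, g) pairs\n",
              nrow(x$per_patient), nrow(x$grid)))
  cat(sprintf("  mean held-out accuracy %.3f\n",
              mean(x$per_patient$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn lopo_cv per-patient held-out metrics.
#' @param x `lopo_cv` object.
#' @param ... unused.
#' @export
tidy.lopo_cv <- function(x, ...) x$per_patient

#' @describeIn lopo_cv one-row overall summary (record-weighted and
#'   patient-mean accuracies).
#' @export
glance.lopo_cv <- function(x, ...) {
  ok <- x$predictions$truth == x$predictions$prediction
  tibble(n_patients = nrow(x$per_patient),
         n_records = nrow(x$predictions),
         accuracy = mean(ok),
         mean_patient_accuracy = mean(x$per_patient$accuracy, na.rm = TRUE),
         mean_sensitivity = mean(x$per_patient$sensitivity, na.rm = TRUE),
         mean_specificity = mean(x$per_patient$specificity, na.rm = TRUE))
}

#' @describeIn lopo_cv per-patient accuracy bar chart.
#' @param object `lopo_cv` object.
#' @export
autoplot.lopo_cv <- function(object, ...) {
  ggplot2::ggplot(object$per_patient,
                  ggplot2::aes(x = .data$patient_id, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(object$per_patient$accuracy),
                        linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "held-out patient", y = "accuracy") +
    ggplot2::theme_minimal()
}
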