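#' Confusion counts
#'
#' Tallies TP/FP/TN/FN with cancerous as the positive class.
#'
#' @param pred_pos,truth_pos logical vectors (TRUE = called/true cancerous),
#'   or supply counts directly via `tp`, `fp`, `tn`, `fn`.
#' @param tp,fp,tn,fn nonnegative integer counts (alternative interface).
#' @return object of class `confusion_counts` (named list).
#' @export
confusion_counts <- function(pred_pos = NULL, truth_pos = NULL,
                             tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(pred_pos)) {
    stopifnot(length(pred_pos) == length(truth_pos))
    tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
    tn <- sum(!pred_pos & !truth_pos); fn <- sum(!pred_pos & truth_pos)
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`, with
#' cancerous the positive class. A metric whose denominator is zero is
#' returned as `NA` with its name recorded in the `undefined` column.
#'
#' @param counts a [confusion_counts()].
#' @return one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `undefined` (comma-separated names, `""` if none).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- with(counts, tp + fp + tn + fn)
  if (tot == 0) abort("no records to evaluate")
  undef <- character(0)
  acc <- with(counts, (tp + tn) / tot)
  sens <- with(counts, if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  spec <- with(counts, if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  if (is.na(sens)) undef <- c(undef, "sensitivity")
  if (is.na(spec)) undef <- c(undef, "specificity")
  tibble(accuracy = acc, sensitivity = sens, specificity = spec,
         undefined = paste(undef, collapse = ","))
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over all distinct score cut-points; tied scores are
#' handled by the rank-midpoint convention, making the value identical to
#' the Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores numeric scores (higher = more cancerous).
#' @param truths logical or label vector (TRUE / `"cancerous"` = positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truths) {
  pos <- as_positive(truths)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    abort("both classes must be present for ROC analysis")
  # trapezoid over cut-points at each distinct score (descending)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n1); fpr <- c(0, fp[last] / n0)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

as_positive <- function(truths) {
  if (is.logical(truths)) return(truths)
  truths == "cancerous" | truths == TRUE | truths == 1
}

#' ROC-optimal probability threshold (Youden's J)
#'
#' Sweeps all candidate cut-points of the validation scores and returns
#' the threshold maximizing `sensitivity + specificity - 1`. The returned
#' threshold is the midpoint between the adjacent distinct scores
#' straddling the optimum, so perfectly separated score sets yield the
#' midpoint of the gap. If no cut-point beats `J = 0` (uninformative
#' scores) 0.5 is returned with a warning.
#'
#' @param scores validation probabilities.
#' @param truths validation truth labels (both classes required).
#' @return scalar threshold.
#' @export
select_threshold <- function(scores, truths) {
  pos <- as_positive(truths)
  if (!any(pos) || all(pos))
    abort("validation set must contain both classes")
  s <- sort(unique(scores))
  cuts <- c(s[1] - 1, (head(s, -1) + s[-1]) / 2, s[length(s)] + 1)
  j <- vapply(cuts, function(ct) {
    sens <- mean(scores[pos] >= ct)
    spec <- mean(scores[!pos] < ct)
    sens + spec - 1
  }, numeric(1))
  if (max(j) <= 0) {
    warn("uninformative validation scores; falling back to threshold 0.5")
    return(0.5)
  }
  best <- cuts[which.max(j)]
  min(max(best, 0), 1)
}

#' Image-wise decision from per-nucleus predictions
#'
#' Counts nuclei called cancerous (`N_C`) among all nuclei of the image
#' (`N_Total`) and calls the image cancerous when the fraction
#' `N_C / N_Total` reaches the threshold (inclusive). An image with no
#' nuclei is `indeterminate` rather than normal — regions with very few
#' nuclei carry no evidence either way.
#'
#' @param preds tibble (or data.frame) of one image's nucleus predictions
#'   with a `decision` column (`"cancerous"` / `"normal"`), or a logical
#'   vector of cancer calls.
#' @param threshold fraction threshold in (0, 1).
#' @param image_id identifier copied into the result.
#' @return one-row tibble of class `imagewise_result`: `image_id`,
#'   `n_cancer`, `n_total`, `fraction`, `decision`, `threshold`.
#' @export
classify_image <- function(preds, threshold, image_id = NA_character_) {
  stopifnot(threshold > 0, threshold < 1)
  calls <- if (is.data.frame(preds)) preds$decision == "cancerous"
           else as.logical(preds)
  n_total <- length(calls); n_cancer <- sum(calls)
  if (n_total == 0L) {
    out <- tibble(image_id = image_id, n_cancer = 0L, n_total = 0L,
                  fraction = NA_real_, decision = "indeterminate",
                  threshold = threshold)
  } else {
    frac <- n_cancer / n_total
    out <- tibble(image_id = image_id, n_cancer = as.integer(n_cancer),
                  n_total = as.integer(n_total), fraction = frac,
                  decision = if (frac >= threshold) "cancerous" else "normal",
                  threshold = threshold)
  }
  class(out) <- c("imagewise_result", class(out))
  out
}

#' Select the image-wise fraction threshold on validation images
#'
#' Evaluates each candidate threshold by the number of correctly
#' classified validation images and returns the winner; ties are broken
#' toward the smaller threshold, since a larger threshold raises the risk
#' of false negatives.
#'
#' @param val_results tibble with per-image `fraction` and `truth`
#'   (`"cancerous"` / `"normal"`); indeterminate images (NA fraction) are
#'   ignored.
#' @param candidates candidate thresholds (default 1%, 5%, 10%, 20%, 30%).
#' @return scalar threshold; the per-candidate tally is attached as
#'   `attr(, "tally")`.
#' @export
select_image_threshold <- function(val_results,
                                   candidates = c(.01, .05, .10, .20, .30)) {
  stopifnot(length(candidates) > 0, "truth" %in% names(val_results))
  ok <- !is.na(val_results$fraction)
  frac <- val_results$fraction[ok]
  pos <- as_positive(val_results$truth[ok])
  tally <- tibble(
    threshold = candidates,
    n_correct = vapply(candidates, function(th)
      sum((frac >= th) == pos), integer(1)))
  best <- tally$threshold[order(-tally$n_correct, tally$threshold)][1]
  attr(best, "tally") <- tally
  best
}

#' Summarise image-wise performance
#'
#' @param results tibble of [classify_image()] rows.
#' @param truth vector of true image labels aligned with `results`.
#' @return one-row tibble with confusion counts and metrics
#'   (indeterminate images are excluded and counted separately).
#' @export
imagewise_metrics <- function(results, truth) {
  det <- results$decision != "indeterminate"
  cc <- confusion_counts(results$decision[det] == "cancerous",
                         as_positive(truth[det]))
  met <- compute_metrics(cc)
  met %>% mutate(n_images = nrow(results),
                 n_indeterminate = sum(!det),
                 tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn)
}

#' Plot an ROC curve with its AUC
#' @param scores numeric scores.
#' @param truths truth labels.
#' @return a ggplot object.
#' @export
plot_roc <- function(scores, truths) {
  pos <- as_positive(truths)
  o <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(pos[o]) / sum(pos))
  fpr <- c(0, cumsum(!pos[o]) / sum(!pos))
  ggplot2::ggplot(tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", roc_auc(scores, truths))) +
    ggplot2::theme_minimal()
}
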