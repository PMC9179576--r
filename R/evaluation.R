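#' Patient-level aggregation of image scores
#'
#' A patient's grading judgment is the maximum of their per-image
#' high-grade probabilities — the reading focuses on the most severe
#' looking slice.
#'
#' @param image_scores non-empty numeric vector of probabilities in
#'   `[0, 1]`.
#' @return the maximum score.
#' @export
aggregate_patient <- function(image_scores) {
  if (length(image_scores) == 0L) stop_rcc("no image scores to aggregate")
  if (any(image_scores < 0 | image_scores > 1))
    stop_rcc("image scores must lie in [0, 1]")
  max(image_scores)
}

#' Score a cohort with a trained grading model
#'
#' Runs the model on every image of every patient and aggregates the
#' per-image high-grade probabilities with [aggregate_patient()].
#'
#' @param model trained 2-output `rcc_model`.
#' @param cohort an `rcc_cohort`; every patient needs at least one image.
#' @param target_edge uniform size fed to the backbone; defaults to the
#'   backbone's `input_edge`.
#' @return an `rcc_predictions` data.frame with columns `patient_id`,
#'   `score` (aggregated G), `label` (true binary label); the per-image
#'   scores (in each patient's image order) are kept in the
#'   `image_scores` attribute.
#' @export
score_cohort <- function(model, cohort, target_edge = NULL) {
  if (n_patients(cohort) == 0L) stop_rcc("cohort is empty")
  target_edge <- target_edge %||% model$spec$backbone$input_edge
  data <- cohort_to_arrays(cohort, target_edge)
  probs <- model_probs(model, data$x)[, 2]
  per_patient <- split(probs, data$patient_index)
  ids <- vapply(cohort$patients, function(p) p$patient_id, character(1))
  out <- data.frame(
    patient_id = ids,
    score = vapply(per_patient, aggregate_patient, numeric(1)),
    label = cohort_labels(cohort),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "image_scores") <- unname(per_patient)
  class(out) <- c("rcc_predictions", "data.frame")
  out
}

#' Build a predictions table from scores and labels
#'
#' Convenience constructor for evaluation and ensembling when the scores
#' do not come from [score_cohort()].
#'
#' @param patient_id character ids.
#' @param score aggregated patient scores in `[0, 1]`.
#' @param label true binary labels in `{0, 1}`.
#' @return an `rcc_predictions` data.frame.
#' @export
patient_predictions <- function(patient_id, score, label) {
  stopifnot(length(patient_id) == length(score),
            length(score) == length(label))
  out <- data.frame(patient_id = as.character(patient_id),
                    score = as.numeric(score), label = as.integer(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("rcc_predictions", "data.frame")
  out
}

#' Thresholded classification metrics
#'
#' Positive class = high grade. A patient is called positive when their
#' aggregated score is `>= threshold`. Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/total, all reported as
#' percentages rounded half-up to one decimal.
#'
#' @param predictions an `rcc_predictions` table with both classes
#'   present.
#' @param threshold decision threshold on the aggregated score
#'   (default 0.5).
#' @return list with `acc`, `sen`, `spc` (percentages), `threshold`, and
#'   the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
classification_metrics <- function(predictions, threshold = 0.5) {
  lab <- predictions$label
  if (length(unique(lab)) < 2L)
    stop_rcc("both classes must be present to compute sen and spc")
  pred <- as.integer(predictions$score >= threshold)
  tp <- sum(pred == 1L & lab == 1L); fn <- sum(pred == 0L & lab == 1L)
  tn <- sum(pred == 0L & lab == 0L); fp <- sum(pred == 1L & lab == 0L)
  list(acc = round_half_up(100 * (tp + tn) / length(lab), 1),
       sen = round_half_up(100 * tp / (tp + fn), 1),
       spc = round_half_up(100 * tn / (tn + fp), 1),
       threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve and AUC
#'
#' The ROC curve is traced over all distinct score thresholds (descending)
#' and the AUC computed by the trapezoid rule, which equals the
#' Mann–Whitney probability that a random high-grade patient outscores a
#' random low-grade one, with ties credited 1/2.
#'
#' @param predictions an `rcc_predictions` table with both classes
#'   present.
#' @return list with `auc` (fraction in `[0, 1]`) and `roc_points`, a
#'   data.frame of (`fpr`, `tpr`) from (0, 0) to (1, 1), both coordinates
#'   non-decreasing.
#' @export
roc_auc <- function(predictions) {
  lab <- predictions$label
  score <- predictions$score
  if (length(unique(lab)) < 2L)
    stop_rcc("both classes must be present to compute the ROC curve")
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  ord <- order(score, decreasing = TRUE)
  lab_s <- lab[ord]; score_s <- score[ord]
  # collapse tied scores so tied positives/negatives advance diagonally
  last_of_run <- c(score_s[-1] != score_s[-length(score_s)], TRUE)
  tp <- cumsum(lab_s == 1L)[last_of_run]
  fp <- cumsum(lab_s == 0L)[last_of_run]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(auc = auc, roc_points = roc)
}

#' Full evaluation of patient predictions
#'
#' @param predictions an `rcc_predictions` table.
#' @param threshold decision threshold for acc/sen/spc; `"youden"` picks
#'   the threshold maximising tpr - fpr on these predictions.
#' @return an `rcc_eval` list: `acc`, `sen`, `spc` (percentages), `auc`
#'   (fraction), `roc_points`, `threshold`.
#' @export
evaluate_predictions <- function(predictions, threshold = 0.5) {
  roc <- roc_auc(predictions)
  if (identical(threshold, "youden"))
    threshold <- youden_threshold(predictions)
  cm <- classification_metrics(predictions, threshold)
  structure(c(cm[c("acc", "sen", "spc")],
              list(auc = roc$auc, roc_points = roc$roc_points,
                   threshold = threshold)),
            class = "rcc_eval")
}

#' @export
print.rcc_eval <- function(x, ...) {
  cat(sprintf("ACC %.1f%%  SEN %.1f%%  SPC %.1f%%  AUC %.3f (thr %.3f)\n",
              x$acc, x$sen, x$spc, x$auc, x$threshold))
  invisible(x)
}

#' @rdname evaluate_predictions
#' @export
youden_threshold <- function(predictions) {
  scores <- sort(unique(predictions$score))
  j <- vapply(scores, function(thr) {
    pred <- predictions$score >= thr
    tpr <- sum(pred & predictions$label == 1L) / sum(predictions$label == 1L)
    fpr <- sum(pred & predictions$label == 0L) / sum(predictions$label == 0L)
    tpr - fpr
  }, numeric(1))
  scores[which.max(j)]
}
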