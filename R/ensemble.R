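#' Decile-stripped ensemble weights from model AUCs
#'
#' When all models' AUCs share the same first decimal digit (the decile),
#' each model's ensemble weight is its AUC with that digit removed
#' (0.864 -> 0.064) — a rule that amplifies the relative differences
#' between closely performing models. When the deciles differ, the rule is
#' extended continuously by subtracting the *smallest* decile from every
#' AUC, which preserves the ordering; pass the raw AUCs as weights
#' yourself if you prefer to bypass the rule.
#'
#' @param aucs numeric vector of per-model AUCs, all in (0, 1).
#' @return positive weights, same length and order as `aucs`.
#' @export
decile_stripped_weights <- function(aucs) {
  if (any(aucs <= 0 | aucs >= 1)) stop_rcc("AUCs must lie strictly in (0, 1)")
  deciles <- floor(10 * aucs) / 10
  w <- aucs - min(deciles)
  if (any(w <= 0))
    stop_rcc("stripped weights must be positive; an AUC sits exactly on ",
             "its decile boundary — use raw AUCs as weights instead")
  w
}

#' Weighted ensemble of per-patient scores
#'
#' The composite prediction is the weight-normalised combination
#' \eqn{F_i = \sum_k \gamma_k G_{ik} / \sum_k \gamma_k}; it is invariant
#' to rescaling all weights and always lies between the smallest and
#' largest input score.
#'
#' @param scores numeric vector: one patient's aggregated score under each
#'   of K models.
#' @param weights positive weights, length K.
#' @return the combined score.
#' @export
ensemble_patient <- function(scores, weights) {
  if (length(scores) != length(weights))
    stop_rcc("scores and weights must have equal length")
  if (any(weights <= 0)) stop_rcc("weights must be positive")
  sum(weights * scores) / sum(weights)
}

#' Combine per-model cohort predictions into ensemble predictions
#'
#' Aligns the K prediction tables by `patient_id` (order differences are
#' resolved; a patient missing from any table is an error) and combines
#' each patient's K scores with [ensemble_patient()].
#'
#' @param per_model_predictions list of K `rcc_predictions` tables over
#'   the same patients.
#' @param weights positive weights, length K (e.g. from
#'   [decile_stripped_weights()]).
#' @return an `rcc_predictions` table in the first table's patient order.
#' @export
ensemble_cohort <- function(per_model_predictions, weights) {
  K <- length(per_model_predictions)
  if (K != length(weights))
    stop_rcc("need one weight per model")
  ref <- per_model_predictions[[1]]
  score_mat <- matrix(NA_real_, nrow(ref), K)
  score_mat[, 1] <- ref$score
  for (k in seq_len(K)[-1]) {
    tab <- per_model_predictions[[k]]
    pos <- match(ref$patient_id, tab$patient_id)
    if (anyNA(pos))
      stop_rcc("patient ", ref$patient_id[which(is.na(pos))[1]],
               " missing from model ", k, "'s predictions")
    extra <- setdiff(tab$patient_id, ref$patient_id)
    if (length(extra))
      stop_rcc("patient ", extra[1], " present in model ", k,
               "'s predictions but not in model 1's")
    score_mat[, k] <- tab$score[pos]
  }
  combined <- apply(score_mat, 1, ensemble_patient, weights = weights)
  patient_predictions(ref$patient_id, combined, ref$label)
}
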