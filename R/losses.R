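#' Bundle network output probabilities with labels
#'
#' @param probs N x 2 matrix; row i holds the output probabilities that
#'   sample i is low grade (column 1) / high grade (column 2). Rows must
#'   sum to 1 within 1e-6.
#' @param labels length-N vector of observed labels in `{0, 1}`.
#' @param validate check invariants (disable only inside tested internals).
#' @return an object of class `rcc_batch`.
#' @export
batch_prediction <- function(probs, labels, validate = TRUE) {
  probs <- as.matrix(probs)
  if (validate) {
    if (ncol(probs) != 2L) stop_rcc("probs must have two columns")
    if (nrow(probs) == 0L) stop_rcc("batch is empty")
    if (length(labels) != nrow(probs))
      stop_rcc("labels length must match probs rows")
    if (!all(labels %in% c(0, 1))) stop_rcc("labels must be 0 or 1")
    if (any(abs(rowSums(probs) - 1) > 1e-6))
      stop_rcc("probability rows must sum to 1 (within 1e-6)")
  }
  structure(list(probs = probs, labels = as.integer(labels)),
            class = "rcc_batch")
}

#' Loss configuration
#'
#' Parameters of the mixed / reweighted cross-entropy family. `alpha` is
#' the assumed one-directional label-noise rate (default 0.4, the value
#' found to work best in the reference study); `lambda0` / `lambda1` weigh
#' the low- and high-grade class contributions.
#'
#' Two escape hatches cover readings of the objective that the source
#' leaves ambiguous: `mixing = "as_printed"` weights plain cross-entropy
#' by `alpha` and the noise term by `1 - alpha` (the printed equation);
#' `"complement"` swaps the two. `noise_term = "class0"` restricts the
#' noise term to samples labelled low grade (the printed equation);
#' `"flip_to_low"` applies `-log p_i0` to every sample, i.e. learning from
#' data with all labels flipped to low.
#'
#' @param alpha noise rate in `[0, 1]`.
#' @param lambda0,lambda1 positive class weights.
#' @param epsilon probability clamp applied before `log`.
#' @param mixing `"as_printed"` or `"complement"`.
#' @param noise_term `"class0"` or `"flip_to_low"`.
#' @return an object of class `rcc_loss_config`.
#' @export
loss_config <- function(alpha = 0.4, lambda0 = 1, lambda1 = 1,
                        epsilon = 1e-12,
                        mixing = c("as_printed", "complement"),
                        noise_term = c("class0", "flip_to_low")) {
  if (alpha < 0 || alpha > 1) stop_rcc("alpha must be in [0, 1]")
  if (lambda0 <= 0 || lambda1 <= 0) stop_rcc("class weights must be positive")
  structure(list(alpha = alpha, lambda0 = lambda0, lambda1 = lambda1,
                 epsilon = epsilon, mixing = match.arg(mixing),
                 noise_term = match.arg(noise_term)),
            class = "rcc_loss_config")
}

clamp_log <- function(p, epsilon) log(pmax(p, epsilon))

#' Cross-entropy loss family
#'
#' `ce_loss` is the ordinary cross-entropy
#' \eqn{-\frac{1}{N}\sum_i \sum_j l_{ij} \log p_{ij}} with one-hot
#' \eqn{l_{ij} = 1[y_i = j]}.
#'
#' `ce_class0_loss` is the noise-countering term
#' \eqn{-\frac{1}{N}\sum_i l_{i0} \log p_{i0}}: only samples labelled low
#' grade contribute, but the divisor stays N (all samples).
#'
#' `mixed_loss` combines the two as
#' \eqn{\alpha L_{CE} + (1-\alpha) L_{CE2}} (under the default
#' `as_printed` mixing), treating high-labelled samples as possibly
#' mislabelled low-grade ones.
#'
#' `weighted_ce_loss` multiplies each sample's contribution by its class
#' weight \eqn{\lambda_{y_i}}; `total_weighted_loss` is the overall
#' objective combining reweighting and the noise term:
#' \eqn{-\alpha\frac{1}{N}\sum_i\sum_j \lambda_j l_{ij}\log p_{ij}
#'      -(1-\alpha)\frac{1}{N}\sum_i \lambda_0 l_{i0}\log p_{i0}}.
#'
#' @param batch an [batch_prediction()].
#' @param config an [loss_config()].
#' @param epsilon probability clamp for the unparameterised losses.
#' @return non-negative scalar.
#' @name losses
NULL

#' @rdname losses
#' @export
ce_loss <- function(batch, epsilon = 1e-12) {
  n <- nrow(batch$probs)
  if (n == 0L) stop_rcc("batch is empty")
  p_true <- batch$probs[cbind(seq_len(n), batch$labels + 1L)]
  -mean(clamp_log(p_true, epsilon))
}

#' @rdname losses
#' @export
ce_class0_loss <- function(batch, epsilon = 1e-12) {
  n <- nrow(batch$probs)
  if (n == 0L) stop_rcc("batch is empty")
  -sum((batch$labels == 0L) * clamp_log(batch$probs[, 1], epsilon)) / n
}

flip_to_low_loss <- function(batch, epsilon = 1e-12) {
  -mean(clamp_log(batch$probs[, 1], epsilon))
}

noise_loss <- function(batch, config) {
  switch(config$noise_term,
         class0 = ce_class0_loss(batch, config$epsilon),
         flip_to_low = flip_to_low_loss(batch, config$epsilon))
}

mixing_coefs <- function(config) {
  if (config$mixing == "as_printed") c(config$alpha, 1 - config$alpha)
  else c(1 - config$alpha, config$alpha)
}

#' @rdname losses
#' @export
mixed_loss <- function(batch, config) {
  co <- mixing_coefs(config)
  co[1] * ce_loss(batch, config$epsilon) + co[2] * noise_loss(batch, config)
}

#' @rdname losses
#' @export
weighted_ce_loss <- function(batch, config) {
  n <- nrow(batch$probs)
  if (n == 0L) stop_rcc("batch is empty")
  lam <- ifelse(batch$labels == 0L, config$lambda0, config$lambda1)
  p_true <- batch$probs[cbind(seq_len(n), batch$labels + 1L)]
  -sum(lam * clamp_log(p_true, config$epsilon)) / n
}

#' @rdname losses
#' @export
total_weighted_loss <- function(batch, config) {
  co <- mixing_coefs(config)
  co[1] * weighted_ce_loss(batch, config) +
    co[2] * config$lambda0 * noise_loss(batch, config)
}

#' Derive class weights from class counts
#'
#' `inverse_frequency` is the textbook rule
#' \eqn{\lambda_j = (n_0 + n_1) / (2 n_j)}: the rarer class contributes
#' more. `noise_adjusted` additionally accounts for the mixed loss's extra
#' low-grade term: it balances the *expected* per-class contribution to
#' the overall objective by solving
#' \eqn{\lambda_0 n_{low} = \alpha \lambda_1 n_{high}} under the
#' normalisation \eqn{\lambda_0 + \lambda_1 = 2}.
#'
#' @param n_low,n_high positive class counts (images or patients).
#' @param scheme `"inverse_frequency"` or `"noise_adjusted"`.
#' @param alpha noise rate used by the `noise_adjusted` scheme.
#' @return named numeric vector `c(lambda0 = , lambda1 = )`.
#' @export
class_weights_from_counts <- function(n_low, n_high,
                                      scheme = c("inverse_frequency",
                                                 "noise_adjusted"),
                                      alpha = 0.4) {
  scheme <- match.arg(scheme)
  if (n_low <= 0 || n_high <= 0) stop_rcc("class counts must be positive")
  if (scheme == "inverse_frequency") {
    n <- n_low + n_high
    c(lambda0 = n / (2 * n_low), lambda1 = n / (2 * n_high))
  } else {
    if (alpha <= 0) stop_rcc("noise_adjusted weights need alpha > 0")
    lambda0 <- 2 * alpha * n_high / (n_low + alpha * n_high)
    lambda1 <- 2 * n_low / (n_low + alpha * n_high)
    c(lambda0 = lambda0, lambda1 = lambda1)
  }
}

# gradient of total_weighted_loss w.r.t. the logits of a 2-class softmax;
# used by the trainer. probs = softmax(logits) row-wise.
grad_total_weighted_logits <- function(probs, labels, config) {
  n <- nrow(probs)
  co <- mixing_coefs(config)
  lam <- ifelse(labels == 0L, config$lambda0, config$lambda1)
  onehot <- cbind(1 - labels, labels)
  g <- co[1] * lam * (probs - onehot)
  mask <- if (config$noise_term == "class0") as.numeric(labels == 0L) else 1
  e0 <- cbind(rep(1, n), rep(0, n))
  g <- g + co[2] * config$lambda0 * mask * (probs - e0)
  g / n
}

# plain multiclass cross-entropy gradient w.r.t. logits (pretext head)
grad_ce_logits <- function(probs, labels_onebased) {
  n <- nrow(probs)
  onehot <- matrix(0, n, ncol(probs))
  onehot[cbind(seq_len(n), labels_onebased)] <- 1
  (probs - onehot) / n
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
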