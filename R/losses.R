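# Composite loss: cross-entropy for the class head, MSE for the severity
# head, combined as L_total = L_class + lambda * L_severity.

#' Cross-entropy classification loss
#'
#' `-log(probs[true_class + 1])`.  Zero iff the true class is predicted with
#' probability one.  A zero probability is clamped at `floor_prob` (default
#' 1e-12, i.e. the loss saturates at `-log(1e-12)`) rather than returning
#' infinity.
#'
#' @param probs Probability vector (non-negative, sums to 1).
#' @param true_class True class index, 0-based.
#' @param floor_prob Clamp for zero predicted probability.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, true_class, floor_prob = 1e-12) {
  if (any(probs < -1e-9) || abs(sum(probs) - 1) > 1e-6)
    stop_invalid("probs must be a probability distribution")
  if (true_class < 0L || true_class >= length(probs))
    stop_invalid("true_class out of range")
  -log(max(probs[true_class + 1L], floor_prob))
}

#' Mean squared error severity loss
#'
#' @param predicted,actual Equal-length numeric vectors of severity scores.
#' @return Mean of squared residuals.
#' @export
severity_mse_loss <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual))
    stop_invalid("predicted and actual must be non-empty and equal length")
  mean((predicted - actual)^2)
}

#' Combine classification and severity losses
#'
#' @param loss_class Non-negative classification loss.
#' @param loss_severity Non-negative severity loss.
#' @param lambda Weight on the severity term (>= 0); `lambda = 0` reduces the
#'   total to the classification loss alone, 0.5 is the balanced default.
#' @return List (class `loss_bundle`) with `loss_class`, `loss_severity`,
#'   `lambda` and `loss_total = loss_class + lambda * loss_severity`.
#' @export
composite_loss <- function(loss_class, loss_severity, lambda = 0.5) {
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  structure(list(loss_class = loss_class, loss_severity = loss_severity,
                 lambda = lambda,
                 loss_total = loss_class + lambda * loss_severity),
            class = "loss_bundle")
}
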