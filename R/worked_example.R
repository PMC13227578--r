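# Reference worked example for the dual output heads, with small fixed
# parameters chosen so the arithmetic can be followed by hand.

#' Dual-head worked example
#'
#' Runs both output heads on a fixed pooled feature vector
#' `x = (2.0, -1.5, 0.5)` with small hand-checkable parameters: a 3x3
#' classification weight matrix with bias `(0.1, -0.2, 0.3)` giving logits
#' `(0.75, -1.80, 1.70)` and probabilities `(0.273, 0.021, 0.706)` after
#' softmax, and a severity weight vector `(0.4, -0.5, 0.6)` with bias 0.2
#' giving the score 2.05.
#'
#' @param quiet Suppress the printed walk-through.
#' @return List with `features`, `W_class`, `b_class`, `logits`,
#'   `class_probs`, `w_severity`, `b_severity`, `severity`.
#' @export
worked_example <- function(quiet = FALSE) {
  x <- c(2.0, -1.5, 0.5)
  W_class <- rbind(c(0.1, -0.2, 0.3),
                   c(-0.5, 0.4, 0.0),
                   c(0.2, -0.6, 0.2))
  b_class <- c(0.1, -0.2, 0.3)
  w_severity <- c(0.4, -0.5, 0.6)
  b_severity <- 0.2
  logits <- as.vector(W_class %*% x) + b_class
  probs <- classification_head(x, W_class, b_class)
  sev <- severity_head(x, w_severity, b_severity)
  if (!quiet) {
    cat("Pooled transformer output x =", sprintf("[%s]", paste(x, collapse = ", ")), "\n")
    cat("Logits  W_class x + b_class =",
        sprintf("[%s]", paste(format(logits), collapse = ", ")), "\n")
    cat("Class probabilities softmax =",
        sprintf("[%s]", paste(sprintf("%.3f", probs), collapse = ", ")), "\n")
    cat("Severity  w . x + b        =", sprintf("%.2f", sev), "\n")
  }
  invisible(list(features = x, W_class = W_class, b_class = b_class,
                 logits = logits, class_probs = probs,
                 w_severity = w_severity, b_severity = b_severity,
                 severity = sev))
}
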