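# Classification report with Cohen's kappa, regression errors, residual
# densities, confidence intervals, Cohen's d, percent change and the
# augmentation A/B comparison table.

#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length vectors of 0-based class indices.
#' @param n_classes Number of classes C (defaults to `max(index) + 1`).
#' @return C x C integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop_invalid("y_true and y_pred must be non-empty and equal length")
  C <- n_classes %||% (max(c(y_true, y_pred)) + 1L)
  cm <- matrix(0L, C, C,
               dimnames = list(true = 0:(C - 1L), pred = 0:(C - 1L)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

#' Classification report
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (their
#' harmonic mean), support-weighted and macro averages, accuracy, and
#' Cohen's kappa `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' taken from the product of the marginals.  A class that is never predicted
#' gets precision 0 and is flagged rather than raising an error.
#'
#' @param y_true,y_pred Equal-length vectors of 0-based class indices.
#' @param n_classes Number of classes (defaults to `max(index) + 1`).
#' @return List (class `classification_report`): `confusion`, `per_class`
#'   data.frame, `accuracy`, `macro`, `weighted`, `kappa`,
#'   `zero_predicted_classes`.
#' @export
classification_report <- function(y_true, y_pred, n_classes = NULL) {
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  C <- nrow(cm)
  n <- sum(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / n
  p_o <- sum(tp) / n
  p_e <- sum(support * predicted) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  structure(list(
    confusion = cm,
    per_class = data.frame(class = 0:(C - 1L), precision = precision,
                           recall = recall, f1 = f1, support = support,
                           row.names = NULL),
    accuracy = p_o,
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    weighted = list(precision = sum(w * precision), recall = sum(w * recall),
                    f1 = sum(w * f1)),
    kappa = kappa,
    zero_predicted_classes = unname(which(predicted == 0)) - 1L
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  df <- x$per_class
  df$precision <- round2(df$precision, digits)
  df$recall <- round2(df$recall, digits)
  df$f1 <- round2(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy %.2f | weighted P/R/F1 %.2f/%.2f/%.2f | macro P %.2f | kappa %.2f\n",
              x$accuracy, x$weighted$precision, x$weighted$recall,
              x$weighted$f1, x$macro$precision, x$kappa))
  invisible(x)
}

#' Severity regression errors
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @return Named vector `c(mae = ..., rmse = ...)`; RMSE >= MAE always, with
#'   equality iff all absolute residuals are equal.
#' @export
regression_metrics <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual))
    stop_invalid("predicted and actual must be non-empty and equal length")
  r <- predicted - actual
  c(mae = mean(abs(r)), rmse = sqrt(mean(r^2)))
}

#' Residual density comparison
#'
#' Kernel density estimates of two residual samples (typically before and
#' after augmentation) over a shared grid, with spread summaries.  Whether
#' the second sample is narrower is reported as a finding, never assumed.
#'
#' @param before,after Non-empty numeric residual vectors.
#' @param n_grid Number of grid points.
#' @return List with `grid`, `before_density`, `after_density`, `summary`
#'   (data.frame of sd and IQR per sample) and `after_narrower` (logical,
#'   by sd).
#' @export
residual_density <- function(before, after, n_grid = 512L) {
  if (length(before) == 0L || length(after) == 0L)
    stop_invalid("both residual samples must be non-empty")
  rng <- range(c(before, after))
  pad <- diff(rng) * 0.2 + 1e-9
  from <- rng[1] - pad; to <- rng[2] + pad
  db <- stats::density(before, from = from, to = to, n = n_grid)
  da <- stats::density(after, from = from, to = to, n = n_grid)
  summ <- data.frame(sample = c("before", "after"),
                     sd = c(stats::sd(before), stats::sd(after)),
                     iqr = c(stats::IQR(before), stats::IQR(after)))
  list(grid = db$x, before_density = db$y, after_density = da$y,
       summary = summ, after_narrower = summ$sd[2] < summ$sd[1])
}

#' Normal-approximation confidence interval
#'
#' `mean +/- z * sd / sqrt(n)` with `z = qnorm((1 + level) / 2)`.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @param n Number of observations (>= 2).
#' @param level Confidence level in (0, 1).
#' @return Named vector `c(lower = ..., upper = ...)`.
#' @export
confidence_interval <- function(mean, sd, n, level = 0.95) {
  if (sd < 0) stop_invalid("sd must be >= 0")
  if (n < 2) stop_invalid("n must be >= 2")
  if (level <= 0 || level >= 1) stop_invalid("level must lie in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean2 - mean1) / s` where the
#' standardizer `s` is either the mean of the two SDs (`"mean_sd"`, the
#' default) or the root-mean-square pooled SD (`"pooled"`,
#' `sqrt((sd1^2 + sd2^2) / 2)`).
#'
#' @param mean1,sd1 First condition.
#' @param mean2,sd2 Second condition.
#' @param method `"mean_sd"` or `"pooled"`.
#' @return Numeric effect size.
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2,
                     method = c("mean_sd", "pooled")) {
  method <- match.arg(method)
  if (sd1 < 0 || sd2 < 0) stop_invalid("standard deviations must be >= 0")
  s <- if (method == "pooled") sqrt((sd1^2 + sd2^2) / 2) else (sd1 + sd2) / 2
  if (s == 0) stop_degenerate("zero standardizer: both SDs are 0")
  (mean2 - mean1) / s
}

#' Percent change
#'
#' `100 * (after - before) / before`; vectorized over `after`.  A zero
#' baseline yields `NA` with a warning rather than an error.
#'
#' @param before Baseline value (non-zero).
#' @param after New value(s).
#' @return Percent change(s).
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) {
    warning("percent change undefined for zero baseline; returning NA")
    return(ifelse(before == 0, NA_real_, 100 * (after - before) / before))
  }
  100 * (after - before) / before
}

#' Augmentation A/B comparison report
#'
#' Builds the original-vs-augmented comparison table for matched metric sets
#' from two training runs, with percent change per metric, and optionally a
#' confidence interval and Cohen's d per metric when per-run SDs and the
#' number of repeats are supplied.
#'
#' @param original,augmented Named numeric vectors (or named lists) with
#'   identical metric names.
#' @param sd_original,sd_augmented Optional matched named vectors of SDs
#'   across repeated runs.
#' @param n_runs Number of repeated runs behind each mean (for intervals).
#' @param level Confidence level.
#' @param d_method Cohen's d standardizer, see [cohens_d()].
#' @return `data.frame` with columns `metric`, `original`, `augmented`,
#'   `change_pct` and, when SDs are given, `cohens_d`, `ci_*`.
#' @export
augmentation_ab_report <- function(original, augmented,
                                   sd_original = NULL, sd_augmented = NULL,
                                   n_runs = NULL, level = 0.95,
                                   d_method = "mean_sd") {
  original <- unlist(original); augmented <- unlist(augmented)
  if (is.null(names(original)) || !identical(sort(names(original)),
                                             sort(names(augmented))))
    stop_invalid("original and augmented must share the same metric names")
  augmented <- augmented[names(original)]
  out <- data.frame(metric = names(original),
                    original = as.numeric(original),
                    augmented = as.numeric(augmented), row.names = NULL)
  out$change_pct <- round2(
    suppressWarnings(100 * (out$augmented - out$original) /
                       ifelse(out$original == 0, NA, out$original)), 2)
  if (!is.null(sd_original) && !is.null(sd_augmented)) {
    sd_original <- unlist(sd_original)[names(original)]
    sd_augmented <- unlist(sd_augmented)[names(original)]
    out$cohens_d <- round2(mapply(function(m1, s1, m2, s2) {
      if (s1 == 0 && s2 == 0) NA_real_
      else cohens_d(m1, s1, m2, s2, method = d_method)
    }, out$original, sd_original, out$augmented, sd_augmented), 2)
    if (!is.null(n_runs)) {
      ci_o <- mapply(function(m, s) confidence_interval(m, s, n_runs, level),
                     out$original, sd_original)
      ci_a <- mapply(function(m, s) confidence_interval(m, s, n_runs, level),
                     out$augmented, sd_augmented)
      out$ci_original_lower <- ci_o["lower", ]
      out$ci_original_upper <- ci_o["upper", ]
      out$ci_augmented_lower <- ci_a["lower", ]
      out$ci_augmented_upper <- ci_a["upper", ]
    }
  }
  out
}
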