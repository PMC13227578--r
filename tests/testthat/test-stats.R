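# Classification report, kappa, regression errors, densities, intervals,
# effect sizes, percent change and the A/B comparison.

# Truth/prediction pair realizing the confusion matrix
# [[3,0,0],[1,2,0],[0,0,4]] (sole error: one class-1 sample predicted 0).
ten_sample_case <- function() {
  list(y_true = c(0, 0, 0, 1, 1, 1, 2, 2, 2, 2),
       y_pred = c(0, 0, 0, 0, 1, 1, 2, 2, 2, 2))
}

test_that("the 10-sample report reproduces the reference metric values", {
  tc <- ten_sample_case()
  rep <- classification_report(tc$y_true, tc$y_pred)
  expect_identical(unname(rep$confusion),
                   matrix(c(3L, 1L, 0L, 0L, 2L, 0L, 0L, 0L, 4L), 3))
  expect_equal(rep$accuracy, 0.90)
  expect_equal(round(rep$per_class$f1[1], 2), 0.86)
  expect_equal(round(rep$weighted$f1, 2), 0.90)
  # weighted precision is exactly 0.925 (displayed as 0.93 under half-up
  # table rounding)
  expect_equal(rep$weighted$precision, 0.925, tolerance = 1e-12)
  expect_equal(round(rep$macro$precision, 2), 0.92)
  expect_identical(rep$per_class$support, c(3, 3, 4))
  # standard kappa on this matrix (p_o = 0.9, p_e = 0.34)
  expect_equal(rep$kappa, (0.9 - 0.34) / (1 - 0.34), tolerance = 1e-12)
  expect_equal(round(rep$kappa, 2), 0.85)
})

test_that("perfect and degenerate predictions hit the kappa boundary cases", {
  y <- c(0, 1, 2, 0, 1, 2)
  perfect <- classification_report(y, y)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  # constant prediction on balanced binary truth: agreement equals chance
  const <- classification_report(c(0, 0, 1, 1), c(0, 0, 0, 0))
  expect_equal(const$kappa, 0)
  expect_identical(const$zero_predicted_classes, 1L)
  expect_equal(const$per_class$precision[2], 0)
})

test_that("kappa and per-class rates match brute-force counting on random draws", {
  set.seed(77)
  for (k in 1:50) {
    n <- sample(10:60, 1); C <- sample(2:5, 1)
    y_true <- sample(0:(C - 1), n, replace = TRUE)
    y_pred <- sample(0:(C - 1), n, replace = TRUE)
    rep <- classification_report(y_true, y_pred, C)
    oracle <- counting_oracle(y_true, y_pred, C)
    expect_equal(rep$per_class$precision, oracle$precision)
    expect_equal(rep$per_class$recall, oracle$recall)
    p_o <- mean(y_true == y_pred)
    p_e <- 0
    for (cl in 0:(C - 1))
      p_e <- p_e + mean(y_true == cl) * mean(y_pred == cl)
    expect_equal(rep$kappa, (p_o - p_e) / (1 - p_e), tolerance = 1e-12)
    # weighted recall is accuracy, algebraically, for every matrix
    expect_equal(rep$weighted$recall, rep$accuracy, tolerance = 1e-12)
  }
})

test_that("report agrees with the counting oracle on many larger draws", {
  set.seed(99)
  for (k in 1:1000) {
    y_true <- sample(0:3, 50, replace = TRUE)
    y_pred <- sample(0:3, 50, replace = TRUE)
    rep <- classification_report(y_true, y_pred, 4)
    oracle <- counting_oracle(y_true, y_pred, 4)
    if (!isTRUE(all.equal(rep$per_class$precision, oracle$precision)) ||
        !isTRUE(all.equal(rep$per_class$recall, oracle$recall)))
      fail(sprintf("mismatch at draw %d", k))
  }
  succeed()
})

test_that("regression metrics obey MAE/RMSE algebra", {
  expect_equal(regression_metrics(c(1, 2), c(1, 2)), c(mae = 0, rmse = 0))
  expect_equal(regression_metrics(c(1, 0), c(0, 1)), c(mae = 1, rmse = 1))
  expect_equal(regression_metrics(c(0, 2), c(0, 0)),
               c(mae = 1, rmse = sqrt(2)))
  set.seed(13)
  for (k in 1:20) {
    p <- rnorm(30); a <- rnorm(30)
    m <- regression_metrics(p, a)
    expect_gte(m[["rmse"]], m[["mae"]])
  }
  # equality iff all absolute residuals are equal
  eq <- regression_metrics(c(2, -2, 2), c(0, 0, 0))
  expect_equal(eq[["rmse"]], eq[["mae"]])
  expect_error(regression_metrics(numeric(0), numeric(0)), "non-empty")
})

test_that("residual densities share a grid and summarize spread honestly", {
  set.seed(6)
  x <- rnorm(500)
  same <- residual_density(x, x)
  expect_equal(same$before_density, same$after_density)
  expect_equal(same$summary$sd[1], same$summary$sd[2])
  expect_false(same$after_narrower)
  halved <- residual_density(x, x / 2)
  expect_equal(halved$summary$sd[2], halved$summary$sd[1] / 2)
  expect_true(halved$after_narrower)
  # the KDE is a density: trapezoid quadrature integrates to ~1
  big <- residual_density(rnorm(1e4), rnorm(1e4))
  dx <- diff(big$grid[1:2])
  expect_equal(sum(big$before_density) * dx, 1, tolerance = 1e-2)
})

test_that("confidence intervals take the normal form", {
  expect_equal(confidence_interval(5, 0, 10), c(lower = 5, upper = 5))
  ci <- confidence_interval(0, 1, 100, 0.95)
  expect_equal(ci[["upper"]], 1.959964 / 10, tolerance = 1e-5)
  expect_equal(ci[["lower"]], -ci[["upper"]])
  # width scales as 1 / sqrt(n)
  w1 <- diff(confidence_interval(0, 2, 50))
  w2 <- diff(confidence_interval(0, 2, 200))
  expect_equal(unname(w1 / w2), 2, tolerance = 1e-12)
  expect_error(confidence_interval(0, 1, 1), "n")
  expect_error(confidence_interval(0, 1, 10, 1.5), "level")
})

test_that("Cohen's d supports both standardizers with the documented values", {
  expect_equal(cohens_d(3, 1, 3, 2), 0)
  expect_equal(cohens_d(3, 1, 3, 2, method = "pooled"), 0)
  expect_equal(round(cohens_d(87.6, 1.1, 90.8, 0.8, method = "mean_sd"), 2),
               3.37)
  expect_equal(round(cohens_d(87.6, 1.1, 90.8, 0.8, method = "pooled"), 2),
               3.33)
  expect_error(cohens_d(1, 0, 2, 0), "zero")
})

test_that("percent change matches the printed-table arithmetic", {
  expect_equal(round(percent_change(87.6, 90.8), 2), 3.65)
  expect_equal(round(percent_change(1.1, 0.8), 1), -27.3)
  expect_equal(percent_change(85.2, 93.1), 9.2723, tolerance = 1e-4)
  expect_equal(round(percent_change(91.6, 78.2), 2), -14.63)
  expect_equal(percent_change(4, 4), 0)
  expect_warning(pc0 <- percent_change(0, 1), "zero baseline")
  expect_true(is.na(pc0))
})

test_that("A/B report recomputes its own deltas and effect sizes", {
  orig <- c(accuracy = 0.88, precision = 0.85, mae = 0.22)
  aug <- c(accuracy = 0.90, precision = 0.88, mae = 0.20)
  tab <- augmentation_ab_report(orig, aug)
  expect_identical(names(tab), c("metric", "original", "augmented", "change_pct"))
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$change_pct[i],
                 round(percent_change(tab$original[i], tab$augmented[i]), 2))
  # identical runs: zero deltas and d = 0
  same <- augmentation_ab_report(orig, orig, sd_original = orig * 0 + 0.5,
                                 sd_augmented = orig * 0 + 0.5, n_runs = 5)
  expect_true(all(same$change_pct == 0))
  expect_true(all(same$cohens_d == 0))
  expect_true(all(same$ci_original_lower < same$original))
  expect_error(augmentation_ab_report(orig, c(foo = 1, bar = 2, baz = 3)),
               "metric names")
})
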