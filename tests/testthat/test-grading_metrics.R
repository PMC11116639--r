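test_that("event counting honors both conventions", {
  e <- c(0, 1, 1, 0, 1)
  expect_equal(count_events(e, "positive_minutes"), 3L)
  expect_equal(count_events(e, "contiguous_runs"), 2L)
  expect_equal(count_events(rep(0, 480)), 0L)
  expect_equal(count_events(rep(1, 480), "positive_minutes"), 480L)
  expect_equal(count_events(rep(1, 480), "contiguous_runs"), 1L)
  expect_error(count_events(c(0, 2)), "binary")

  # brute-force run scan on random records
  set.seed(14)
  for (rep in 1:25) {
    e <- rbinom(60, 1, 0.3)
    runs <- 0; prev <- 0
    for (v in e) { if (v == 1 && prev == 0) runs <- runs + 1; prev <- v }
    expect_equal(count_events(e, "contiguous_runs"), runs)
    expect_equal(count_events(e, "positive_minutes"), sum(e))
  }
})

test_that("AHI is exact division and grades monotonically", {
  expect_equal(compute_ahi(16, 8)$ahi, 2)
  expect_equal(compute_ahi(44, 8)$ahi, 5.5)
  expect_equal(compute_ahi(389, 8)$ahi, 48.625)
  expect_error(compute_ahi(10, 0), "positive")
  expect_error(compute_ahi(-1, 8), "nonnegative")

  # severity is monotone non-decreasing in N at fixed t
  labels <- vapply(0:400, function(n) unname(compute_ahi(n, 8)$severity),
                   integer(1))
  expect_true(all(diff(labels) >= 0))
})

test_that("severity bins follow the clinical cut points with boundaries upward", {
  expect_equal(unname(grade_severity(0)), 0L)
  expect_equal(unname(grade_severity(4.999)), 0L)
  expect_equal(unname(grade_severity(5)), 1L)
  expect_equal(unname(grade_severity(15)), 2L)
  expect_equal(unname(grade_severity(30)), 3L)
  expect_equal(names(grade_severity(c(1, 7, 20, 50))),
               c("normal", "mild", "moderate", "severe"))
  expect_error(grade_severity(-0.1), "nonnegative")
})

test_that("binary metrics match their defining formulas on enumerated tables", {
  perfect <- binary_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$specificity, 1)

  r <- binary_metrics(c(1, 0, 1, 0), c(1, 1, 0, 0))  # TP FP FN TN = 1 each
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 0.5)
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$TP + r$FP + r$FN + r$TN, r$n)

  expect_warning(z <- binary_metrics(c(1, 0), c(0, 0)), "precision")
  expect_equal(z$precision, 0)
  expect_equal(z$recall, 0)
  expect_error(binary_metrics(c(1, 0), c(1)), "equal length")
})

test_that("confusion counts always total n on random label pairs", {
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    r <- suppressWarnings(binary_metrics(rbinom(n, 1, 0.5),
                                         rbinom(n, 1, 0.5)))
    expect_equal(r$TP + r$FP + r$FN + r$TN, n)
  }
})

test_that("regression metrics use standard forms with a faithful R2 variant", {
  exact <- regression_metrics(1:5, 1:5)
  expect_equal(exact$mae, 0); expect_equal(exact$mse, 0)
  expect_equal(exact$r2, 1)

  r <- regression_metrics(c(0, 2), c(1, 1))
  expect_equal(r$mae, 1); expect_equal(r$mse, 1); expect_equal(r$r2, 0)

  expect_warning(c0 <- regression_metrics(c(3, 3), c(1, 2)), "undefined")
  expect_equal(c0$r2, 0)

  # the variant denominator sum((ybar - yhat)^2)
  y <- c(1, 2, 3, 6); yh <- c(2, 2, 2, 5)
  v <- regression_metrics(y, yh, paper_faithful_r2 = TRUE)
  expect_equal(v$r2, 1 - sum((y - yh)^2) / sum((mean(y) - yh)^2))
})

test_that("trapezoidal AUC equals the all-pairs rank oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(16)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)   # coarse scores force ties
    expect_equal(roc_auc(y, s)$auc, pairs_auc(y, s), tolerance = 1e-12)
  }
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  set.seed(17)
  y <- rbinom(100, 1, 0.4)
  rp <- roc_auc(y, runif(100))$roc_points
  expect_equal(unlist(rp[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rp[nrow(rp), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rp$fpr) >= 0))
  expect_true(all(diff(rp$tpr) >= 0))
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  y <- rbinom(150, 1, 0.5)
  s <- rnorm(150) + y
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("permutation importance ranks an injected noise column last", {
  set.seed(19)
  n <- 400
  informative <- rnorm(n)
  noise <- rnorm(n)
  y <- as.integer(informative + rnorm(n, 0, 0.3) > 0)
  x <- cbind(signal = informative, dead = noise, signal_copy = informative)
  model <- train_event_classifier(x, y, run_config(n_rounds = 30L))
  imp <- feature_importance(model, x, y, n_repeats = 5, seed = 21)
  expect_equal(imp$feature[nrow(imp)], "dead")
  expect_lt(imp$auc_drop[imp$feature == "dead"], 0.05)
  # duplicated informative column: importance splits but both drops stay >= 0
  expect_true(all(imp$auc_drop[imp$feature != "dead"] > 0))
  # seeded repeatability
  imp2 <- feature_importance(model, x, y, n_repeats = 5, seed = 21)
  expect_identical(imp, imp2)
})
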