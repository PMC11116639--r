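test_that("fusion concatenates blocks in stable (s, C[, e]) order", {
  sem <- matrix(rnorm(480 * 8), 480, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
  mfcc <- matrix(rnorm(480 * 13), 480, 13,
                 dimnames = list(NULL, paste0("c", 1:13)))
  e <- rep(c(0L, 1L), 240)

  f <- fuse(sem, mfcc, mode = "inference_safe")
  expect_equal(dim(f), c(480L, 21L))
  expect_equal(colnames(f), c(paste0("s", 1:8), paste0("c", 1:13)))
  expect_false("e" %in% colnames(f))

  expect_warning(fp <- fuse(sem, mfcc, e, mode = "paper_faithful"),
                 "circular")
  expect_equal(dim(fp), c(480L, 22L))
  expect_equal(unname(fp[, 22]), e)

  expect_error(fuse(sem[1:10, ], mfcc), "mismatch")
  expect_error(fuse(sem, mfcc, e[1:10], mode = "paper_faithful"),
               "mismatch")
})

test_that("training recovers a linearly separable fixture", {
  fx <- separable_fixture(200)
  model <- train_event_classifier(fx$x, fx$y,
                                  run_config(random_seed = 3))
  pred <- predict_minutes(model, fx$x)
  expect_gte(mean(pred$labels == fx$y), 0.99)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  expect_length(pred$scores, 200L)
})

test_that("training is seeded-deterministic and validates its inputs", {
  fx <- separable_fixture(120, seed = 2)
  cfg <- run_config(random_seed = 9, n_rounds = 20L)
  m1 <- train_event_classifier(fx$x, fx$y, cfg)
  m2 <- train_event_classifier(fx$x, fx$y, cfg)
  expect_identical(predict_minutes(m1, fx$x)$scores,
                   predict_minutes(m2, fx$x)$scores)

  expect_error(train_event_classifier(fx$x, rep(1, 120)), "single class")
  bad <- fx$x; bad[3, 2] <- NaN
  expect_error(train_event_classifier(bad, fx$y), "f2")

  # identical feature rows get identical scores
  same <- fx$x[rep(1, 10), ]
  expect_length(unique(predict_minutes(m1, same)$scores), 1L)
})

test_that("per-round training loss is non-increasing without row subsampling", {
  fx <- separable_fixture(150, seed = 5)
  cfg <- run_config(subsample = 1, colsample_bytree = 1, n_rounds = 30L)
  model <- train_event_classifier(fx$x, fx$y, cfg)
  loss <- model$training_log$train_logloss
  expect_length(loss, 30L)
  expect_true(all(diff(loss) <= 1e-12))
})

test_that("prediction rejects mismatched feature columns", {
  fx <- separable_fixture(100)
  model <- train_event_classifier(fx$x, fx$y, run_config(n_rounds = 5L))
  wrong <- fx$x
  colnames(wrong)[2] <- "g2"
  expect_error(predict_minutes(model, wrong), "do not match")
})

test_that("night-grouped cross-validation keeps nights whole and finds signal", {
  fx <- separable_fixture(240, seed = 8)
  nights <- rep(1:12, each = 20)
  cv <- cross_validate(fx$x, fx$y, nights,
                       grid = list(run_config(n_rounds = 15L)), k = 4)
  # partition property: each night in exactly one fold
  expect_length(cv$fold_of, 12L)
  expect_true(all(table(cv$fold_of) >= 1))
  expect_equal(nrow(cv$results), 4L)
  expect_gt(cv$best_auc, 0.95)
  # a one-config grid returns that config
  expect_equal(cv$best_config$n_rounds, 15L)
  expect_error(cross_validate(fx$x, fx$y, rep(1:3, each = 80), k = 5),
               "fewer nights")
})

test_that("paper-faithful fusion lets the leaked label dominate", {
  # features carry no signal; only the leaked e column does
  set.seed(12)
  x <- matrix(rnorm(300 * 5), 300, 5, dimnames = list(NULL, paste0("s", 1:5)))
  y <- rbinom(300, 1, 0.4)
  suppressWarnings(
    xf <- fuse(x[, 1:3, drop = FALSE], x[, 4:5, drop = FALSE], y,
               mode = "paper_faithful"))
  model <- train_event_classifier(xf, y, run_config(n_rounds = 30L))
  acc <- mean(predict_minutes(model, xf)$labels == y)
  expect_gte(acc, 0.99)   # circularity: the label is an input
  expect_true("e" %in% model$feature_names)

  # inference-safe mode never sees the event column
  xs <- fuse(x[, 1:3, drop = FALSE], x[, 4:5, drop = FALSE], y,
             mode = "inference_safe")
  model_s <- train_event_classifier(xs, y, run_config(n_rounds = 10L))
  expect_false("e" %in% model_s$feature_names)
})
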