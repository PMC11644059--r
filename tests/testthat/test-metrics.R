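test_that("confusion counts samples by (true, predicted) pairs", {
  expect_equal(unclass(confusion(c(1, 2), c(1, 2), K = 2)),
               matrix(c(1L, 0L, 0L, 1L), 2), ignore_attr = TRUE)
  cm <- confusion(c(1, 1, 2), c(2, 2, 2), K = 2)
  expect_equal(as.integer(cm), as.integer(matrix(c(0, 0, 2, 1), 2)))
  set.seed(1)
  big <- confusion(sample(9, 1000, TRUE), sample(9, 1000, TRUE), K = 9)
  expect_equal(sum(big), 1000)
  expect_error(confusion(1:3, 1:2, K = 3), "equal length")
  expect_error(confusion(c(1, 4), c(1, 2), K = 3), "1..3")
})

test_that("one-vs-rest reduction recovers TP/FN/FP/TN", {
  cm <- matrix(c(8, 3, 2, 7), 2)  # rows true: (8,2),(3,7)
  expect_equal(binary_counts(cm, 1), c(TP = 8, FN = 2, FP = 3, TN = 7))
  ident <- diag(c(5, 5, 5))
  for (c in 1:3) {
    b <- binary_counts(ident, c)
    expect_equal(unname(b[c("FN", "FP")]), c(0, 0))
  }
  # rows partition the samples
  expect_equal(sum(vapply(1:2, function(c) {
    b <- binary_counts(cm, c); unname(b["TP"] + b["FN"])
  }, numeric(1))), sum(cm))
})

test_that("accuracy, sensitivity and specificity follow their defining ratios", {
  cm <- matrix(c(8, 3, 2, 7), 2)
  r <- classification_metrics(cm)
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$sensitivity, (0.8 + 0.7) / 2)
  expect_equal(r$specificity, (0.7 + 0.8) / 2)

  perfect <- classification_metrics(diag(c(4, 9, 2)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # balanced truths, one predicted class: accuracy collapses to 1/K
  one_col <- matrix(0, 3, 3); one_col[, 1] <- 5
  expect_equal(classification_metrics(one_col)$accuracy, 1 / 3)
  expect_error(classification_metrics(matrix(0, 2, 2)), "all zero")
})

test_that("binary accuracy equals (TP+TN)/total for either class reduction", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    true <- sample(2, n, TRUE); pred <- sample(2, n, TRUE)
    cm <- confusion(true, pred, 2)
    acc <- classification_metrics(cm)$accuracy
    for (c in 1:2) {
      b <- binary_counts(cm, c)
      expect_identical(acc, unname((b["TP"] + b["TN"]) / sum(b)))
    }
  }
})

test_that("classes absent from the truth are flagged and excluded from macro means", {
  cm <- matrix(c(3, 0, 0, 1, 2, 0, 0, 1, 0), 3, byrow = TRUE)
  cm[3, ] <- 0  # class 3 never occurs
  r <- classification_metrics(cm)
  expect_false(r$per_class$defined[3])
  expect_true(is.na(r$per_class$sensitivity[3]))
  expect_equal(r$sensitivity, mean(r$per_class$sensitivity[1:2]))
})

test_that("metrics match brute-force recomputation from raw labels", {
  set.seed(31)
  for (rep in 1:200) {
    K <- sample(2:9, 1)
    n <- sample(K:300, 1)
    true <- sample(K, n, TRUE); pred <- sample(K, n, TRUE)
    r <- classification_metrics(confusion(true, pred, K))
    o <- brute_force_metrics(true, pred, K)
    expect_equal(r$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(r$sensitivity, o$sensitivity, tolerance = 1e-12)
    expect_equal(r$specificity, o$specificity, tolerance = 1e-12)
  }
})

test_that("the learning-rate schedule is a non-increasing staircase", {
  cfg <- train_config()
  expect_equal(lr_at(1, cfg), 0.001)
  expect_equal(lr_at(50, cfg), 0.001)
  expect_equal(lr_at(51, cfg), 1e-4)
  expect_equal(lr_at(200, cfg), 1e-6)
  lrs <- lr_at(1:200, cfg)
  expect_true(all(diff(lrs) <= 0))
  # drops happen only when crossing a multiple of decay_every
  drops <- which(diff(lrs) < 0)
  expect_equal(drops %% cfg$decay_every, rep(0, length(drops)))
  expect_error(lr_at(0, cfg), "1..200")
  expect_error(lr_at(201, cfg), "1..200")
})
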