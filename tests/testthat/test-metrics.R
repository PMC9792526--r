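test_that("confusion matrices tally labels exactly", {
  true <- c(0, 1, 2, 3, 3, 2, 1, 0, 0)
  pred <- c(0, 1, 1, 3, 2, 2, 1, 3, 0)
  cm <- confusion(true, pred)
  expect_equal(sum(cm), 9)
  expect_equal(diag(cm), c(2, 2, 1, 1), ignore_attr = TRUE)
  expect_equal(cm[3, 2], 1L)   # one high-risk called medium
  expect_equal(unname(rowSums(cm)),
               as.integer(table(factor(true, levels = 0:3))))

  perfect <- confusion(0:3, 0:3)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  expect_error(confusion(c(0, 4), c(0, 1)), "out of range")
})

test_that("per-class scores agree with direct TP/FP/FN counting", {
  set.seed(17)
  for (trial in 1:100) {
    C <- sample(2:5, 1)
    n <- sample(10:60, 1)
    true <- sample(0:(C - 1), n, TRUE)
    pred <- sample(0:(C - 1), n, TRUE)
    cm <- confusion(true, pred, C)
    cls <- sample(0:(C - 1), 1)
    tp <- sum(true == cls & pred == cls)
    fp <- sum(true != cls & pred == cls)
    fn <- sum(true == cls & pred != cls)
    row <- prf1(cm, cls)
    p_ref <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    r_ref <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    expect_equal(row$precision, p_ref)
    expect_equal(row$recall, r_ref)
    # F1 lies between precision and recall
    if (!row$degenerate) {
      expect_gte(row$f1, min(p_ref, r_ref) - 1e-9)
      expect_lte(row$f1, max(p_ref, r_ref) + 1e-9)
    }
  }
  # harmonic mean of equal values is that value
  expect_equal(f1_score(80, 80), 80)
})

test_that("macro means and accuracy follow their definitions", {
  true <- rep(0:3, each = 10)
  pred <- true
  pred[c(1, 11, 12, 21, 31)] <- c(1, 0, 0, 3, 0)
  rep_ <- metrics_report(true, pred)
  cm <- attr(rep_, "confusion")
  expect_equal(attr(rep_, "accuracy"), 100 * sum(diag(cm)) / 40)
  recalls <- sapply(0:3, function(c) prf1(cm, c)$recall)
  expect_equal(unname(macro(rep_)["recall"]), mean(recalls))
  expect_equal(rep_$state, c("low", "medium", "high", "attack"))

  perfect <- metrics_report(true, true)
  expect_equal(attr(perfect, "accuracy"), 100)
  expect_equal(unname(macro(perfect)), rep(100, 3))
})

test_that("rank-based AUC equals the pair-counting oracle, ties included", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(auc(rep(5, 8), rep(0:1, 4)), 0.5)
  set.seed(23)
  for (trial in 1:30) {
    n <- sample(10:100, 1)
    scores <- sample(1:12, n, TRUE)   # heavy ties
    labels <- sample(0:1, n, TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("relative and absolute changes are kept distinct", {
  expect_equal(percent_change(84.75, 89.56), 5.68, tolerance = 5e-3)
  expect_equal(percent_change(50, 50), 0)
  expect_equal(point_change(83.14, 84.51), 1.37, tolerance = 1e-9)
  expect_error(percent_change(0, 10), "positive")
  # round trip old -> new -> old flips sign but not magnitude
  up <- percent_change(80, 90)
  down <- percent_change(90, 80)
  expect_gt(up, 0)
  expect_lt(down, 0)
  expect_false(isTRUE(all.equal(up, -down)))
})

test_that("run aggregation reports mean, sample sd, and a 95% CI", {
  agg <- aggregate_runs(c(80, 82, 84))
  expect_equal(agg$mean, 82)
  expect_equal(agg$sd, 2)
  expect_equal(agg$ci_hi - agg$mean, 1.96 * 2 / sqrt(3))

  same <- aggregate_runs(c(75, 75, 75, 75))
  expect_equal(same$sd, 0)
  expect_equal(same$ci_lo, same$ci_hi)
  expect_error(aggregate_runs(c(80)), "at least 2")

  # report-level aggregation covers every state and metric
  true <- rep(0:3, each = 25)
  set.seed(5)
  reports <- lapply(1:3, function(i) {
    pred <- true
    flip <- sample(100, 10)
    pred[flip] <- sample(0:3, 10, TRUE)
    metrics_report(true, pred)
  })
  agg2 <- aggregate_runs(reports)
  expect_true(all(c("accuracy", "macro_recall") %in% agg2$metric))
  expect_equal(sum(agg2$state == "attack"), 3)  # precision, recall, f1
  expect_true(all(agg2$ci_lo <= agg2$mean & agg2$mean <= agg2$ci_hi))
})
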