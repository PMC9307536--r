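test_that("change counting matches its definition", {
  expect_equal(count_changes(codes_to_seq(rep(1L, 5L), 2L)), 0L)
  expect_equal(count_changes(codes_to_seq(c(1L, 2L, 1L), 2L)), 2L)
  expect_equal(count_changes(codes_to_seq(1L, 2L)), 0L)
})

test_that("volatility is the ratio of prediction to ground-truth changes", {
  pair <- example_volatility_pair()
  expect_equal(count_changes(pair_pred <- pair$pred), 3L)
  expect_equal(count_changes(pair$truth), 2L)
  expect_equal(prediction_volatility(pair), 1.5)

  gt <- codes_to_seq(rep(c(1L, 2L), each = 10L), 2L)
  expect_equal(prediction_volatility(gt$label, gt$label), 1.0)
  expect_equal(prediction_volatility(codes_to_seq(rep(1L, 30L), 3L)$label,
    codes_to_seq(rep(c(1L, 2L, 3L), each = 10L), 3L)$label), 0.0)
})

test_that("a change-free ground truth yields the undefined marker", {
  const <- codes_to_seq(rep(1L, 10L), 2L)
  varying <- codes_to_seq(rep(c(1L, 2L), 5L), 2L)
  expect_message(
    v <- prediction_volatility(varying$label, const$label),
    "undefined"
  )
  expect_true(is.na(v))
})

test_that("a perfect prediction scores 1 everywhere", {
  gt <- codes_to_seq(rep(c(1L, 2L, 3L), each = 7L), 3L)
  ev <- evaluate_pair(make_pair(gt, gt))
  g <- glance(ev)
  expect_equal(g$weighted_f1, 1.0)
  expect_equal(g$weighted_precision, 1.0)
  expect_equal(g$weighted_recall, 1.0)
  expect_equal(g$mean_accuracy, 1.0)
  expect_equal(g$volatility, 1.0)
  expect_equal(unname(diag(confusion_matrix(ev))), rep(100, 3L))
})

test_that("the two-class worked example reproduces the hand computation", {
  vocab <- c("A", "B")
  gt <- label_sequence(c("A", "A", "B", "B"), vocab)
  pr <- label_sequence(c("A", "B", "B", "B"), vocab)
  ev <- evaluate_pair(make_pair(gt, pr))
  pc <- tidy(ev)
  expect_equal(pc$precision, c(1, 2 / 3))
  expect_equal(pc$recall, c(0.5, 1))
  expect_equal(pc$f1, c(2 / 3, 0.8))
  expect_equal(pc$support, c(2L, 2L))
  expect_equal(glance(ev)$weighted_f1, 11 / 15)
  expect_equal(unname(confusion_matrix(ev)["B", ]), c(100 / 3, 200 / 3))
})

test_that("degenerate one-class videos stay well-defined", {
  gt <- codes_to_seq(rep(2L, 12L), 3L)
  ev <- suppressMessages(evaluate_pair(make_pair(gt, gt)))
  expect_equal(glance(ev)$weighted_f1, 1.0)
  expect_true(is.na(glance(ev)$volatility))
})

test_that("weighted F1 is 1 exactly when the prediction matches frame-for-frame", {
  withr::local_seed(21)
  for (i in seq_len(25)) {
    K <- sample(2:5, 1L)
    gt <- random_codes(sample(5:100, 1L), K)
    pred <- gt
    if (i %% 2L == 0L) { # corrupt one frame in half the cases
      j <- sample(seq_along(pred), 1L)
      pred[j] <- (pred[j] %% K) + 1L
    }
    ev <- suppressMessages(
      evaluate_pair(make_pair(codes_to_seq(gt, K), codes_to_seq(pred, K)))
    )
    expect_equal(abs(glance(ev)$weighted_f1 - 1) < 1e-12, identical(pred, gt))
  }
})

test_that("weighted recall equals overall frame accuracy", {
  withr::local_seed(22)
  for (i in seq_len(25)) {
    K <- sample(2:5, 1L)
    gt <- random_codes(sample(10:200, 1L), K)
    pred <- random_codes(length(gt), K)
    ev <- suppressMessages(
      evaluate_pair(make_pair(codes_to_seq(gt, K), codes_to_seq(pred, K)))
    )
    expect_equal(glance(ev)$weighted_recall, mean(gt == pred), tolerance = 1e-12)
  }
})

test_that("confusion rows are percentages whose diagonal is the precision", {
  withr::local_seed(23)
  K <- 4L
  gt <- random_codes(400L, K)
  pred <- random_codes(400L, K) # all classes predicted w.h.p.
  ev <- suppressMessages(
    evaluate_pair(make_pair(codes_to_seq(gt, K), codes_to_seq(pred, K)))
  )
  cm <- confusion_matrix(ev)
  expect_equal(unname(rowSums(cm)), rep(100, K), tolerance = 0.1)
  expect_equal(unname(diag(cm)), 100 * tidy(ev)$precision, tolerance = 1e-9)
})

test_that("threshold smoothing never increases volatility", {
  withr::local_seed(24)
  for (i in seq_len(30)) {
    K <- sample(2:4, 1L)
    gt <- codes_to_seq(rep(random_codes(4L, K), each = 25L), K)
    pred <- codes_to_seq(random_codes(100L, K), K)
    if (count_changes(gt) == 0L) next
    n <- sample(1:15, 1L)
    expect_lte(
      prediction_volatility(threshold_smooth(pred, n)$label, gt$label),
      prediction_volatility(pred$label, gt$label)
    )
  }
})

test_that("inserting duplicate frames inside runs changes neither change count", {
  withr::local_seed(25)
  for (i in seq_len(20)) {
    K <- 3L
    gt <- rep(random_codes(5L, K), each = 10L)
    pred <- random_codes(length(gt), K)
    j <- sample(seq_along(gt), 1L)
    gt2 <- append(gt, gt[j], after = j) # duplicate inside an existing run
    pred2 <- append(pred, pred[j], after = j)
    expect_equal(count_changes(codes_to_seq(gt2, K)), count_changes(codes_to_seq(gt, K)))
    expect_equal(count_changes(codes_to_seq(pred2, K)), count_changes(codes_to_seq(pred, K)))
  }
})

test_that("fold aggregation reports mean and population sd per metric", {
  gt <- codes_to_seq(rep(c(1L, 2L), each = 20L), 2L)
  pred <- codes_to_seq(c(rep(1L, 18L), rep(2L, 22L)), 2L)
  r1 <- evaluate_pair(make_pair(gt, pred))
  agg0 <- aggregate_folds(list(r1, r1, r1))
  expect_true(all(agg0$sd == 0))

  two <- tibble::tibble(weighted_f1 = c(0.8, 0.9))
  agg <- aggregate_folds(two)
  expect_equal(agg$mean[agg$metric == "weighted_f1"], 0.85)
  expect_equal(agg$sd[agg$metric == "weighted_f1"], 0.05)

  expect_error(aggregate_folds(list(r1)), "at least 2 folds")
})

test_that("fold means are stable across independent master seeds", {
  sc <- standard_scenario()
  run_means <- sapply(c(101L, 202L), function(s) {
    pairs <- simulate_pairs(sc$workflow, sc$noise, 4L, seed = s)
    reports <- lapply(pairs, function(p) suppressMessages(evaluate_pair(p)))
    agg <- aggregate_folds(reports)
    agg$mean[agg$metric == "weighted_f1"]
  })
  sds <- sapply(c(101L, 202L), function(s) {
    pairs <- simulate_pairs(sc$workflow, sc$noise, 4L, seed = s)
    reports <- lapply(pairs, function(p) suppressMessages(evaluate_pair(p)))
    agg <- aggregate_folds(reports)
    agg$sd[agg$metric == "weighted_f1"]
  })
  expect_lt(abs(run_means[1L] - run_means[2L]), 3 * max(sds))
})
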