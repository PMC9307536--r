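test_that("constant sequences are fixed points of both smoothers", {
  x <- label_sequence(rep("A", 30L), c("A", "B"))
  for (n in c(1L, 5L, 60L)) {
    expect_identical(modal_smooth(x, n), x)
    expect_identical(threshold_smooth(x, n), x)
  }
})

test_that("modal ties resolve to the most recent class", {
  # every length-2 binary sequence with n = 1: t = 0 passes through,
  # t = 1 is a window tie broken toward the newer frame
  for (a in 1:2) {
    for (b in 1:2) {
      x <- codes_to_seq(c(a, b), 2L)
      got <- as.integer(modal_smooth(x, 1L)$label)
      expect_identical(got, oracle_modal(c(a, b), 1L))
      expect_identical(got, c(a, b)) # tie -> most recent = raw value
    }
  }
})

test_that("threshold smoothing follows the documented recurrence", {
  x <- codes_to_seq(c(1L, 2L, 1L, 2L, 2L, 2L), 2L)
  expect_identical(as.integer(threshold_smooth(x, 2L)$label), c(1L, 2L, 2L, 2L, 2L, 2L))
  expect_identical(
    as.integer(threshold_smooth(x, 2L)$label),
    oracle_threshold(c(1L, 2L, 1L, 2L, 2L, 2L), 2L)
  )
})

test_that("both smoothers agree with their brute-force oracles on random input", {
  withr::local_seed(42)
  for (i in seq_len(120)) {
    K <- sample(2:4, 1L)
    len <- sample(1:120, 1L)
    n <- sample(1:15, 1L)
    codes <- random_codes(len, K)
    x <- codes_to_seq(codes, K)
    expect_identical(as.integer(modal_smooth(x, n)$label), oracle_modal(codes, n))
    expect_identical(as.integer(threshold_smooth(x, n)$label), oracle_threshold(codes, n))
  }
})

test_that("sequences shorter than the window pass through unchanged", {
  x <- codes_to_seq(c(1L, 2L, 1L), 2L)
  expect_identical(modal_smooth(x, 10L), x)
  expect_identical(threshold_smooth(x, 10L), x)
})

test_that("window sizes outside [1, 60] are configuration errors", {
  x <- codes_to_seq(c(1L, 2L), 2L)
  for (bad in list(0L, 61L, -3L, 2.5, NA_integer_)) {
    expect_error(modal_smooth(x, bad), "configuration error")
    expect_error(threshold_smooth(x, bad), "configuration error")
  }
})

test_that("threshold smoothing never increases the change count", {
  withr::local_seed(7)
  for (i in seq_len(60)) {
    K <- sample(2:4, 1L)
    codes <- random_codes(sample(2:150, 1L), K)
    x <- codes_to_seq(codes, K)
    n <- sample(1:20, 1L)
    expect_lte(count_changes(threshold_smooth(x, n)), count_changes(x))
  }
})

test_that("committed threshold change points are at least n+1 frames apart", {
  withr::local_seed(8)
  for (i in seq_len(40)) {
    n <- sample(1:10, 1L)
    codes <- random_codes(sample((2L * n + 2L):200L, 1L), 3L)
    out <- as.integer(threshold_smooth(codes_to_seq(codes, 3L), n)$label)
    cps <- which(diff(out) != 0L) # change at position cp+1 (1-based)
    cps <- cps[cps + 1L > n] # ignore the passthrough prefix
    if (length(cps) > 1L) {
      expect_true(all(diff(cps) >= n + 1L))
    }
  }
})

test_that("smoothers are causal: suffix edits never alter earlier output", {
  withr::local_seed(9)
  for (i in seq_len(30)) {
    K <- 3L
    len <- sample(20:80, 1L)
    n <- sample(1:8, 1L)
    codes <- random_codes(len, K)
    cut <- sample(2:(len - 1L), 1L)
    mutated <- codes
    mutated[(cut + 1L):len] <- random_codes(len - cut, K)
    for (fn in list(modal_smooth, threshold_smooth)) {
      a <- as.integer(fn(codes_to_seq(codes, K), n)$label)
      b <- as.integer(fn(codes_to_seq(mutated, K), n)$label)
      expect_identical(a[1:cut], b[1:cut])
    }
  }
})

test_that("window selection scores every n and keeps the smallest argmax", {
  vocab <- c("A", "B", "C")
  gt <- label_sequence(rep(c("A", "B", "C"), each = 30L), vocab, video_id = "v")
  perfect <- make_pair(gt, gt)
  # on an already-perfect prediction the best window is the smallest one:
  # M_1 is the identity (a 2-frame tie resolves to the current frame) and
  # every larger window only adds post-change lag
  selm <- select_window(list(perfect), "modal", n_range = c(1L, 10L))
  expect_equal(selm$best_n, 1L)
  expect_equal(selm$best_score, 1.0)
  selt <- select_window(list(perfect), "threshold", n_range = c(1L, 10L))
  expect_equal(selt$best_n, 1L)
  expect_true(all(diff(selt$scores$weighted_f1) <= 1e-12)) # lag grows with n
  expect_equal(nrow(tidy(selt)), 10L)

  # constant sequences are fixed points of both smoothers, so every n
  # ties at 1.0 and the tie must resolve to the smallest n
  const <- make_pair(
    label_sequence(rep("A", 40L), vocab, video_id = "c"),
    label_sequence(rep("A", 40L), vocab, video_id = "c")
  )
  for (kind in c("modal", "threshold")) {
    sel <- select_window(list(const), kind, n_range = c(1L, 10L))
    expect_true(all(sel$scores$weighted_f1 == 1.0))
    expect_equal(sel$best_n, 1L)
  }

  sel5 <- select_window(list(perfect), "modal", n_range = c(5L, 5L))
  expect_equal(sel5$best_n, 5L)
})

test_that("window selection brackets the burst length under designed noise", {
  # all error bursts have length exactly 3 and all correct runs exceed 10:
  # a threshold window in [3, 10] removes every burst without losing any
  # genuine change, so the tuner must land there and beat n = 1
  withr::local_seed(0)
  K <- 3L
  pairs <- lapply(1:3, function(v) {
    gt <- rep(seq_len(K), each = 40L)
    pred <- gt
    for (s in c(15L, 55L, 95L)) {
      pred[s:(s + 2L)] <- (gt[s:(s + 2L)] %% K) + 1L
    }
    make_pair(
      codes_to_seq(gt, K, video_id = paste0("v", v)),
      codes_to_seq(pred, K, video_id = paste0("v", v))
    )
  })
  sel <- select_window(pairs, "threshold")
  expect_gte(sel$best_n, 3L)
  expect_lte(sel$best_n, 10L)
  expect_gt(sel$best_score, sel$scores$weighted_f1[sel$scores$n == 1L])
})

test_that("window selection rejects empty training sets", {
  expect_error(select_window(list(), "modal"), "empty training set")
})
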