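#' Describe a semi-Markov surgical workflow generator
#'
#' The generator emulates the structure of operative workflows: classes
#' (phases or steps) are visited in a fixed canonical order, but a class
#' can occasionally be skipped, the surgeon can briefly fall back to the
#' previous class before resuming (a revisit), and the time spent in each
#' visit is heavy-tailed. Durations are log-normal in seconds (1 frame =
#' 1 s), truncated below at 1 s.
#'
#' @param vocabulary Character vector of class names in canonical order.
#' @param order Integer permutation giving the canonical visit order over
#'   `vocabulary`; defaults to file order.
#' @param skip_prob Per-class probability of being skipped entirely.
#' @param revisit_prob Per-transition probability of inserting a brief
#'   return to the previous class.
#' @param duration_log_mean,duration_log_sd Log-normal duration
#'   parameters, recycled over classes. The defaults put the median visit
#'   at 600 s with a heavy right tail.
#' @param revisit_scale Multiplier applied to `duration_log_mean` for the
#'   inserted revisit (revisits are brief compared to first visits).
#' @return An object of class `workflow_model`.
#' @examples
#' workflow_model(label_vocabulary(paste0("S", 1:7), task = "steps"))
#' @export
workflow_model <- function(vocabulary,
                           order = seq_along(vocabulary),
                           skip_prob = 0.1,
                           revisit_prob = 0.1,
                           duration_log_mean = log(600),
                           duration_log_sd = 0.5,
                           revisit_scale = 0.25) {
  vocabulary <- as.character(vocabulary)
  K <- length(vocabulary)
  if (K < 2L) {
    rlang::abort("model error: a workflow needs at least 2 classes")
  }
  if (!identical(sort(as.integer(order)), seq_len(K))) {
    rlang::abort("model error: `order` must be a permutation of 1..K")
  }
  for (p in c(skip_prob, revisit_prob)) {
    if (p < 0 || p > 1) rlang::abort("model error: probabilities must lie in [0, 1]")
  }
  structure(
    list(
      vocabulary = vocabulary,
      order = as.integer(order),
      skip_prob = skip_prob,
      revisit_prob = revisit_prob,
      duration_log_mean = rep_len(duration_log_mean, K),
      duration_log_sd = rep_len(duration_log_sd, K),
      revisit_scale = revisit_scale
    ),
    class = "workflow_model"
  )
}

#' @export
print.workflow_model <- function(x, ...) {
  cat("Semi-Markov workflow model over", length(x$vocabulary), "classes\n")
  cat("  order:", paste(x$vocabulary[x$order], collapse = " -> "), "\n")
  cat(sprintf(
    "  skip %.2f, revisit %.2f, median duration ~%.0f s\n",
    x$skip_prob, x$revisit_prob, exp(mean(x$duration_log_mean))
  ))
  invisible(x)
}

#' Simulate a ground-truth workflow sequence
#'
#' Draws one synthetic video: the visit order is the model's canonical
#' order with per-class skips and single-step revisits, then each visit
#' gets an independent log-normal duration rounded to a whole number of
#' seconds (minimum 1 s). The output is deterministic given
#' `(model, seed)` and never perturbs the caller's RNG state.
#'
#' In the degenerate draw where every class is skipped, one class (chosen
#' uniformly) has its skip disabled and the visit order is regenerated;
#' the event is reported with a message.
#'
#' @param model A [workflow_model()].
#' @param seed Integer seed.
#' @param video_id Identifier given to the simulated video.
#' @return A label-sequence tibble.
#' @export
simulate_ground_truth <- function(model, seed, video_id = "sim") {
  stopifnot(inherits(model, "workflow_model"))
  withr::with_seed(seed, {
    K <- length(model$vocabulary)
    canon <- model$order
    kept <- canon[stats::runif(K) >= model$skip_prob]
    if (length(kept) == 0L) {
      forced <- canon[sample.int(K, 1L)]
      rlang::inform(paste0(
        "all classes skipped; regenerating with skip disabled for class '",
        model$vocabulary[forced], "'"
      ))
      kept <- canon[stats::runif(K) >= model$skip_prob | canon == forced]
      if (!forced %in% kept) kept <- forced # belt and braces for tiny K
    }
    visits <- kept[1L]
    brief <- logical(1L)
    if (length(kept) > 1L) {
      for (i in 2:length(kept)) {
        visits <- c(visits, kept[i])
        brief <- c(brief, FALSE)
        if (stats::runif(1L) < model$revisit_prob) {
          visits <- c(visits, kept[i - 1L], kept[i])
          brief <- c(brief, TRUE, TRUE)
        }
      }
    }
    mu <- model$duration_log_mean[visits]
    mu[brief] <- mu[brief] * model$revisit_scale
    durations <- pmax(1L, as.integer(round(stats::rlnorm(
      length(visits),
      meanlog = mu, sdlog = model$duration_log_sd[visits]
    ))))
    label_sequence(rep.int(visits, durations), model$vocabulary, video_id = video_id)
  })
}

#' Neighbour-biased confusion matrix
#'
#' Frame classifiers on ordered workflows mistake a class mostly for its
#' order-neighbours (the adjacent phases/steps), rarely for distant ones.
#' This helper builds the corresponding row-stochastic confusion matrix:
#' `diag` on the true class, `neighbor_mass` shared equally among the
#' class's order-neighbours, and any remainder spread uniformly over the
#' other wrong classes.
#'
#' @param K Number of classes.
#' @param diag Probability of emitting the true class.
#' @param neighbor_mass Total probability given to order-neighbours;
#'   defaults to everything left after `diag`.
#' @return K x K row-stochastic matrix (rows = ground truth).
#' @export
neighbor_confusion <- function(K, diag = 0.85, neighbor_mass = NULL) {
  if (is.null(neighbor_mass)) neighbor_mass <- 1 - diag
  if (diag < 0 || diag > 1 || neighbor_mass < 0 || diag + neighbor_mass > 1 + 1e-12) {
    rlang::abort("model error: need diag, neighbor_mass >= 0 with diag + neighbor_mass <= 1")
  }
  C <- matrix(0, K, K)
  for (s in seq_len(K)) {
    nb <- intersect(c(s - 1L, s + 1L), seq_len(K))
    far <- setdiff(seq_len(K), c(s, nb))
    C[s, s] <- diag
    C[s, nb] <- neighbor_mass / length(nb)
    rest <- 1 - diag - neighbor_mass
    if (length(far) > 0L) {
      C[s, far] <- rest / length(far)
    } else {
      C[s, nb] <- C[s, nb] + rest / length(nb)
    }
  }
  C
}

#' Describe the prediction-noise generator
#'
#' Two corruption mechanisms are applied to a ground-truth sequence, in
#' order:
#'
#' 1. a memoryless misclassification channel — each frame's prediction is
#'    drawn from the confusion row of its true class (neighbour-biased by
#'    default, see [neighbor_confusion()]);
#' 2. occlusion bursts — short intervals of spurious labels emulating
#'    uninformative frames (blurred scenes, endoscope withdrawal). Bursts
#'    start independently at each frame with probability
#'    `burst_start_prob`, last a uniform number of frames between
#'    `burst_len[1]` and `burst_len[2]`, and overwrite the channel output
#'    with wrong labels: per-frame uniform over wrong classes
#'    (`"uniform_wrong"`) or one wrong class held for the whole burst
#'    (`"fixed_class"`).
#'
#' The defaults (start probability 0.013, lengths 3-12) make bursts cover
#' roughly 10% of frames.
#'
#' @param confusion K x K row-stochastic matrix, ground truth ->
#'   emitted prediction.
#' @param burst_start_prob Per-frame probability that a burst begins.
#' @param burst_len Integer `c(min, max)` burst length in frames.
#' @param burst_label_mode `"uniform_wrong"` or `"fixed_class"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(confusion,
                        burst_start_prob = 0.013,
                        burst_len = c(3L, 12L),
                        burst_label_mode = c("uniform_wrong", "fixed_class")) {
  burst_label_mode <- rlang::arg_match(burst_label_mode)
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion)) {
    rlang::abort("model error: confusion must be a square matrix")
  }
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9)) {
    rlang::abort("model error: confusion rows must be nonnegative and sum to 1")
  }
  burst_len <- as.integer(burst_len)
  if (length(burst_len) != 2L || burst_len[1L] < 1L || burst_len[2L] < burst_len[1L]) {
    rlang::abort("model error: burst_len must be c(min, max) with 1 <= min <= max")
  }
  if (burst_start_prob < 0 || burst_start_prob > 1) {
    rlang::abort("model error: burst_start_prob must lie in [0, 1]")
  }
  structure(
    list(
      confusion = confusion,
      burst_start_prob = burst_start_prob,
      burst_len = burst_len,
      burst_label_mode = burst_label_mode
    ),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Prediction noise model over", nrow(x$confusion), "classes\n")
  cat(sprintf(
    "  channel diagonal %.3f (mean), bursts: start %.4f/frame, length %d-%d, mode %s\n",
    mean(diag(x$confusion)), x$burst_start_prob,
    x$burst_len[1L], x$burst_len[2L], x$burst_label_mode
  ))
  invisible(x)
}

#' Corrupt a ground-truth sequence into synthetic predictions
#'
#' Applies the [noise_model()] channel and burst process to a
#' ground-truth sequence. Deterministic given `(gt, noise, seed)`;
#' the caller's RNG state is untouched.
#'
#' @param gt Ground-truth label-sequence tibble.
#' @param noise A [noise_model()] whose confusion matrix matches the
#'   sequence's vocabulary size.
#' @param seed Integer seed.
#' @return A label-sequence tibble of corrupted predictions, same length
#'   and vocabulary as `gt`.
#' @export
corrupt_predictions <- function(gt, noise, seed) {
  stopifnot(inherits(noise, "noise_model"))
  validate_sequence(gt, "gt")
  K <- nlevels(gt$label)
  if (nrow(noise$confusion) != K) {
    rlang::abort("model error: confusion matrix size does not match the vocabulary")
  }
  g <- seq_codes(gt)
  nT <- length(g)
  withr::with_seed(seed, {
    pred <- integer(nT)
    for (s in seq_len(K)) {
      idx <- which(g == s)
      if (length(idx) > 0L) {
        pred[idx] <- sample.int(K, length(idx), replace = TRUE, prob = noise$confusion[s, ])
      }
    }
    if (noise$burst_start_prob > 0) {
      starts <- which(stats::runif(nT) < noise$burst_start_prob)
      lens <- sample.int(noise$burst_len[2L] - noise$burst_len[1L] + 1L,
        length(starts),
        replace = TRUE
      ) + noise$burst_len[1L] - 1L
      busy_until <- 0L
      for (i in seq_along(starts)) {
        t0 <- starts[i]
        if (t0 <= busy_until) next # bursts never overlap
        t1 <- min(nT, t0 + lens[i] - 1L)
        span <- t0:t1
        if (noise$burst_label_mode == "uniform_wrong") {
          offs <- sample.int(K - 1L, length(span), replace = TRUE)
          pred[span] <- ((g[span] - 1L + offs) %% K) + 1L
        } else {
          off <- sample.int(K - 1L, 1L)
          pred[span] <- ((g[span] - 1L + off) %% K) + 1L
        }
        busy_until <- t1
      }
    }
    label_sequence(pred, levels(gt$label), video_id = unique(as.character(gt$video_id))[1L])
  })
}

#' Simulate a set of (ground truth, prediction) pairs
#'
#' Convenience wrapper drawing `n_videos` independent synthetic videos:
#' per-video sub-seeds are derived from `seed`, each ground truth comes
#' from [simulate_ground_truth()] and each prediction from
#' [corrupt_predictions()]. Identical inputs give bit-identical pairs.
#'
#' @param workflow A [workflow_model()].
#' @param noise A [noise_model()].
#' @param n_videos Number of videos to simulate.
#' @param seed Master integer seed.
#' @param video_prefix Prefix for the generated video identifiers.
#' @return A list of pair tibbles of length `n_videos`.
#' @export
simulate_pairs <- function(workflow, noise, n_videos, seed, video_prefix = "sim") {
  if (n_videos < 1L) {
    rlang::abort("model error: n_videos must be >= 1")
  }
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * n_videos))
  purrr::map(seq_len(n_videos), function(i) {
    vid <- sprintf("%s%03d", video_prefix, i)
    gt <- simulate_ground_truth(workflow, seed = sub[2L * i - 1L], video_id = vid)
    pr <- corrupt_predictions(gt, noise, seed = sub[2L * i])
    make_pair(gt, pr)
  })
}

#' Worked example: a pair with 3 predicted and 2 true class changes
#'
#' A canonical illustration of the volatility metric: over three phases
#' P1-P3, the ground truth runs (P1 x 8)(P2 x 8)(P3 x 8) — two class
#' changes — while the prediction briefly falls back to P1 inside P2,
#' giving runs (P1 x 8)(P2 x 5)(P1 x 3)(P3 x 8) and three class changes.
#' Its prediction volatility is therefore 3/2 = 1.5.
#'
#' @return A pair tibble of 24 frames over vocabulary P1, P2, P3.
#' @examples
#' prediction_volatility(example_volatility_pair())
#' @export
example_volatility_pair <- function() {
  vocab <- label_vocabulary(c("P1", "P2", "P3"), task = "phases")
  gt <- label_sequence(
    rep(c("P1", "P2", "P3"), times = c(8L, 8L, 8L)),
    vocab,
    video_id = "volatility_example"
  )
  pr <- label_sequence(
    rep(c("P1", "P2", "P1", "P3"), times = c(8L, 5L, 3L, 8L)),
    vocab,
    video_id = "volatility_example"
  )
  make_pair(gt, pr)
}

#' Worked example: a volatile two-class prediction stream
#'
#' A 60-frame, two-class sequence whose run-length encoding is
#' (C1 x 10)(C2 x 2)(C1 x 8)(C2 x 2)(C1 x 8)(C2 x 2)(C1 x 8)(C2 x 20):
#' seven class changes, where every non-terminal C2 run is a short
#' 2-frame burst and the terminal C2 run is genuine. Both smoothers with
#' window `n = 5` reduce its seven class changes to one — the single true
#' transition into C2 — making it the standard demonstration that modal
#' and threshold smoothing suppress bursts without losing real changes.
#'
#' @return A label-sequence tibble of 60 frames over vocabulary C1, C2.
#' @examples
#' count_changes(example_smoothing_sequence())
#' count_changes(threshold_smooth(example_smoothing_sequence(), 5))
#' @export
example_smoothing_sequence <- function() {
  vocab <- label_vocabulary(c("C1", "C2"))
  label_sequence(
    rep(
      c("C1", "C2", "C1", "C2", "C1", "C2", "C1", "C2"),
      times = c(10L, 2L, 8L, 2L, 8L, 2L, 8L, 20L)
    ),
    vocab,
    video_id = "smoothing_example"
  )
}
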