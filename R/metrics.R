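#' Count class changes in a label sequence
#'
#' A class change is any frame whose label differs from the previous
#' frame's. Change counts are the building block of prediction
#' volatility: a stable prediction stream has roughly as many changes as
#' the ground truth, a volatile one has many more.
#'
#' @param seq Label-sequence tibble or factor.
#' @return Integer number of changes (0 for a constant sequence).
#' @examples
#' vocab <- label_vocabulary(c("A", "B"))
#' count_changes(label_sequence(c("A", "B", "A"), vocab))
#' @export
count_changes <- function(seq) {
  codes <- seq_codes(seq)
  if (length(codes) == 0L) {
    rlang::abort("sequence error: empty sequence")
  }
  sum(diff(codes) != 0L)
}

#' Prediction volatility
#'
#' The ratio of the number of class changes in the prediction to the
#' number of class changes in the ground truth. A perfectly stable,
#' correct prediction has volatility 1; frame-wise classifiers on
#' occlusion-prone video routinely reach volatilities in the tens or
#' hundreds, which is what temporal smoothing suppresses. The metric acts
#' as a proxy for prediction uncertainty.
#'
#' When the ground truth never changes class (a single-phase clip) the
#' ratio is undefined: the function messages and returns `NA`, and such
#' videos are excluded from aggregation.
#'
#' @param pred Predicted label-sequence tibble or factor, or a pair
#'   tibble (in which case `truth` is taken from it).
#' @param truth Ground-truth label-sequence tibble or factor.
#' @return A nonnegative ratio, or `NA` when undefined.
#' @examples
#' prediction_volatility(example_volatility_pair()) # 3 changes / 2 changes
#' @export
prediction_volatility <- function(pred, truth = NULL) {
  if (is.null(truth)) {
    validate_pair(pred)
    truth <- pred$truth
    pred <- pred$pred
  }
  n_pred <- count_changes(pred)
  n_truth <- count_changes(truth)
  if (n_truth == 0L) {
    rlang::inform("prediction volatility undefined: ground truth has no class changes")
    return(NA_real_)
  }
  n_pred / n_truth
}

# Internal: K x K contingency table of integer codes, rows = truth,
# cols = prediction.
contingency_codes <- function(truth, pred, K) {
  tab <- matrix(0, nrow = K, ncol = K)
  counts <- table(factor(truth, levels = seq_len(K)), factor(pred, levels = seq_len(K)))
  tab[] <- as.numeric(counts)
  tab
}

# Internal: per-class precision/recall/F1 and pooled summary statistics
# from a truth-by-prediction contingency table. The 0/0 convention for
# precision and recall is 0, matching common practice for absent classes.
metrics_from_contingency <- function(tab, labels = NULL) {
  K <- nrow(tab)
  if (is.null(labels)) labels <- as.character(seq_len(K))
  tp <- diag(tab)
  support <- rowSums(tab) # ground-truth frames per class
  predicted <- colSums(tab) # predicted frames per class
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  present <- support > 0
  w <- support[present] / sum(support[present])
  per_class <- tibble::tibble(
    label = labels,
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    support = as.integer(support)
  )
  # Confusion rows are indexed by the *predicted* class and normalised to
  # percentages, so the diagonal of row o is the precision of class o and
  # the off-diagonal cells are its false discovery rates. Rows for classes
  # never predicted are NA.
  confusion <- matrix(NA_real_, K, K, dimnames = list(predicted = labels, truth = labels))
  nz <- predicted > 0
  confusion[nz, ] <- 100 * t(tab)[nz, , drop = FALSE] / predicted[nz]
  list(
    per_class = per_class,
    confusion = confusion,
    weighted_f1 = sum(w * f1[present]),
    weighted_precision = sum(w * precision[present]),
    weighted_recall = sum(w * recall[present]),
    mean_accuracy = mean(recall[present]),
    n_frames = sum(tab)
  )
}

# Internal: just the pooled weighted-F1 (hot path of select_window).
weighted_f1_from_contingency <- function(tab) {
  tp <- diag(tab)
  support <- rowSums(tab)
  predicted <- colSums(tab)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  present <- support > 0
  sum(support[present] / sum(support[present]) * f1[present])
}

#' Evaluate a prediction against its ground truth
#'
#' Computes the frame-wise evaluation suite for one video: per-class
#' precision, recall and F1 with ground-truth supports; support-weighted
#' F1, precision and recall; mean-accuracy (macro-averaged per-class
#' recall over classes present in the ground truth); prediction
#' volatility; and a confusion matrix normalised over the predicted class
#' so its diagonal holds per-class precision and its off-diagonal cells
#' the false discovery rates, as percentages.
#'
#' Weighted metrics average over classes present in the ground truth,
#' weighted by their frame counts. Classes that are predicted but never
#' occur in the ground truth still get a per-class row (support 0) and a
#' confusion row, but do not enter the weighted means.
#'
#' @param pair A pair tibble (see [make_pair()]).
#' @return An object of class `workflow_eval`. [generics::glance()] gives
#'   the one-row summary, [generics::tidy()] the per-class table,
#'   [confusion_matrix()] the percentage matrix and
#'   [ggplot2::autoplot()] a confusion heatmap.
#' @examples
#' glance(evaluate_pair(example_volatility_pair()))
#' @export
evaluate_pair <- function(pair) {
  validate_pair(pair)
  K <- length(levels(pair$truth))
  tab <- contingency_codes(as.integer(pair$truth), as.integer(pair$pred), K)
  m <- metrics_from_contingency(tab, levels(pair$truth))
  vol <- withCallingHandlers(
    prediction_volatility(pair$pred, pair$truth),
    message = function(c) invokeRestart("muffleMessage")
  )
  if (is.na(vol)) {
    rlang::inform(paste0(
      "volatility undefined for video '",
      if ("video_id" %in% names(pair)) pair$video_id[1L] else "video",
      "' (ground truth has no class changes); excluded from aggregation"
    ))
  }
  structure(
    list(
      summary = tibble::tibble(
        weighted_f1 = m$weighted_f1,
        weighted_precision = m$weighted_precision,
        weighted_recall = m$weighted_recall,
        mean_accuracy = m$mean_accuracy,
        volatility = vol,
        n_frames = as.integer(m$n_frames)
      ),
      per_class = m$per_class,
      confusion = m$confusion,
      n_videos = 1L,
      n_undefined_volatility = as.integer(is.na(vol))
    ),
    class = "workflow_eval"
  )
}

#' Evaluate a set of videos as one pooled dataset
#'
#' Pools the frames of several (ground truth, prediction) pairs into a
#' single contingency table before computing the weighted and per-class
#' metrics, so long videos weigh more than short ones — the convention
#' used when scoring a whole training or validation fold. Volatility,
#' which is a per-video ratio, is instead averaged over the videos where
#' it is defined.
#'
#' @param pairs A list of pair tibbles sharing one vocabulary, or a
#'   single pair tibble.
#' @return A `workflow_eval` object, as [evaluate_pair()].
#' @export
evaluate_fold <- function(pairs) {
  pairs <- as_pair_list(pairs)
  K <- length(levels(pairs[[1L]]$truth))
  tabs <- purrr::map(pairs, ~ contingency_codes(as.integer(.x$truth), as.integer(.x$pred), K))
  m <- metrics_from_contingency(Reduce(`+`, tabs), levels(pairs[[1L]]$truth))
  vols <- purrr::map_dbl(pairs, function(p) {
    withCallingHandlers(
      prediction_volatility(p$pred, p$truth),
      message = function(c) invokeRestart("muffleMessage")
    )
  })
  n_undef <- sum(is.na(vols))
  if (n_undef > 0L) {
    rlang::inform(paste0(
      "volatility undefined for ", n_undef, " of ", length(vols),
      " videos (no ground-truth class changes); excluded from the fold mean"
    ))
  }
  structure(
    list(
      summary = tibble::tibble(
        weighted_f1 = m$weighted_f1,
        weighted_precision = m$weighted_precision,
        weighted_recall = m$weighted_recall,
        mean_accuracy = m$mean_accuracy,
        volatility = if (all(is.na(vols))) NA_real_ else mean(vols, na.rm = TRUE),
        n_frames = as.integer(m$n_frames)
      ),
      per_class = m$per_class,
      confusion = m$confusion,
      n_videos = length(pairs),
      n_undefined_volatility = as.integer(n_undef)
    ),
    class = "workflow_eval"
  )
}

#' Confusion matrix of an evaluation
#'
#' @param x A `workflow_eval` object.
#' @return K x K matrix of percentages; rows are predicted classes
#'   (rows sum to 100), columns are ground-truth classes. Rows for
#'   classes never predicted are `NA`.
#' @export
confusion_matrix <- function(x) {
  stopifnot(inherits(x, "workflow_eval"))
  x$confusion
}

#' @export
print.workflow_eval <- function(x, ...) {
  cat("Frame-wise workflow evaluation (", x$n_videos, " video",
    if (x$n_videos != 1L) "s", ", ", x$summary$n_frames, " frames)\n",
    sep = ""
  )
  s <- x$summary
  cat(sprintf(
    "  weighted-F1 %.4f | precision %.4f | recall %.4f | mean-accuracy %.4f\n",
    s$weighted_f1, s$weighted_precision, s$weighted_recall, s$mean_accuracy
  ))
  if (is.na(s$volatility)) {
    cat("  volatility undefined (no ground-truth class changes)\n")
  } else {
    cat(sprintf("  prediction volatility %.3f\n", s$volatility))
  }
  invisible(x)
}

#' @method glance workflow_eval
#' @export
glance.workflow_eval <- function(x, ...) {
  x$summary
}

#' @method tidy workflow_eval
#' @export
tidy.workflow_eval <- function(x, ...) {
  x$per_class
}

#' @method autoplot workflow_eval
#' @export
autoplot.workflow_eval <- function(object, ...) {
  df <- as.data.frame.table(object$confusion, responseName = "percent")
  names(df)[1:2] <- c("predicted", "truth")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted, fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$predicted))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", na.value = "grey90") +
    ggplot2::labs(
      x = "ground truth", y = "predicted",
      fill = "% of predicted",
      title = "Confusion matrix (diagonal = precision, off-diagonal = FDR)"
    )
}

#' Aggregate per-fold evaluations into cross-validation summaries
#'
#' Given one pooled evaluation per cross-validation fold, reports the
#' arithmetic mean and the population standard deviation of every summary
#' metric across folds — the "mean +/- sd" convention of cross-validated
#' benchmarks. Folds whose volatility is undefined (every video constant
#' in ground truth) are dropped from the volatility summary only.
#'
#' @param reports A list of `workflow_eval` objects (one per fold), or a
#'   data frame of their [generics::glance()] rows.
#' @return A tibble with columns `metric`, `mean`, `sd`, `n_folds`.
#' @export
aggregate_folds <- function(reports) {
  if (is.data.frame(reports)) {
    df <- tibble::as_tibble(reports)
  } else {
    if (!is.list(reports)) {
      rlang::abort("`reports` must be a list of workflow_eval objects or a data frame")
    }
    df <- purrr::map_dfr(reports, function(r) {
      if (inherits(r, "workflow_eval")) r$summary else tibble::as_tibble(r)
    })
  }
  if (nrow(df) < 2L) {
    rlang::abort("aggregation error: at least 2 folds are required")
  }
  metrics <- intersect(
    c("weighted_f1", "weighted_precision", "weighted_recall", "mean_accuracy", "volatility"),
    names(df)
  )
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  purrr::map_dfr(metrics, function(m) {
    v <- df[[m]]
    v <- v[!is.na(v)]
    tibble::tibble(
      metric = m,
      mean = if (length(v) > 0L) mean(v) else NA_real_,
      sd = if (length(v) > 0L) pop_sd(v) else NA_real_,
      n_folds = length(v)
    )
  })
}
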