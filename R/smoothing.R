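# Window sizes are bounded because the smoothers are meant for online use:
# a window of n frames delays a committed class change by up to n seconds
# at 1 Hz, and windows beyond a minute stop being clinically acceptable.
WINDOW_MAX <- 60L

check_window <- function(n) {
  if (length(n) != 1L || is.na(n) || n != as.integer(n) || n < 1L || n > WINDOW_MAX) {
    rlang::abort(paste0(
      "configuration error: window size n must be an integer in [1, ",
      WINDOW_MAX, "], got ", format(n)
    ))
  }
  as.integer(n)
}

# Accept either a sequence tibble or a bare factor, smooth the codes with
# `core`, and return the input's own shape.
smooth_dispatch <- function(x, core) {
  if (is.data.frame(x)) {
    validate_sequence(x, "pred")
    codes <- seq_codes(x)
    seq_with_codes(x, core(codes, nlevels(x$label)))
  } else if (is.factor(x)) {
    factor(levels(x)[core(as.integer(x), nlevels(x))], levels = levels(x))
  } else {
    rlang::abort("`pred` must be a label-sequence tibble or a factor")
  }
}

#' Modal temporal smoothing (sliding-window mode filter)
#'
#' Replaces the prediction at each frame `t >= n` with the modal class of
#' the window holding the current and the previous `n` frames (`n + 1`
#' frames in total). The first `n` frames pass through unchanged, so the
#' filter is causal and can run online. When two or more classes tie for
#' the mode, the most recent one wins: the tied class whose latest
#' occurrence in the window is closest to the current frame.
#'
#' Isolated misclassification spikes shorter than half the window are
#' outvoted by the surrounding correct predictions, which is what makes
#' the filter effective against the brief bursts of spurious labels that
#' endoscope withdrawal and scene occlusion produce.
#'
#' @param pred Label-sequence tibble (or bare factor) of predictions.
#' @param n Window size: the number of previous frames pooled with the
#'   current one. Must lie in `[1, 60]`.
#' @return The smoothed sequence, same type and length as `pred`.
#' @examples
#' vocab <- label_vocabulary(c("A", "B"))
#' x <- label_sequence(c("A", "A", "A", "B", "A", "A"), vocab)
#' modal_smooth(x, n = 2)$label
#' @seealso [threshold_smooth()], [select_window()]
#' @export
modal_smooth <- function(pred, n) {
  n <- check_window(n)
  smooth_dispatch(pred, function(codes, K) modal_core(codes, K, n))
}

# Vectorised windowed mode with most-recent tie-break. Window counts come
# from differenced cumulative indicator sums; the tie-break packs (count,
# latest occurrence) into one score so max.col resolves both at once.
modal_core <- function(codes, K, n) {
  nT <- length(codes)
  if (nT <= n) {
    return(codes) # whole sequence is inside the passthrough prefix
  }
  w <- n + 1L
  ind <- matrix(0L, nrow = nT, ncol = K)
  ind[cbind(seq_len(nT), codes)] <- 1L
  cum <- apply(ind, 2L, cumsum)
  wins <- cum
  if (nT > w) {
    wins[(w + 1L):nT, ] <- cum[(w + 1L):nT, , drop = FALSE] - cum[1:(nT - w), , drop = FALSE]
  }
  pos <- matrix(0L, nrow = nT, ncol = K)
  pos[cbind(seq_len(nT), codes)] <- seq_len(nT)
  last <- apply(pos, 2L, cummax)
  # score = count * (nT + 1) + latest occurrence; occurrences are distinct
  # across classes present in the window, so the argmax is unique.
  score <- wins * (nT + 1) + last
  out <- codes
  rows <- (n + 1L):nT
  out[rows] <- max.col(score[rows, , drop = FALSE], ties.method = "first")
  out
}

#' Threshold temporal smoothing (hysteresis filter)
#'
#' Commits to the class of frame `t >= n` only when the current and the
#' previous `n` predictions all agree (`n + 1` identical frames in a row);
#' otherwise the output holds its previous value. The first `n` frames
#' pass through unchanged. The output therefore changes class only after a
#' sustained run of consistent predictions — a debounce, in signal-
#' processing terms — so any error burst shorter than `n + 1` frames is
#' ignored entirely, at the cost of an `n`-frame lag after every genuine
#' class change.
#'
#' @inheritParams modal_smooth
#' @return The smoothed sequence, same type and length as `pred`.
#' @examples
#' vocab <- label_vocabulary(c("A", "B"))
#' x <- label_sequence(c("A", "B", "A", "B", "B", "B"), vocab)
#' threshold_smooth(x, n = 2)$label
#' @seealso [modal_smooth()], [select_window()]
#' @export
threshold_smooth <- function(pred, n) {
  n <- check_window(n)
  smooth_dispatch(pred, function(codes, K) threshold_core(codes, n))
}

# The window x[t-n..t] is uniform iff the run of identical values ending
# at t has length >= n + 1; committed frames keep their own value and the
# rest carry the last committed value forward.
threshold_core <- function(codes, n) {
  nT <- length(codes)
  if (nT <= n) {
    return(codes)
  }
  runlen <- sequence(rle(codes)$lengths)
  t_idx <- seq_len(nT)
  committed <- t_idx <= n | runlen >= n + 1L
  out_src <- cummax(ifelse(committed, t_idx, 0L))
  codes[out_src]
}

#' Select the smoothing window on a training set
#'
#' Scans window sizes over `n_range` (by default the full `[1, 60]`),
#' applies the chosen smoother to every training prediction, scores each
#' window by the weighted-F1 of the smoothed predictions against the
#' ground truths, and returns the best window. By default all training
#' frames are pooled into one contingency table before scoring, treating
#' the training videos as a single dataset; `pooled = FALSE` averages
#' per-video weighted-F1 instead. Ties go to the smallest window, which
#' prefers the shorter decision lag.
#'
#' @param pairs A list of pair tibbles (see [make_pair()]), or a single
#'   pair tibble.
#' @param kind `"modal"` or `"threshold"`.
#' @param n_range Integer vector `c(min, max)` of window sizes to scan.
#' @param pooled Pool frames across videos before scoring (default) or
#'   average per-video scores.
#' @return An object of class `window_selection` with fields `kind`,
#'   `best_n`, `best_score` and a `scores` tibble (`n`, `weighted_f1`).
#'   [generics::tidy()] returns the score table; [ggplot2::autoplot()]
#'   plots it.
#' @export
select_window <- function(pairs, kind = c("modal", "threshold"),
                          n_range = c(1L, WINDOW_MAX), pooled = TRUE) {
  kind <- rlang::arg_match(kind)
  pairs <- as_pair_list(pairs)
  if (length(pairs) == 0L) {
    rlang::abort("selection error: empty training set")
  }
  lo <- check_window(n_range[1L])
  hi <- check_window(n_range[length(n_range)])
  if (hi < lo) {
    rlang::abort("configuration error: n_range must satisfy min <= max")
  }
  smoother <- if (kind == "modal") modal_smooth else threshold_smooth
  truth_codes <- purrr::map(pairs, ~ seq_codes(.x$truth))
  pred_codes <- purrr::map(pairs, ~ seq_codes(.x$pred))
  K <- length(levels(pairs[[1L]]$truth))
  score_one <- function(n) {
    smoothed <- purrr::map(pred_codes, function(p) {
      if (kind == "modal") modal_core(p, K, n) else threshold_core(p, n)
    })
    if (pooled) {
      tab <- Reduce(`+`, purrr::map2(truth_codes, smoothed, ~ contingency_codes(.x, .y, K)))
      weighted_f1_from_contingency(tab)
    } else {
      mean(purrr::map2_dbl(truth_codes, smoothed, function(g, p) {
        weighted_f1_from_contingency(contingency_codes(g, p, K))
      }))
    }
  }
  ns <- lo:hi
  scores <- purrr::map_dbl(ns, score_one)
  best <- ns[which.max(scores)] # which.max: first maximum = smallest n
  structure(
    list(
      kind = kind,
      best_n = best,
      best_score = max(scores),
      pooled = pooled,
      scores = tibble::tibble(n = ns, weighted_f1 = scores)
    ),
    class = "window_selection"
  )
}

#' @export
print.window_selection <- function(x, ...) {
  cat("Smoothing window selection (", x$kind, ")\n", sep = "")
  cat("  scanned n in [", min(x$scores$n), ", ", max(x$scores$n), "]",
    if (x$pooled) ", pooled weighted-F1\n" else ", per-video mean weighted-F1\n",
    sep = ""
  )
  cat(sprintf("  best n = %d (weighted-F1 %.4f)\n", x$best_n, x$best_score))
  invisible(x)
}

#' @method tidy window_selection
#' @export
tidy.window_selection <- function(x, ...) {
  x$scores
}

#' @method glance window_selection
#' @export
glance.window_selection <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, best_n = x$best_n,
    best_score = x$best_score, pooled = x$pooled
  )
}

#' @method autoplot window_selection
#' @export
autoplot.window_selection <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$n, y = .data$weighted_f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = object$scores[object$scores$n == object$best_n, ],
      colour = "red", size = 2
    ) +
    ggplot2::labs(
      x = "window size n (frames)", y = "training weighted-F1",
      title = paste0("Window selection (", object$kind, " smoothing)"),
      subtitle = paste0("best n = ", object$best_n)
    )
}

# Internal: normalise `pairs` to a list of validated pair tibbles.
as_pair_list <- function(pairs) {
  if (is.data.frame(pairs)) {
    pairs <- list(pairs)
  }
  if (!is.list(pairs)) {
    rlang::abort("`pairs` must be a pair tibble or a list of pair tibbles")
  }
  purrr::walk(pairs, validate_pair)
  if (length(pairs) > 1L) {
    vocabs <- purrr::map(pairs, ~ levels(.x$truth))
    if (!all(purrr::map_lgl(vocabs, identical, vocabs[[1L]]))) {
      rlang::abort("pairing error: all pairs must share one vocabulary")
    }
  }
  pairs
}
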