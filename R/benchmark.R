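#' Standard synthetic benchmark scenario
#'
#' The default conditions used to compare smoothers head-to-head on
#' synthetic data: a 7-step workflow with occasional skips and revisits
#' and heavy-tailed (log-normal, median 600 s) step durations, corrupted
#' by a neighbour-biased channel with 0.85 diagonal plus occlusion bursts
#' covering roughly 10% of frames.
#'
#' @return A list with elements `workflow` (a [workflow_model()]) and
#'   `noise` (a [noise_model()]).
#' @export
standard_scenario <- function() {
  vocab <- label_vocabulary(paste0("S", 1:7), task = "steps")
  list(
    workflow = workflow_model(vocab),
    noise = noise_model(neighbor_confusion(7L, diag = 0.85))
  )
}

#' Cross-validated smoothing benchmark on synthetic data
#'
#' Simulates `folds x videos_per_fold` synthetic videos and runs the full
#' evaluation protocol: for each fold, the other folds' videos form the
#' training set on which the modal and threshold windows are tuned
#' ([select_window()]) and the HMM post-processor is fitted
#' ([fit_hmm()]); each post-processor is then applied to the fold's
#' predictions and scored with [evaluate_fold()]. Per-fold pooled scores
#' are aggregated to mean +/- population sd with [aggregate_folds()],
#' giving one row per (method, metric).
#'
#' @param workflow A [workflow_model()]; defaults to the
#'   [standard_scenario()] workflow.
#' @param noise A [noise_model()]; defaults to the standard scenario's.
#' @param folds Number of cross-validation folds (>= 2).
#' @param videos_per_fold Simulated videos per fold.
#' @param seed Master integer seed; the whole benchmark is a pure
#'   function of its arguments.
#' @param n_range Window range scanned by the tuner.
#' @param lookahead HMM decoding lookahead in frames.
#' @param alpha HMM pseudocount.
#' @param methods Subset of `c("raw", "modal", "threshold", "hmm")`.
#' @return An object of class `wf_benchmark`: `results` (method x metric
#'   tibble with mean, sd), `per_fold` (per-fold glance rows), `windows`
#'   (chosen n per fold), and the configuration. [generics::tidy()]
#'   returns `results`; [ggplot2::autoplot()] plots them.
#' @export
run_benchmark <- function(workflow = NULL, noise = NULL,
                          folds = 5L, videos_per_fold = 2L, seed = 1L,
                          n_range = c(1L, 60L), lookahead = 5L, alpha = 1,
                          methods = c("raw", "modal", "threshold", "hmm")) {
  if (folds < 2L) {
    rlang::abort("configuration error: folds must be >= 2")
  }
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(workflow) || is.null(noise)) {
    sc <- standard_scenario()
    if (is.null(workflow)) workflow <- sc$workflow
    if (is.null(noise)) noise <- sc$noise
  }
  n_videos <- folds * videos_per_fold
  pairs <- simulate_pairs(workflow, noise, n_videos, seed = seed)
  fold_of <- rep(seq_len(folds), each = videos_per_fold)

  smooth_pair <- function(pair, fn) {
    out <- pair
    out$pred <- fn(pair_pred_sequence(pair))$label
    out
  }
  quiet_fold <- function(ps) {
    withCallingHandlers(evaluate_fold(ps), message = function(c) invokeRestart("muffleMessage"))
  }

  per_fold <- list()
  windows <- list()
  for (f in seq_len(folds)) {
    train <- pairs[fold_of != f]
    val <- pairs[fold_of == f]
    fits <- list()
    if ("modal" %in% methods) {
      fits$modal <- select_window(train, "modal", n_range = n_range)
    }
    if ("threshold" %in% methods) {
      fits$threshold <- select_window(train, "threshold", n_range = n_range)
    }
    if ("hmm" %in% methods) {
      fits$hmm <- fit_hmm(train, alpha = alpha, lookahead = lookahead)
    }
    for (m in methods) {
      val_m <- switch(m,
        raw = val,
        modal = purrr::map(val, smooth_pair, fn = function(s) modal_smooth(s, fits$modal$best_n)),
        threshold = purrr::map(val, smooth_pair, fn = function(s) {
          threshold_smooth(s, fits$threshold$best_n)
        }),
        hmm = purrr::map(val, smooth_pair, fn = function(s) hmm_decode_online(fits$hmm, s))
      )
      g <- glance(quiet_fold(val_m))
      per_fold[[length(per_fold) + 1L]] <- dplyr::mutate(g, method = m, fold = f, .before = 1L)
    }
    windows[[f]] <- tibble::tibble(
      fold = f,
      modal_n = if ("modal" %in% methods) fits$modal$best_n else NA_integer_,
      threshold_n = if ("threshold" %in% methods) fits$threshold$best_n else NA_integer_
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  results <- per_fold |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(~ aggregate_folds(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(method = factor(.data$method, levels = methods)) |>
    dplyr::arrange(.data$method)
  structure(
    list(
      results = results,
      per_fold = per_fold,
      windows = dplyr::bind_rows(windows),
      config = list(
        folds = folds, videos_per_fold = videos_per_fold, seed = seed,
        n_range = n_range, lookahead = lookahead, alpha = alpha,
        methods = methods, workflow = workflow, noise = noise
      )
    ),
    class = "wf_benchmark"
  )
}

#' @export
print.wf_benchmark <- function(x, ...) {
  cat(sprintf(
    "Synthetic smoothing benchmark: %d folds x %d videos, seed %d\n",
    x$config$folds, x$config$videos_per_fold, x$config$seed
  ))
  wide <- x$results |>
    dplyr::mutate(cell = sprintf("%.3f+/-%.3f", .data$mean, .data$sd)) |>
    dplyr::select("method", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' @method tidy wf_benchmark
#' @export
tidy.wf_benchmark <- function(x, ...) {
  x$results
}

#' @method glance wf_benchmark
#' @export
glance.wf_benchmark <- function(x, ...) {
  x$results |>
    dplyr::select("method", "metric", "mean") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "mean")
}

#' @method autoplot wf_benchmark
#' @export
autoplot.wf_benchmark <- function(object, ...) {
  ggplot2::ggplot(
    object$results,
    ggplot2::aes(x = .data$method, y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "mean +/- sd across folds",
      title = "Smoothing benchmark on synthetic workflow data"
    )
}

#' Plot a ground truth / prediction timeline
#'
#' Step-style timeline of one or more label streams over video time — the
#' standard way to eyeball volatility and the effect of a smoother.
#'
#' @param ... Named label-sequence tibbles (or pair tibbles, whose two
#'   columns are shown as separate tracks), all over one vocabulary.
#' @return A ggplot object.
#' @examples
#' x <- example_smoothing_sequence()
#' plot_timeline(raw = x, threshold = threshold_smooth(x, 5))
#' @export
plot_timeline <- function(...) {
  tracks <- rlang::list2(...)
  if (length(tracks) == 0L) {
    rlang::abort("plot error: supply at least one sequence")
  }
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    names(tracks) <- paste0("track", seq_along(tracks))
  }
  df <- purrr::imap_dfr(tracks, function(x, nm) {
    if (is.data.frame(x) && all(c("truth", "pred") %in% names(x))) {
      dplyr::bind_rows(
        tibble::tibble(
          track = paste0(nm, "_truth"),
          frame = seq_len(nrow(x)) - 1L, label = x$truth
        ),
        tibble::tibble(
          track = paste0(nm, "_pred"),
          frame = seq_len(nrow(x)) - 1L, label = x$pred
        )
      )
    } else {
      tibble::tibble(
        track = nm,
        frame = seq_len(nrow(x)) - 1L, label = x$label
      )
    }
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$frame,
    y = as.integer(.data$label),
    colour = .data$track
  )) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(df$label)),
      labels = levels(df$label)
    ) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL)
}
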