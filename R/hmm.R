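#' Fit a discrete HMM post-processor from labelled training videos
#'
#' Supervised maximum-likelihood estimation with a Laplace pseudocount:
#' hidden states are the ground-truth workflow classes and observations
#' are the classifier's frame-wise predictions, so every distribution is a
#' smoothed count over the completed training sequences.
#'
#' * initial distribution: `pi[s] proportional to alpha + #sequences
#'   starting in ground-truth state s`;
#' * transitions: `A[s, s'] proportional to alpha + #frame-to-frame
#'   ground-truth transitions s -> s'`;
#' * emissions: `B[s, o] proportional to alpha + #frames with ground truth
#'   s and prediction o`.
#'
#' The pseudocount `alpha > 0` keeps every probability strictly positive,
#' which guarantees the online decoder always has an admissible path. The
#' self-transition mass that surgical workflows concentrate on the
#' diagonal of `A` is what lets the decoder absorb short misclassification
#' bursts.
#'
#' @param pairs List of pair tibbles (ground truth + prediction) sharing
#'   one vocabulary, or a single pair tibble.
#' @param alpha Additive pseudocount, `> 0`. Default 1.
#' @param lookahead Default decoding lookahead `L` in frames, stored with
#'   the model (see [hmm_decode_online()]). Default 5.
#' @return An object of class `hmm_post` with fields `labels`, `pi`, `A`,
#'   `B`, `alpha`, `lookahead`.
#' @examples
#' pair <- example_volatility_pair()
#' fit_hmm(list(pair), alpha = 1, lookahead = 5)
#' @export
fit_hmm <- function(pairs, alpha = 1, lookahead = 5L) {
  pairs <- tryCatch(as_pair_list(pairs), error = function(e) {
    rlang::abort(paste0("estimation error: ", conditionMessage(e)))
  })
  if (length(pairs) == 0L) {
    rlang::abort("estimation error: empty training set")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    rlang::abort("estimation error: alpha must be a positive number")
  }
  if (lookahead < 0) {
    rlang::abort("estimation error: lookahead must be >= 0")
  }
  labels <- levels(pairs[[1L]]$truth)
  K <- length(labels)
  pi_count <- numeric(K)
  A_count <- matrix(0, K, K, dimnames = list(labels, labels))
  B_count <- matrix(0, K, K, dimnames = list(labels, labels))
  for (p in pairs) {
    g <- as.integer(p$truth)
    o <- as.integer(p$pred)
    pi_count[g[1L]] <- pi_count[g[1L]] + 1
    if (length(g) > 1L) {
      steps <- table(
        factor(g[-length(g)], levels = seq_len(K)),
        factor(g[-1L], levels = seq_len(K))
      )
      A_count <- A_count + as.numeric(steps)
    }
    B_count <- B_count + as.numeric(table(
      factor(g, levels = seq_len(K)), factor(o, levels = seq_len(K))
    ))
  }
  normalize <- function(x) x / sum(x)
  pi <- normalize(pi_count + alpha)
  A <- t(apply(A_count + alpha, 1L, normalize))
  B <- t(apply(B_count + alpha, 1L, normalize))
  names(pi) <- labels
  dimnames(A) <- dimnames(B) <- list(labels, labels)
  structure(
    list(
      labels = labels, pi = pi, A = A, B = B,
      alpha = alpha, lookahead = as.integer(lookahead)
    ),
    class = "hmm_post"
  )
}

#' Online Viterbi decoding with a fixed lookahead
#'
#' Decodes a predicted label sequence through the fitted HMM under the
#' online constraint: the state reported at frame `t` is position `t` of
#' the Viterbi-optimal path for the observation prefix up to frame
#' `min(t + L, T - 1)`. With `L = 0` the decoder is strictly causal; every
#' extra frame of lookahead trades decision latency (L seconds at 1 Hz)
#' for stability, and `L >= T` reproduces classical full-sequence Viterbi
#' decoding.
#'
#' All dynamic programming runs in log space; ties in the maximisation
#' break toward the lower state index so decoding is deterministic across
#' platforms.
#'
#' @param model An `hmm_post` object from [fit_hmm()] (or [read_hmm()]).
#' @param pred Label-sequence tibble (or factor) of predictions over the
#'   model's vocabulary.
#' @param lookahead Lookahead `L` in frames; defaults to the value stored
#'   in the model.
#' @return The decoded sequence, same type and length as `pred`.
#' @export
hmm_decode_online <- function(model, pred, lookahead = NULL) {
  stopifnot(inherits(model, "hmm_post"))
  L <- if (is.null(lookahead)) model$lookahead else as.integer(lookahead)
  if (L < 0) {
    rlang::abort("configuration error: lookahead must be >= 0")
  }
  vocab <- seq_vocab(pred)
  if (!identical(as.character(vocab), as.character(model$labels))) {
    rlang::abort("decoding error: sequence vocabulary does not match the model's labels")
  }
  smooth_dispatch(pred, function(codes, K) viterbi_online(model, codes, L))
}

# One forward Viterbi pass (delta = best log-score, psi = argmax
# backpointers) serves every horizon: delta[t, ] depends only on the
# observation prefix, so the state reported at frame t is obtained by
# backtracking at most L steps from the argmax at horizon min(t + L, T).
viterbi_online <- function(model, obs, L) {
  K <- length(model$labels)
  nT <- length(obs)
  logpi <- log(model$pi)
  logA <- log(model$A)
  logB <- log(model$B)
  delta <- matrix(-Inf, nT, K)
  psi <- matrix(1L, nT, K)
  delta[1L, ] <- logpi + logB[, obs[1L]]
  if (nT > 1L) {
    for (t in 2:nT) {
      cand <- delta[t - 1L, ] + logA # rows = previous state, cols = current
      best_prev <- max.col(t(cand), ties.method = "first")
      delta[t, ] <- cand[cbind(best_prev, seq_len(K))] + logB[, obs[t]]
      psi[t, ] <- best_prev
    }
  }
  out <- integer(nT)
  for (t in seq_len(nT)) {
    h <- min(t + L, nT)
    if (!is.finite(max(delta[h, ]))) {
      rlang::abort("decoding error: no admissible state path for the observed sequence")
    }
    s <- which.max(delta[h, ])
    while (h > t) {
      s <- psi[h, s]
      h <- h - 1L
    }
    out[t] <- s
  }
  out
}

#' @export
print.hmm_post <- function(x, ...) {
  cat("Discrete HMM post-processor:", length(x$labels), "states (",
    paste(x$labels, collapse = ", "), ")\n",
    sep = " "
  )
  cat(sprintf(
    "  pseudocount alpha = %g, lookahead L = %d frames\n",
    x$alpha, x$lookahead
  ))
  cat(sprintf(
    "  mean self-transition %.3f, mean diagonal emission %.3f\n",
    mean(diag(x$A)), mean(diag(x$B))
  ))
  invisible(x)
}

#' @method tidy hmm_post
#' @export
tidy.hmm_post <- function(x, ...) {
  K <- length(x$labels)
  dplyr::bind_rows(
    tibble::tibble(
      component = "initial", from = NA_character_,
      to = x$labels, probability = as.numeric(x$pi)
    ),
    tibble::tibble(
      component = "transition",
      from = rep(x$labels, times = K),
      to = rep(x$labels, each = K),
      probability = as.numeric(x$A)
    ),
    tibble::tibble(
      component = "emission",
      from = rep(x$labels, times = K),
      to = rep(x$labels, each = K),
      probability = as.numeric(x$B)
    )
  )
}

#' @method glance hmm_post
#' @export
glance.hmm_post <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$labels),
    alpha = x$alpha,
    lookahead = x$lookahead,
    mean_self_transition = mean(diag(x$A)),
    mean_diag_emission = mean(diag(x$B))
  )
}

#' Read / write an HMM post-processor as JSON
#'
#' The serialised form is a JSON object with keys `pi`, `A`, `B`,
#' `alpha`, `lookahead` and `labels`; matrices are stored row-major as
#' nested arrays. Reading a written model reproduces it exactly up to
#' double-precision printing.
#'
#' @param model An `hmm_post` object.
#' @param path File path of the JSON model.
#' @return `read_hmm()` returns an `hmm_post`; `write_hmm()` returns
#'   `path` invisibly.
#' @export
write_hmm <- function(model, path) {
  stopifnot(inherits(model, "hmm_post"))
  jsonlite::write_json(
    list(
      labels = as.character(model$labels),
      pi = as.numeric(model$pi),
      A = unname(apply(model$A, 1L, as.numeric, simplify = FALSE)),
      B = unname(apply(model$B, 1L, as.numeric, simplify = FALSE)),
      alpha = model$alpha,
      lookahead = model$lookahead
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("I/O error: model file not found: ", path))
  }
  j <- jsonlite::fromJSON(path)
  labels <- as.character(j$labels)
  K <- length(labels)
  A <- matrix(as.numeric(t(j$A)), K, K, byrow = TRUE, dimnames = list(labels, labels))
  B <- matrix(as.numeric(t(j$B)), K, K, byrow = TRUE, dimnames = list(labels, labels))
  # fromJSON returns row-major nested arrays as a K x K matrix already
  if (is.matrix(j$A)) A <- matrix(as.numeric(j$A), K, K, dimnames = list(labels, labels))
  if (is.matrix(j$B)) B <- matrix(as.numeric(j$B), K, K, dimnames = list(labels, labels))
  model <- structure(
    list(
      labels = labels,
      pi = stats::setNames(as.numeric(j$pi), labels),
      A = A, B = B,
      alpha = as.numeric(j$alpha),
      lookahead = as.integer(j$lookahead)
    ),
    class = "hmm_post"
  )
  validate_hmm(model)
  model
}

# Internal: row-stochasticity and parameter checks.
validate_hmm <- function(model) {
  K <- length(model$labels)
  ok <- function(v) all(v >= 0) && abs(sum(v) - 1) < 1e-9
  if (!ok(model$pi)) rlang::abort("model error: pi is not a probability distribution")
  for (s in seq_len(K)) {
    if (!ok(model$A[s, ])) rlang::abort("model error: transition row is not a distribution")
    if (!ok(model$B[s, ])) rlang::abort("model error: emission row is not a distribution")
  }
  if (model$alpha <= 0) rlang::abort("model error: alpha must be positive")
  if (model$lookahead < 0) rlang::abort("model error: lookahead must be >= 0")
  invisible(model)
}
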