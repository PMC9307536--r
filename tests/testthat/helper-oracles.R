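# Independent reference implementations used to cross-check the package.
# They are deliberately written the slow, literal way (recount every
# window, enumerate every path) and share no code with the package.

# Windowed mode with most-recent tie-break, recomputed from scratch at
# every frame.
oracle_modal <- function(codes, n) {
  out <- codes
  for (t in seq_along(codes)) {
    if (t - 1 < n) next # 0-based t < n: passthrough
    win <- codes[(t - n):t]
    counts <- table(win)
    tied <- as.integer(names(counts)[counts == max(counts)])
    if (length(tied) == 1L) {
      out[t] <- tied
    } else {
      latest <- sapply(tied, function(cl) max(which(win == cl)))
      out[t] <- tied[which.max(latest)]
    }
  }
  out
}

# Literal hysteresis state machine: commit only when the last n+1 raw
# predictions agree, otherwise repeat the previous output.
oracle_threshold <- function(codes, n) {
  out <- integer(length(codes))
  for (t in seq_along(codes)) {
    if (t - 1 < n) {
      out[t] <- codes[t]
    } else {
      win <- codes[(t - n):t]
      out[t] <- if (length(unique(win)) == 1L) win[1L] else out[t - 1L]
    }
  }
  out
}

# Exhaustive max-probability state-path search: scores all K^T paths in
# log space and returns every optimal path (distinct paths can tie
# exactly, e.g. by swapping a 2-cycle across identical observations), so
# callers check optimality rather than assuming a unique winner.
oracle_viterbi <- function(pi, A, B, obs, tol = 1e-9) {
  K <- length(pi)
  nT <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), nT))[, nT:1, drop = FALSE])
  score <- apply(paths, 1L, function(s) {
    lp <- log(pi[s[1L]]) + log(B[s[1L], obs[1L]])
    if (nT > 1L) {
      for (t in 2:nT) {
        lp <- lp + log(A[s[t - 1L], s[t]]) + log(B[s[t], obs[t]])
      }
    }
    lp
  })
  best <- max(score)
  list(
    logp = best,
    paths = unname(paths[score >= best - tol, , drop = FALSE])
  )
}

# TRUE iff `path` is one of the oracle's optimal paths.
oracle_accepts <- function(oracle, path) {
  any(apply(oracle$paths, 1L, identical, y = as.integer(path)))
}

# Random label-sequence codes.
random_codes <- function(len, K) {
  sample.int(K, len, replace = TRUE)
}

codes_to_seq <- function(codes, K, video_id = "t") {
  label_sequence(paste0("k", codes), paste0("k", seq_len(K)), video_id = video_id)
}

# Random row-stochastic matrix with no ties (generic entries).
random_stochastic <- function(K) {
  m <- matrix(stats::rgamma(K * K, shape = 2), K, K)
  m / rowSums(m)
}

random_hmm <- function(K, lookahead = 5L) {
  pi <- stats::rgamma(K, shape = 2)
  pi <- pi / sum(pi)
  labels <- paste0("k", seq_len(K))
  A <- random_stochastic(K)
  B <- random_stochastic(K)
  dimnames(A) <- dimnames(B) <- list(labels, labels)
  names(pi) <- labels
  structure(
    list(
      labels = labels, pi = pi, A = A, B = B,
      alpha = 1, lookahead = as.integer(lookahead)
    ),
    class = "hmm_post"
  )
}

# Sample (states, emissions) from a known HMM, literal forward loop.
sample_hmm_sequence <- function(pi, A, B, len) {
  K <- length(pi)
  states <- integer(len)
  obs <- integer(len)
  states[1L] <- sample.int(K, 1L, prob = pi)
  obs[1L] <- sample.int(K, 1L, prob = B[states[1L], ])
  for (t in seq_len(len)[-1L]) {
    states[t] <- sample.int(K, 1L, prob = A[states[t - 1L], ])
    obs[t] <- sample.int(K, 1L, prob = B[states[t], ])
  }
  list(states = states, obs = obs)
}

# Ground truth + burst-only corruption used by the exact-recovery checks:
# gt changes separated by > n frames, error bursts of length <= n, every
# burst separated from every other burst and change point by > n frames,
# and a clean first n+1 frames.
make_burst_case <- function(n, K = 3L, n_runs = 4L, run_len = 4L * n + 8L) {
  gt <- unlist(lapply(seq_len(n_runs), function(i) {
    rep(((i - 1L) %% K) + 1L, run_len)
  }))
  pred <- gt
  burst_starts <- c()
  t <- 2L * n + 2L
  while (t + n <= length(gt)) {
    run_id <- (t - 1L) %/% run_len
    pos_in_run <- t - run_id * run_len
    # keep bursts away from run boundaries so separations stay > n
    if (pos_in_run > n + 1L && pos_in_run + n < run_len - n) {
      burst_starts <- c(burst_starts, t)
      t <- t + 3L * n + 5L
    } else {
      t <- t + 1L
    }
  }
  for (s in burst_starts) {
    len <- 1L + (s %% n)
    span <- s:(s + len - 1L)
    pred[span] <- (gt[span] %% K) + 1L # a wrong class
  }
  list(gt = gt, pred = pred, bursts = burst_starts, K = K)
}
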