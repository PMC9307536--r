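---
title: "Stabilising frame-wise workflow predictions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilising frame-wise workflow predictions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfsmooth)
```

## Setting

A workflow recogniser labels every second of surgical video with one of
K classes — the phase or step of the operation. Errors in such output
are not exchangeable with errors in ordinary classification: a stream
that is right 80% of the time but flips class every few seconds is far
less usable intra-operatively than one with the same accuracy and a
handful of clean transitions. `wfsmooth` treats the classifier as a
black box and works entirely on its label stream: it quantifies the
flipping (prediction volatility), removes it (temporal smoothing
functions and an HMM post-processor), and scores the result
(support-weighted F1 and friends). A synthetic generator supplies
controlled inputs with the failure modes seen in real endoscopic video.

## The smoothers

Let $x_t$ be the predicted class at frame $t$ (1 Hz, $t = 0, 1, \dots$)
and $y_t$ the smoothed output. Both smoothers pass frames $t < n$
through unchanged and never look ahead.

**Modal, $M_n$.** $y_t$ is the mode of the window
$x_{t-n}, \dots, x_t$ — the current and previous $n$ frames, i.e.
$n + 1$ values. The window length being $n+1$, not $n$, is an easy
off-by-one: it is fixed by the contract that $M_1$ applied to a
two-frame window $\{a, b\}$ with $a \neq b$ is a tie. Ties resolve to
the tied class whose most recent occurrence is closest to $t$ ("most
recent wins"). This reading makes $M_1$ exactly the identity and makes
the window-5 worked example below reproducible; it is also
deterministic, which any tie rule here must be.

**Threshold, $T_n$.** $y_t = x_t$ when
$x_{t-n} = \dots = x_t$; otherwise $y_t = y_{t-1}$. The holdover chains
on the smoothed stream, not the raw one — holding the previous *raw*
prediction would let a two-class oscillation leak through, and the
filter would not debounce at all. Consequences worth stating plainly:

* any error burst shorter than $n+1$ frames is removed entirely;
* every genuine class change is committed exactly $n$ frames late (the
  deterministic lag of $T_n$), so even a perfect input stream scores
  slightly below 1 after threshold smoothing whenever the ground truth
  changes class;
* committed change points are always at least $n+1$ frames apart, so
  the output's change rate is bounded by construction.

The two differ exactly where predictions oscillate rapidly between two
classes: $M_n$ switches once the newcomer outnumbers the incumbent in
the window, $T_n$ waits for an uninterrupted run. That makes $T_n$ the
stronger volatility reducer, and on our benchmarks the slightly better
F1 performer too.

```{r worked-example}
x <- example_smoothing_sequence() # 7 class changes, one genuine
c(
  raw = count_changes(x),
  M5 = count_changes(modal_smooth(x, 5)),
  T5 = count_changes(threshold_smooth(x, 5))
)
```

**Window selection.** `select_window()` scans $n \in [1, 60]$ on
training pairs and keeps the smallest $n$ maximising weighted-F1. The
upper bound is an online-use constraint: at 1 Hz a 60-frame window
already means a minute of decision lag. Training frames are pooled into
one contingency table before scoring (the training set is treated as a
single dataset); per-video averaging is available via `pooled = FALSE`
and matters only when video lengths are very unbalanced. Ties go to the
smallest window because lag is the cost axis.

## The HMM post-processor

`fit_hmm()` estimates a discrete HMM whose hidden states are the true
classes and whose observations are the classifier's predictions, by
supervised counting over completed training videos with a Laplace
pseudocount $\alpha$ (default 1): initial probabilities from sequence
starts, transitions from ground-truth frame pairs, emissions from
(truth, prediction) frames. Nothing is iterated — with labelled
training data the maximum-likelihood counts are closed-form, and
Baum–Welch would only blur them. $\alpha > 0$ guarantees strictly
positive rows, so decoding can never paint itself into a zero-probability
corner. A corner case fixed by the estimator: a state observed only at
the end of every training sequence has no outgoing transitions, and its
transition row is then the uniform distribution in the $\alpha \to 0$
limit — the counts say nothing, and the estimator says so.

`hmm_decode_online()` reports at frame $t$ the state at position $t$ of
the Viterbi-optimal path for the observations up to
$\min(t + L,\, T-1)$. One forward pass computes the log-space scores
and backpointers for the whole sequence; each output frame then
backtracks at most $L$ steps from the argmax at its horizon, so decoding
is $O(TK^2 + TL)$ rather than $T$ separate Viterbi runs. $L$ trades
latency for stability ($L$ seconds at 1 Hz; default $L = 5$), and
$L \ge T$ reproduces classical full-sequence Viterbi exactly. Ties in
every maximisation break toward the lower state index for
platform-independent determinism; note that genuinely tied optimal
paths do occur (swapping a 2-cycle across identical observations leaves
the path probability unchanged), which is why our oracle tests check
optimality of the returned path rather than assuming a unique winner.

Both phases and steps use this categorical-emission HMM. A
Gaussian-emission variant over categorical predictions would need a
feature mapping there is no principled default for, so it is out of
scope.

## Evaluation suite

* **Volatility** = (prediction class changes) / (ground-truth class
  changes). A video whose ground truth never changes class has no
  denominator; the value is reported as `NA`, messaged, and excluded
  from aggregation — silently mapping it to 0 or infinity would bias
  fold means in opposite directions.
* **Weighted F1 / precision / recall** are support-weighted means over
  classes present in the ground truth. Weighted recall is algebraically
  the plain frame accuracy (the test suite asserts this numerically).
* **Mean-accuracy** is implemented as macro-averaged per-class recall
  over classes present in the ground truth. The term has no universal
  definition; this reading is distinct from weighted recall, which is
  why both are reported.
* **Confusion matrices** are normalised over the *predicted* class:
  the diagonal of row $o$ is the precision of class $o$ and the
  off-diagonals are false discovery rates, in percentages. Classes
  never predicted give an `NA` row rather than a fabricated one.
* **Cross-validation** aggregation is mean ± *population* standard
  deviation across folds (the folds are the entire population of the
  experiment, not a sample; the choice is one line in
  `aggregate_folds()` if sample sd is preferred). Per-fold scores pool
  frames across the fold's videos; volatility, being a per-video ratio,
  is averaged over the fold's videos with defined values.
* Per-class rows with zero support use the 0/0 = 0 convention for
  precision and recall, keeping every reported fraction in [0, 1] on
  degenerate clips.

## The synthetic generator

The generator is structural, not fitted: it reproduces the qualitative
features of operative workflows that matter to smoothing, with
parameters chosen once as field-plausible defaults.

* **Ground truth** (`workflow_model()`, `simulate_ground_truth()`):
  classes visited in canonical order; each class skipped with
  probability 0.1; after each transition, probability 0.1 of briefly
  revisiting the previous class ("occasional" skips and repeats);
  visit durations log-normal with median 600 s (`meanlog = log(600)`,
  `sdlog = 0.5` for a heavy right tail), truncated at 1 s. If a draw
  skips every class, one uniformly chosen class has its skip disabled
  and the draw is repeated, with a message.
* **Predictions** (`noise_model()`, `corrupt_predictions()`): a
  memoryless channel draws each frame from the confusion row of its
  true class — by default `neighbor_confusion()` with 0.85 on the
  diagonal and the rest on the order-neighbours, since workflow
  classifiers confuse adjacent stages far more than distant ones — and
  occlusion bursts (start probability 0.013/frame, uniform length
  3–12, expected coverage ≈ 10% of frames) overwrite short intervals
  with wrong labels, per-frame uniform over wrong classes by default,
  emulating uninformative frames during scene occlusion or endoscope
  withdrawal.
* Everything is a pure function of (parameters, seed) via an isolated
  RNG scope; the caller's `.Random.seed` is never touched.

What the simulator does **not** model: label noise in the ground truth,
long-range duration correlations, partial video loss, class-dependent
burst rates, and any coupling between channel errors and time-of-phase.
Green tests on synthetic data therefore demonstrate the algorithms'
contracts (recovery, monotonicity, calibration, ordering of methods),
not clinical performance on real video.

## Benchmark protocol and problem sizes

`run_benchmark()` mirrors a cross-validated evaluation: simulate
`folds × videos_per_fold` videos, and per fold tune $n$ for each
smoother and fit the HMM on the out-of-fold videos before scoring the
fold. With the default scenario a video is roughly 60–90 minutes of
1 Hz frames. The package's own test suite runs the benchmark at small
sizes (2–5 folds, 1–2 videos per fold, ~20 repetitions for the ordering
check) — ample for the qualitative contrasts it asserts, since the
effect sizes (volatility ratios of 100+ vs < 5) dwarf the run-to-run
spread.

```{r benchmark, eval = FALSE}
bm <- run_benchmark(folds = 5, videos_per_fold = 2, seed = 2026)
bm
tidy(bm)
autoplot(bm)
```

On this scenario both smoothers raise weighted-F1 by ~0.2 while cutting
volatility from ~250 to below 5, and threshold beats modal on both axes
— the qualitative pattern that motivates post-hoc smoothing in the
first place.

## Degenerate inputs and numerical notes

* Sequences shorter than the window are passed through whole (the
  "first $n$ frames unchanged" rule covers the entire sequence); no
  error.
* Window sizes outside $[1, 60]$, empty training sets, mismatched
  vocabularies and non-contiguous frame indices are hard errors with
  located messages, never silent coercions.
* All Viterbi arithmetic is in log space; probabilities from counting
  with $\alpha > 0$ are strictly positive, so `-Inf` appears only if a
  hand-built model contains structural zeros, and an all-`-Inf` horizon
  aborts with a decoding error rather than returning an arbitrary
  state.
* CSV interchange is deliberately minimal (`frame,label`, 0-based
  contiguous frames, labels as names restricted to `[A-Za-z0-9_-]`);
  write-then-read is bit-exact, asserted over randomised round trips.

## Known limitations

* The smoothers operate on hard labels; classifier confidence, if
  available, is discarded.
* The HMM assumes stationary transition and emission behaviour across a
  video; real procedures drift.
* Window tuning optimises weighted-F1 alone; a clinical deployment
  might prefer a lag-penalised objective.
* The simulator's skip/revisit grammar is an approximation of real
  step-sequence variation graphs, which are richer than
  skip-one/revisit-one.
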