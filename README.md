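# wfsmooth

Temporal smoothing and stability evaluation for frame-wise surgical
workflow predictions.

## The problem

Automated surgical workflow recognition assigns each video frame of an
operation to a clinically defined **phase** (coarse, e.g. 3 classes) or
**step** (fine, e.g. 7 classes), typically at 1 frame per second. Frame
classifiers do this well on average, but their raw output is *volatile*:
scene occlusion, bleeding and endoscope withdrawal produce short bursts
of spurious labels, so the predicted class can flip from one second to
the next even while the surgery sits inside a single phase. Volatile
output undermines clinical trust and any downstream system keyed to
phase transitions.

`wfsmooth` is the post-processing and evaluation toolkit for this
setting. It takes per-video label sequences (ground truth and
predictions, as plain `frame,label` CSV) and provides causal smoothers,
an HMM post-processor, the volatility metric, the weighted-F1 evaluation
protocol, and a synthetic workflow simulator for controlled benchmarks.

## The methods

Write the predicted class at frame *t* as *x(t)*, the smoothed output as
*y(t)*. Both smoothers pass the first *n* frames through unchanged and
are causal (no future frames used):

- **Modal smoothing `M_n`** — *y(t)* is the mode of
  *x(t−n), …, x(t)* (the current and previous *n* predictions, a window
  of *n + 1* frames). Modal ties resolve to the tied class seen most
  recently.
- **Threshold smoothing `T_n`** — *y(t) = x(t)* if
  *x(t−n) = … = x(t)* (n + 1 consecutive identical predictions),
  otherwise *y(t) = y(t−1)*. A hysteresis/debounce filter: the output
  changes class only after a sustained run, at the cost of a
  deterministic *n*-frame lag after each genuine change.
- **HMM post-processing** — hidden states are the true workflow classes,
  observations are the classifier's predictions. All distributions are
  estimated by supervised counting with a Laplace pseudocount on
  completed training videos; decoding is online Viterbi where the label
  at frame *t* comes from the optimal path for the observations up to
  *t + L* (default lookahead *L* = 5 frames).
- **Prediction volatility** — the ratio (number of class changes in the
  prediction) / (number of class changes in the ground truth); a proxy
  for prediction uncertainty. 1 is ideal; raw classifier output on
  occlusion-prone video commonly lands in the tens to hundreds.
- **Evaluation** — support-weighted F1 (the primary score), weighted
  precision/recall, mean-accuracy (macro-averaged per-class recall),
  confusion matrices normalised over the predicted class (diagonal =
  precision, off-diagonals = false discovery rate), and cross-validation
  aggregation as mean ± sd across folds. The smoothing window *n* is
  tuned on training data by scanning *n* ∈ [1, 60] and keeping the
  smallest *n* maximising training weighted-F1.

## Worked example

```r
library(wfsmooth)

# volatility on the canonical worked example:
# ground truth (P1 x8)(P2 x8)(P3 x8) has 2 class changes,
# the prediction (P1 x8)(P2 x5)(P1 x3)(P3 x8) has 3
pair <- example_volatility_pair()
prediction_volatility(pair)
#> [1] 1.5

glance(evaluate_pair(pair))
#> # A tibble: 1 × 6
#>   weighted_f1 weighted_precision weighted_recall mean_accuracy volatility n_frames
#> 1       0.870              0.909           0.875         0.875        1.5       24
```

The prediction is right on 21 of 24 frames (weighted recall 0.875) but
makes one extra transition, hence volatility 3/2 = 1.5.

```r
# a volatile two-class stream: 7 class changes, of which only the last
# run is a genuine transition
x <- example_smoothing_sequence()
c(raw = count_changes(x),
  M5  = count_changes(modal_smooth(x, 5)),
  T5  = count_changes(threshold_smooth(x, 5)))
#> raw  M5  T5
#>   7   1   1
```

Both smoothers with window 5 collapse the seven changes to the single
true transition.

The end-to-end synthetic benchmark (7-step workflow, neighbour-biased
misclassification with 0.85 diagonal, occlusion bursts on ~10% of
frames, fivefold cross-validation with per-fold window tuning):

```r
run_benchmark(folds = 5, videos_per_fold = 2, seed = 2026)
#> Synthetic smoothing benchmark: 5 folds x 2 videos, seed 2026
#>     method   weighted_f1 weighted_precision weighted_recall mean_accuracy       volatility
#>        raw 0.785+/-0.013      0.801+/-0.019   0.775+/-0.009 0.775+/-0.009 244.540+/-60.419
#>      modal 0.981+/-0.004      0.981+/-0.004   0.981+/-0.004 0.979+/-0.003    4.040+/-2.380
#>  threshold 0.987+/-0.003      0.987+/-0.003   0.987+/-0.003 0.987+/-0.003    1.384+/-0.306
#>        hmm 0.965+/-0.006      0.966+/-0.007   0.963+/-0.005 0.964+/-0.005   14.757+/-5.110
```

Both smoothing functions raise weighted-F1 over the raw channel while
cutting volatility by roughly two orders of magnitude, with threshold
smoothing the more effective of the two on both axes.

## Command line

The installed `exec/wfsmooth` script exposes the same operations:

```sh
wfsmooth simulate  --seed 1 --n-videos 5 --out sims/
wfsmooth smooth    --method threshold --window 5 --vocab sims/vocab.json \
                   --input sims/video001_pred.csv --output smoothed.csv
wfsmooth evaluate  --truth sims/video001_gt.csv --pred smoothed.csv \
                   --vocab sims/vocab.json --report report.json
wfsmooth tune      --method threshold --pairs sims/ --vocab sims/vocab.json \
                   --report tuning.json
wfsmooth benchmark --seed 1 --folds 5 --videos-per-fold 2 --report bench.json
```

Every command writes a provenance record (parameters, seed, input
digests, package version) beside its output.

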