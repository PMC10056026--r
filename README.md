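# osemg

Open-set recognition of wrist movements from low-density (8-channel,
200 Hz) surface electromyography.

## The problem

sEMG pattern recognition for wrist rehabilitation is usually closed-set: a
classifier trained on a fixed vocabulary of movements assigns *every* input
to one of them. Real users also produce out-of-vocabulary movements whose
muscle-activation signatures are deliberately or accidentally similar to
the trained ones; a closed-set classifier mislabels these, and in an
exoskeleton-control setting a mislabel becomes a wrong command. `osemg` is
for researchers who need a classifier that can say "none of the above":
it labels the 7 target wrist classes (including neutral) and *rejects*
unrelated movements.

## The method

1. **Feature images.** The 8-channel signal is segmented into 250 ms
   windows every 100 ms within each trial. Windows are muscle-active when
   their mean rectified amplitude exceeds
   `Threshold = mu_neutral + 3 * sigma_neutral` (statistics of the
   rectified neutral signal). Each active window gives a per-channel
   feature row — RMS `sqrt(mean(x^2))`, MAV `mean(|x|)`, WL
   `sum(|diff(x)|)` — and `T = 53` consecutive rows form a `3 x 53 x 8`
   image.
2. **Discriminative features.** A small CNN (three convolutions, two fully
   connected layers, leaky rectifiers, 20% dropout) maps each image to a
   512-dimensional deep feature and class logits, trained with Adam on the
   joint loss `L = L_softmax + lambda * L_center`, where
   `L_center = (1/2N) sum_i ||x_i - c_{y_i}||^2` pulls features toward
   per-class centers updated batch-wise with a damped rule (rate `alpha`).
   Default `lambda = 0.00025`.
3. **Rejection gate.** A mirror autoencoder (512-256-128-64-128-256-512)
   is trained by MSE on target-class deep features only. The novelty score
   of a sample is `e = 1 - cor(x, AE(x))` (Pearson). Per-class thresholds
   `tau_c` are calibrated on the validation set as the smallest error
   covering a preset recall fraction `r` of each class; a sample is
   accepted with the CNN's label iff `e <= tau_c`, otherwise rejected.
4. **Evaluation.** Accuracy/precision/recall/FPR/F-score, an open-set
   confusion matrix with a pooled `unrelated` row and a `reject` column,
   and the target-vs-unrelated ROC/AUC of the reconstruction error.

A seeded synthetic generator emulates the acquisition protocol (5 s
repetitions, 3 s rest, 6 repetitions of 7 target + 5 unrelated movements
with a configurable target/unrelated similarity band), so the entire
pipeline is testable without external data.

## Worked example

```r
library(osemg)
run <- run_pipeline(pipeline_config(seed = 1))
print(run)
```

```
osemg pipeline run (seed 1): 28 train / 7 validation / 37 test images
Open-set evaluation
-------------------
                  predicted
truth              extension flexion neutral pronation radial_deviation supination ulnar_deviation reject
  extension                1       0       0         0                0          0               0      0
  flexion                  0       0       0         0                0          0               0      1
  neutral                  0       0       1         0                0          0               0      0
  pronation                0       0       0         1                0          0               0      0
  radial_deviation         0       0       0         0                0          0               0      1
  supination               0       0       0         0                0          0               0      1
  ulnar_deviation          0       0       0         0                0          0               0      1
  unrelated                0       0       0         0                0          0               0     30

target accuracy (per-sample)    42.9%
target accuracy (macro)         42.9%
closed-set CNN accuracy        100.0%
unrelated rejection rate       100.0%
overall accuracy                89.2%
macro F-score                  100.0%
rejection AUC                  100.0%
```

Reading the output: the CNN labels every target test image correctly
(closed-set accuracy 100%), the reconstruction error separates target from
unrelated test samples perfectly (AUC 100%), and all 30 unrelated images
are rejected. The open-set target accuracy (42.9%) is lower because, with
only 1–2 validation images per class under the default data sizes, the
recall-quantile thresholds are coarse and several correctly-labeled target
images fall above their class threshold; the macro F-score averages over
the classes for which it is defined. `sweep_recall(run)` tabulates how
raising the recall factor trades rejection for target acceptance, and
`sweep_lambda()` reproduces the center-loss-weight experiment.

The command-line interface (`inst/cli/osemg`) exposes the same stages as
subcommands (`simulate`, `preprocess`, `split`, `train-cnn`, `train-ae`,
`calibrate`, `evaluate`, `run`, `sweep-recall`, `sweep-lambda`), with a
single JSON config file (`osemg config` prints the defaults). Recordings
are CSV pairs (`t,ch1..ch8` plus a trial table); feature images and model
checkpoints are RDS archives; reports are JSON plus an aligned-text table.

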