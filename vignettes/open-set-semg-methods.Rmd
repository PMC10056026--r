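---
title: "Open-set wrist-movement recognition from low-density sEMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-set wrist-movement recognition from low-density sEMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Myoelectric pattern recognition for wrist rehabilitation assumes a closed
vocabulary: a classifier trained on, say, seven wrist movements will assign
*every* input to one of those seven classes. In practice users produce
movements outside the vocabulary — finger abductions, fists, variants of the
trained gestures — whose 8-channel surface-EMG signatures overlap heavily
with the trained classes. A closed-set classifier silently mislabels them,
which in an exoskeleton-control loop means wrong commands. `osemg`
implements an open-set recognizer: a discriminative convolutional feature
network labels the movement, and a reconstruction-based novelty gate may
overrule it and *reject* the sample instead.

## Signal model and preprocessing

The input is an 8-channel recording at 200 Hz (the bandwidth and density of
consumer EMG armbands), organized into trials: repetitions of one movement
followed by rest.

**Windows.** The signal is cut into overlapping analysis windows of 250 ms
(50 samples) every 100 ms, always inside a single trial. A trial of $n$
samples yields $\lfloor (n-L)/S \rfloor + 1$ windows.

**Activity detection.** A window is in the muscle-active state when its mean
rectified amplitude exceeds

$$\mathrm{Threshold} = \mu_{\text{neutral}} + 3\,\sigma_{\text{neutral}},$$

where $\mu$ and $\sigma$ are the mean and population standard deviation of
the *rectified* neutral-state signal. Three choices here are ours, because
the rule is underspecified in common usage: (i) the statistics are computed
on $|x|$ — raw sEMG is zero-mean, so unrectified statistics would make the
threshold insensitive to amplitude; (ii) the per-window statistic compared
against the threshold is the mean rectified amplitude over all samples and
channels, the most direct reading of "window amplitude"; (iii) the
comparison is strict (`>`), so a window exactly at threshold is inactive.
All are deterministic and fixed.

**Feature images.** Each active window is summarized per channel by three
amplitude-linked time-domain features,

$$\mathrm{RMS} = \sqrt{\tfrac1N \sum_n x_n^2}, \qquad
  \mathrm{MAV} = \tfrac1N \sum_n |x_n|, \qquad
  \mathrm{WL} = \sum_{n\ge2} |x_n - x_{n-1}|,$$

giving a $3\times8$ feature row. $T$ consecutive active windows are stacked
into a $3\times T\times 8$ image (default $T = 53$), sliding with stride 1
within the trial. At 250/100 ms windowing, a 5-s repetition yields 48–50
windows, slightly fewer than the canonical stack depth of 53; we therefore
read the $3\times53\times8$ image as a stack of per-window feature rows
covering roughly one repetition, pad short trials by repeating the final
row (recording the pad count), and keep $T$ configurable. Padding by
repetition preserves the amplitude statistics without inventing values.

The neutral class is, by construction, the class with no muscle activity:
its trials have no active windows. Rather than dropping the class, the
preprocessing falls back to using all windows of a trial that contains no
active window. The classifier thus learns neutral as the low-amplitude
pattern, which is exactly its physiological meaning.

Feature planes are passed to the network raw. Whether any normalization is
applied before the network is an open design point; we default to raw
features (the WL plane is numerically larger than RMS/MAV, but the
per-parameter scaling of Adam absorbs the difference) and expose a
per-plane standardization switch (`standardize`) that is off by default.

## The discriminative feature network

A small CNN maps a $3\times T\times 8$ image to class logits through three
convolutions (kernels $16\times2$ stride $(2,2)$ pad $(0,0)$; $8\times3$
stride $(2,1)$ pad $(2,1)$; $3\times3$ stride $(1,1)$ pad $(1,1)$), two
fully connected layers (1024, then 512 units), and a softmax output over
the $M = 7$ target classes. Activations are leaky rectifiers; 20% dropout
acts between the two fully connected layers during training. The 512-unit
layer's activations are the *deep features* $x_i$ consumed by the rejection
stage. The convolutional channel widths (32, 64, 64) and the 1024-unit
width are our reconstruction of an under-specified "small-scale CNN"; all
are configurable, and the 512-wide feature layer is the fixed interface to
the rejector.

Training minimizes the joint loss

$$L = L_{\mathrm{softmax}} + \lambda\, L_{\mathrm{center}}, \qquad
  L_{\mathrm{center}} = \frac{1}{2N}\sum_{i=1}^{N} \lVert x_i - c_{y_i}\rVert_2^2,$$

with Adam (learning rate $10^{-4}$, batch 32, 200 epochs by default) and
$\lambda = 2.5\times10^{-4}$. The cross-entropy term separates classes; the
center term pulls each deep feature toward its class centroid $c_{y_i}$,
shrinking within-class scatter so that target-class features occupy compact
regions an autoencoder can learn well. We implement the center loss in its
standard non-negative form (half mean squared distance); its gradient with
respect to the features is then exactly $(x_i - c_{y_i})/N$, which the test
suite verifies against finite differences.

Centers are not free parameters of the optimizer. After each Adam step they
are updated from the same mini-batch by the damped rule

$$\Delta c_j = \frac{\sum_i \delta(y_i = j)\,(c_j - x_i)}{1 + \sum_i \delta(y_i = j)},
  \qquad c_j \leftarrow c_j - \alpha\, \Delta c_j,$$

with $\alpha \in (0,1)$ controlling the center learning rate. Iterating
this rule on a frozen batch contracts each center to its class mean, which
is tested as a fixed-point property. Choices that the formulation leaves
open, fixed here: $\alpha$ defaults to 0.5 (no canonical value exists;
exposed in `train_config()`); centers initialize at zero (deterministic,
and the update rule converges regardless); and centers are updated *after*
the weight step of each batch, using the features computed in that batch's
forward pass. All randomness — initialization, shuffling, dropout — derives
from the training seed, so training is reproducible.

## The rejection gate

A mirror autoencoder (512–256–128–64–128–256–512 by default; hidden leaky
rectifiers, linear output) is trained with mean squared error, Adam
($10^{-4}$, batch 32, 1000 epochs) on the *training-set deep features of
the target classes only*, with the CNN frozen. The bottleneck at 1/8 of the
input width is our choice; widths are configurable but must remain
palindromic. The hidden widths are not prescribed anywhere; a bottleneck
small enough to force compression is what matters.

At test time a sample's novelty score is the Pearson-correlation
reconstruction error

$$e(x) = 1 - \rho(x,\, \mathrm{AE}(x)) \in [0, 2].$$

The AE is *trained* with MSE but *scored* with correlation: correlation is
scale-free in 512 dimensions and yields scores on a small non-negative
scale on which thresholds in the few-hundredths range are meaningful. If
either the feature or its reconstruction is constant the correlation is
undefined; the score then takes its maximal value 2 with a warning, which
errs on the side of rejection.

**Calibration.** Given a preset recall factor $r \in (0,1]$, the threshold
of class $c$ is the $\lceil r\,n_c\rceil$-th order statistic of the class's
validation-set errors — the smallest error covering at least a fraction
$r$ of them. A sample is accepted, with the CNN's label $c$, iff
$e \le \tau_c$; the boundary accepts. With boundary-accept, the accepted
fraction of every class on the calibration set itself is $\ge r$ by
construction, a guarantee the acceptance tests exercise. Per-class
thresholds are the primary mode; a pooled global threshold is recorded and
can be selected (`mode = "global"`), since a single-threshold reading of
the calibration rule is also defensible. Raising $r$ can only raise
thresholds, hence accept more targets and reject fewer unrelated movements
— the recall/rejection trade-off the recall sweep tabulates.

The calibration could alternatively be read as "the mean reconstruction
error at which recall is reached"; we implement the per-class quantile,
which matches the per-class wording of the rule and makes the recall
guarantee exact. Similarly, a bank of per-class autoencoders is a plausible
variant; we implement the single AE trained on all target features, the
reading consistent with the training description.

A rejection model records the fingerprint of the CNN checkpoint whose
features it was calibrated on and refuses to run against a different
network unless forced.

## Evaluation

`binary_metrics()` implements accuracy, precision, recall/TPR, FPR and
F-score exactly; any rate with a zero denominator is reported as `NA`,
never as 0, because silent zeros corrupt averages. Summaries over classes
are macro-averages over the classes for which the metric is defined, and
this convention is stated wherever a mean is reported. The open-set
confusion matrix has one row per target class plus a pooled `unrelated`
row, and one column per target class plus a `reject` column. Two accuracy
notions are reported, since "mean accuracy" is ambiguous: per-sample
(pooled) and macro (mean of per-class rates).

For the ROC, the positive event is "target sample accepted as target":
sweeping every distinct error value as the acceptance threshold, TPR is the
accepted fraction of targets and FPR the accepted fraction of unrelated
samples; ties share one step and the AUC is the trapezoidal area, which
equals the pairwise concordance probability (verified against brute force).

## The synthetic data generator

No public dataset is bundled; the generator produces recordings with the
statistical features the method actually relies on, so the whole pipeline
is testable end to end:

* 8 channels at 200 Hz; repetitions of 5 s followed by 3 s rest, 6
  repetitions per movement — the acquisition protocol of consumer-armband
  studies.
* Band-shaped Gaussian noise (Butterworth band-pass 20–95 Hz at 200 Hz,
  the sEMG energy band under that sampling rate) amplitude-modulated by a
  trapezoidal envelope with 200 ms ramps, so activity onsets are gradual
  rather than instantaneous. During an active repetition the per-channel
  standard deviation is `base_amplitude * activation[ch] + noise_sd`; at
  rest it is the `noise_sd` floor (default 0.02, with target gains of
  order 1 — a high but not unrealistic SNR for surface EMG on a strong
  contraction).
* 6 non-neutral target classes with activation patterns
  $e_i + 0.5\,e_{i+2}$ (one primary and one secondary channel): nearly
  orthogonal, and with *equal total gain*, so classes are not separable by
  overall amplitude and the network must learn the spatial pattern. The
  neutral class has uniform gains of 0.03, at most 5% of the largest
  target gain.
* 5 unrelated classes built as convex mixtures of two target activations
  plus a small deterministic perturbation. The mixing weight is solved
  numerically (by `uniroot` on the maximum cosine similarity to any
  target) so the similarity lands at prescribed levels spread across a
  configurable band, default $[0.5, 0.95]$; mixtures are then rescaled to
  the mean target norm so amplitude gives nothing away. Widening the
  band's upper bound makes unrelated movements more target-like, and the
  test suite checks that the downstream rejection AUC indeed degrades —
  the band is a difficulty dial, not a fitted quantity. No quantitative
  similarity level is prescribed anywhere for the real movement sets; the
  band and its default are our construction.

What the generator does **not** emulate: motor-unit physiology,
force/kinematics coupling, electrode shift, inter-subject variability,
fatigue, or power-line artifacts. Passing tests on this data demonstrates
the correctness and the qualitative behavior of the method — not field
performance on real recordings.

## Problem sizes and numerical choices in the test suite

Under the default conditions (6 repetitions, $T = 53$) each movement
contributes 6 feature images, so the 60/20/20 class-stratified split leaves
roughly 4/1/1 images per target class and places all 30 unrelated images in
the test set. These sizes keep the full pipeline at about a minute on one
CPU core, and the acceptance tests train it repeatedly (3 seeds × 2 center-
loss weights; 5 seeds at an easier similarity band $[0.5, 0.8]$). Two
consequences are worth naming. First, with only 1–2 validation images per
class the recall quantile is coarse, so the *open-set* acceptance of target
samples on the test set is pessimistic and noisy even when the closed-set
accuracy and the rejection AUC are high; we therefore report the closed-set
accuracy of the classification stage and the AUC of the rejection stage as
the primary per-stage quantities, alongside the open-set accuracy. Second,
fast plumbing tests use deliberately shrunken configurations (short
repetitions, shallow stacks, few epochs) where statistical performance is
irrelevant; statistical claims are only made on the default conditions.

Unrelated images never enter training or validation; they exist only to be
rejected at test time.

## Known limitations

* The feature network and autoencoder are implemented directly on BLAS
  matrix operations with hand-derived gradients; this keeps the package
  dependency-free and the runs reproducible, but it is CPU-bound and not
  intended for datasets beyond desk scale.
* Per-class thresholds from very small validation sets are order
  statistics of a handful of errors; operating points are then coarse.
  With realistic validation sizes (tens of samples per class) the recall
  calibration behaves as intended.
* The synthetic generator's separability dial controls spatial-pattern
  overlap only; real unrelated movements can also differ in temporal
  structure, which the stationary noise model does not represent.
* Training-set accuracy saturates quickly on the synthetic classes; the
  interesting regime for the method is the rejection trade-off, not
  closed-set difficulty.
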