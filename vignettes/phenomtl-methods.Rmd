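---
title: "Multitask phenotyping of rosette plants: models, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask phenotyping of rosette plants: models, data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Top-view images of rosette plants such as *Arabidopsis thaliana* carry
several phenotyping traits at once: the number of leaves (a developmental
stage indicator), the projected leaf area (PLA, the fraction of the frame
covered by the plant, a biomass proxy) and the accession or genotype.
Leaf counts are the most expensive of these to annotate; PLA can be
obtained from a plant segmentation and the genotype is usually known in
advance. `phenomtl` implements a multitask convolutional network that
predicts all three traits from one image and — the central mechanism — a
*label-masked* loss that lets images lacking a count annotation still
train the PLA and genotype tasks, so the cheap annotations subsidise the
expensive one.

## Model

The network is a hard-parameter-sharing multitask architecture:

* a convolutional feature extractor;
* a shared fully connected representation of 1536 units (ReLU), used by
  all tasks;
* a count branch (512 -> 1, final ReLU so counts are non-negative);
* a PLA branch (512 -> 1, final LeakyReLU with slope 0.01, clamped to
  [0, 1] at prediction time only);
* a genotype branch (512 -> 256 -> 2) read as a two-class probability.

Everything up to and including the 1536-unit layer is shared: each
branch's backward pass writes into the same parameter arrays, which both
regularises the representation and is what transfers information between
tasks.

The packaged feature extractor (`small_cnn`) is four 3x3, stride-2
convolution blocks of 16/32/64/128 filters followed by global average
pooling. It preserves the multitask structure at a size that trains on a
single CPU in tens of seconds. A ResNet50 feature extractor (optionally
ImageNet-pretrained) is the full-scale configuration of the same
architecture; it needs a GPU deep-learning runtime, which this package
deliberately does not ship, so `build_model()` rejects the `resnet50_*`
backbone names with an informative error rather than pretending to
support them. There is no off-the-shelf deep-learning framework among
this package's dependencies: the forward and backward passes (im2col
convolutions in single precision via RcppArmadillo/BLAS, dense layers,
Adam) are implemented in the package itself, which keeps the multitask
loss masking fully transparent and testable.

### Losses

The training loss is

```
total = 10 * MSE_count(masked) + 10 * MSE_pla(masked) + weighted CE_genotype(masked)
```

Each task term averages only over the images whose availability flag for
that task is `TRUE`; a task with no unmasked image in a batch contributes
exactly zero and, importantly, exactly zero gradient (this is asserted by
finite differences in the test suite). The factor 10 on both regression
terms keeps them on a comparable scale to the cross-entropy. Genotype
cross-entropy is weighted per class with the balanced heuristic
`w_c = N / (2 N_c)`, so imbalanced training sets do not bias the
classifier toward the majority class.

The 0.04 regularizer on the layers feeding each final prediction layer is
implemented as an *activity* penalty: the loss adds 0.04 times the batch
mean of the summed squared activations of those layers. We also
prototyped the same coefficient as weight decay on those layers and found
it far too aggressive at desk scale — it shrinks the 512x1536 branch
weights faster than the cross-entropy gradient can grow them and pins the
genotype branch at chance — so the activity form, which penalises what
the layer does rather than what it is, is the package's design choice.

### Optimisation

Adam with learning rate 1e-4 is the full-scale default
(`train_config()`); the desk-scale experiment drivers use 1e-3, a
standard rate for a small network trained from scratch, with batch size
8. Inputs are intensities in [0, 1] centred by subtracting 0.5 at the
network entry; without centring, a from-scratch network of this size
stalls on some seeds. The regression output biases are initialised at
the training-set target means, so optimisation starts from the mean
predictor instead of spending epochs reaching it.

Early stopping monitors the total validation loss and the returned
checkpoint is the best validation loss observed, never a later one. Two
refinements matter for small networks: early stopping is only armed
after a configurable warm-up (`min_epochs`), because the count task
spends its first epochs on a flat pre-convergence plateau — roughly four
times longer when only 25% of count labels are present, since
count-bearing batches are then four times rarer — and a patience counter
started against a lucky first-epoch validation value would kill runs
that have not converged yet. And the validation set should contain more
than one plant: a single held-out plant gives a checkpoint-selection
signal noisy enough to pick pre-convergence weights. Training is
deterministic given the seed.

## Synthetic data

`generate_dataset()` renders rosettes whose ground truth is exact by
construction, emulating the structure of real top-view time series:
multi-plant growth series, counts non-decreasing in time, two visually
distinct genotype classes, and textured nuisance backgrounds.

* **Phyllotaxis**: leaf *i* sits at `(i - 1) * 137.5` degrees (the golden
  angle) plus uniform jitter of up to 10 degrees, so older and newer
  leaves interleave and occlude realistically.
* **Growth**: leaf length scales with `sqrt(i)`; the count at timepoint
  `t` is `2 + floor(growth_rate * (t - 1))`, a deterministic,
  reproducible growth curve. The growth curves are stand-ins with
  plausible rates (0.45 leaves/timepoint for the wild type, 0.35 for the
  elongated mutant), not calibrated to any particular real dataset.
* **Genotypes**: the wild-type preset is round and dark green (hue
  115-135), the default mutant elongated and yellow-green (hue 70-95); a
  third preset (`subtilis`) sits close to the wild type for experiments
  on visually confusable accessions. A mean-hue threshold classifier
  separates the two default classes with high accuracy, which guarantees
  the genotype task is learnable at desk scale.
* **Background**: low-frequency brown/grey noise plus a darker pot disc,
  so models must learn to ignore nuisance structure and occlusion maps
  have genuine background regions.
* **PLA** is recomputed from the rendered mask, so the stored annotation
  agrees with the mask-derived fraction by construction.

What the generator does **not** emulate: leaf texture and venation,
specular soil highlights, camera noise, perspective distortion, and
leaves that cross the image border. Passing tests on synthetic data
therefore demonstrate that the machinery (masked loss, sharing,
reduction schedules, metrics) behaves as designed, not that any
particular accuracy transfers to real imagery.

## Preprocessing, augmentation, splits

Images are resized (bilinear; masks nearest-neighbour) to the square
model input — 320 px at full scale, 96 px at desk scale — and scaled to
[0, 1]. Each training image receives one transform per epoch drawn from
{rotation U(0, 180) degrees, per-axis shift up to 10% of the side,
horizontal flip, vertical flip}; flips and integer shifts are exact index
operations, rotation resamples bilinearly. Composition of several
transforms is deliberately not the default: one transform per draw keeps
the augmentation distribution simple and label-preserving.

Cross-validation splits are always at the plant level (a plant's whole
time series is either train or test), genotype-stratified when every
genotype has at least `k` plants, with one training plant per fold held
out as the validation set — a plant-level validation set avoids
time-series leakage into the early-stopping signal.

Count-label reduction schedules operate per plant along the time axis:
`uniform` removes evenly spaced labels (for keep 0.75 every 4th starting
with the first; for keep 0.25 only every 4th is retained),
`juvenile_first` removes the earliest timepoints, `mature_first` the
latest, `random` a seeded uniform sample. When the kept count is
fractional it is rounded up. PLA and genotype availability are never
touched.

## Metrics

The count metric suite follows the CVPPP leaf-counting conventions:
predictions are rounded half away from zero to integer counts before
computing DiC (mean and population standard deviation), |DiC|, percentage
agreement, MSE and R^2 (an unrounded variant is available via
`raw = TRUE`). The DiC sign convention is fixed as prediction minus
ground truth. The +/-1 accuracy and its signed histogram summarise how
tightly predictions cluster around the truth.

The bootstrapped paired t-test is a bootstrap-t under the centred null:
the observed paired t statistic is compared with t statistics of
resampled mean-centred differences; the two-tailed p-value is the
fraction of resampled |t*| at or above |t_obs|. Degenerate resamples with
zero variance count as exceedances unless their mean is also zero, which
makes the test conservative; identical inputs return p = 1 by convention.

## Occlusion analysis

`occlusion_scan()` slides a black square window (zeros on the [0, 1]
intensity scale, i.e. before input centring) across the image and records
each task's prediction at every position; the grid has
`floor((S - w) / stride) + 1` cells per side. Window 60 px and stride
20 px at a 320-px input are the reference geometry and are scaled
proportionally for other input sizes (18/6 at 96 px). Both deltas against
the unoccluded baseline and raw predictions are kept, since either view
of the map is informative. `focus_score()` summarises a map as the
fraction of total absolute prediction change attributable to windows
overlapping the plant mask — a trained model should concentrate its
sensitivity on the plant, not the background.

## Desk-scale experiment regime

The experiment drivers (`run_mtl_vs_single()`, `run_label_reduction()`,
`run_strategy_comparison()`) default to `desk_spec()`: 20 synthetic
plants x 12 timepoints at 96 px, the small backbone with a 768-unit
shared layer, two-fold plant-level cross-validation with two validation
plants per fold, five seeds, and at most 48 epochs with patience 10
after a 22-epoch warm-up. Augmentation is off in this regime: the
generator already randomises leaf placement and orientation, so
augmentation adds no generalisation on synthetic data and only slows
convergence (it stays on by default for real images). These sizes are
the package's choice of a regime where a full comparison grid (two
models x two label fractions x five seeds, each cross-validated)
completes on a single CPU while the directional effects — multitask not
worse than single task, single-task degradation under label removal,
multitask compensation, mature labels mattering more than random ones —
are still resolvable. All comparisons share datasets and splits within a
seed, and every experiment is a pure function of its spec and seeds.
Stochastic comparisons are asserted directionally over seeds (at least
4 of 5) rather than numerically, because exact values at this scale are
dominated by seed noise.

## Numerical choices and degenerate inputs

* Convolution arithmetic runs in single precision (the usual precision
  for CNN training); metrics, losses and dense-layer algebra are double.
* He-normal initialisation; the count output bias starts at 1 so the
  final ReLU unit is active from the first step.
* R^2 on a constant ground truth is undefined and returned as `NA` with
  a warning.
* An all-zero plant mask is a valid empty plant (PLA 0); `focus_score`
  on an empty mask is an error, and a map with zero total sensitivity
  returns `NA` with a warning.
* A batch in which every image is masked for every task is rejected as
  unlearnable; a non-finite loss aborts training naming the offending
  task term.

## Known limitations

* The shipped backbone is small; absolute accuracies on real datasets
  require the full-scale configuration (large pretrained backbone,
  320-px inputs) and corresponding hardware.
* The generator's genotype classes are separable by colour alone, so
  genotype accuracy on synthetic data overstates what hue-similar real
  accessions allow.
* Fractional-pixel shifts are rounded to integers; rotation is the only
  resampling augmentation.
* The bootstrap test assumes exchangeable paired differences; it is not
  a substitute for a hierarchical model when errors cluster by plant.
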