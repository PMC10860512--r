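---
title: "Transfer learning for lung GTV segmentation: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning for lung GTV segmentation: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Deep segmentation models for the lung gross tumour volume (GTV) are
typically trained at one institution and then deployed at another, where
scanners, acquisition protocols and patient populations differ. Two
questions follow. First, how much does such a *domain shift* degrade a
source-trained model? Second, can a small locally collected re-training
set restore performance by fine-tuning — without destroying what the model
learned at the source (catastrophic forgetting)? Because automatic
contours are judged against human experts who themselves disagree,
inter-observer variability sets the ceiling for any automatic method, so
the evaluation must include multiple independent delineations of the same
tumours and agreement-level (consensus) analysis.

`gtvseg` implements this entire study design as a reusable, fully seeded
pipeline: a two-domain synthetic CT phantom generator with simulated
observers, a 2D attention U-Net with native Dice-loss training, a
fine-tuning protocol, volume-level geometric evaluation and the associated
ANOVA/Tukey statistics.

## The segmentation model

The network is a 2D attention U-Net operating slice by slice. With depth
$d$ it has $2d + 1$ blocks: $d$ encoder blocks, one bottleneck and $d$
decoder blocks — the reference configuration with $d = 4$ has nine blocks.
Every block starts with batch normalization followed by two $3\times3$
stride-1 pad-1 convolutions with leaky-ReLU activations
($\alpha = 0.1$); encoder blocks end in $2\times2$ max-pooling and filter
counts double per level. Decoder levels upsample by nearest-neighbour
followed by a $3\times3$ convolution, gate the matching encoder skip with
an additive attention gate, concatenate and apply a batchnorm-prefixed
double convolution. The head is a single $1\times1$ convolution with a
sigmoid, giving per-pixel foreground probabilities.

The attention gate follows the standard additive formulation: with skip
features $x$ and the coarser decoder feature $g$ (upsampled to the skip
resolution),
$$\alpha = \sigma\!\big(\psi(\mathrm{ReLU}(W_x x + W_g g + b))\big),
\qquad \hat{x} = \alpha \odot x,$$
with the inter-channel width set to half the skip channels. Forcing
$\alpha \equiv 1$ provably reduces the network to a plain U-Net skip, and
the test suite asserts this bit-exactly. Since no deep-learning framework
is assumed, the forward and backward passes are implemented natively:
im2col + GEMM convolution kernels in C++ and hand-derived gradients for
every layer, verified against central finite differences in
`test-gradients.R`.

Design choices the architecture leaves open were resolved as follows:
batch normalization prefixes *all* blocks (encoder, bottleneck, decoder);
upsampling is nearest-neighbour + convolution (transposed-convolution
checkerboard artefacts avoided); weights use He-uniform initialization
from a recorded seed; inference uses frozen batch-norm running statistics
so repeated forward passes are bit-identical.

## Training and fine-tuning

Training minimizes the soft Dice loss
$$L = 1 - \frac{2\sum p\,t + s}{\sum p + \sum t + s},$$
computed per image and averaged over the batch, with smoothing $s = 1$ so
slices with empty masks (which the training stream includes by default)
contribute a stable, well-behaved term. Optimization is Adam over
shuffled slice batches; validation is a *subject-level* split (default
10%, minimum one subject) so no patient contributes slices to both sides.
The checkpoint with the lowest validation loss is retained.

Fine-tuning continues training of the whole model (no layer freezing)
from the pretrained weights on the target-domain cohort. The guard
against catastrophic forgetting is early stopping on the new-domain
validation-loss plateau (the monitored-curve practice turned into a
rule); optionally a source-domain validation set is scored every epoch so
forgetting is directly measurable.

Two presets ship. `full_scale` keeps the clinical full-scale protocol —
512×512 slices, Adam learning rate $10^{-6}$, 300 pretraining and up to
150 fine-tuning epochs, batch size 6 — for users with real data and
accelerator hardware; it is not exercised by the tests. `desk_scale` is
the package's own scaled study: 64×64 slices, depth-3 network with 8 base
channels, learning rate $10^{-3}$ for pretraining and $3\times10^{-4}$
for fine-tuning (the usual practice of fine-tuning more gently), at most
10 epochs per stage with early-stopping patience 4/3. On the synthetic
phantoms below, training converges within a handful of epochs, and the
whole two-domain study completes in a few minutes on one CPU core. Batch
size 6 and the 10% subject-level validation fraction are kept from the
full-scale protocol.

## What the phantom generator emulates — and what it does not

Each synthetic subject is an axial stack containing an elliptical
soft-tissue body, two low-attenuation lung fields and one tumour: an
ellipsoid (through-plane semi-axis 0.7 of the in-plane radius, so typical
tumours span several slices) whose boundary is perturbed by a smooth
random direction field scaled by an irregularity knob. Intensities are
flat HU plateaus (air −1000, lung −800, soft tissue +40, tumour drawn
per subject from a configurable HU range) plus additive Gaussian noise
and a domain-level calibration offset.

A "domain" is a parameter bundle (`domain_spec()`): image grid, slice
count and thickness, plateaus, tumour HU range, noise level, offset,
tumour size distribution and patient orientation. The default source
domain uses 2.5 mm pixels, 3 mm slices, noise 20 HU and tumour radii
8–14 mm. The default target domain shifts all the knobs at once: +80 HU
offset, noise 90 HU, 5 mm slices, radii 10–16 mm, feet-first orientation
(exercising the canonicalization path) and a lower-attenuation tumour
appearance (HU −130 to −40 versus +20 to +90). The appearance and noise
shifts are what actually break the source model: a plain offset survives
the fixed intensity window and the batch-norm front end, whereas dim,
noisy tumours genuinely change the decision boundary — the property the
transfer experiment depends on, and one the test suite checks via a
Kolmogorov–Smirnov statistic on normalized intensity histograms.

Observers are simulated in physical millimetres so their behaviour is
spacing-invariant across domains: observer $i$ marks voxel $v$ iff
$\mathrm{sdist}(v) \le b_i + g_i(v)$, where sdist is the signed Euclidean
distance to the truth boundary (negative inside, computed by a separable
anisotropic distance transform) and $g_i$ is a smooth zero-mean random
field. The defaults — jitter SD 2.2 mm, per-observer biases −1…+1 mm,
field wavelengths 10–28 mm — were calibrated once so that median pairwise
observer Dice on default-size tumours lands near 0.8, inside the 0.7–0.9
band reported for independent expert delineations; they are configuration,
not claims about any particular clinic's observers.

What the phantom does *not* emulate: anatomy (vessels, airways,
mediastinum), texture, partial-volume effects, reconstruction kernels, or
tumours abutting structures of similar intensity. Segmentation of these
phantoms is therefore much easier than clinical segmentation — absolute
Dice values here approach 1 where clinical studies report 0.6–0.8. What
transfers to real data is the *mechanism*: the pipeline demonstrates, end
to end, that a measured domain-shift degradation is recovered by
small-cohort fine-tuning while source-domain agreement stays put, with
all bookkeeping (quarantined test sets, seeded stages, consensus
analysis) in place.

## Evaluation and statistics

All metrics are volume-level per subject: confusion counts over the full
restacked 3D prediction, then
$\mathrm{DSC} = 2tp/(2tp + fp + fn)$,
$\mathrm{precision} = tp/(tp+fp)$, $\mathrm{recall} = tp/(tp+fn)$.
Degenerate cases follow a fixed convention: both masks empty scores 1
(flagged); an empty prediction against a non-empty reference scores DSC
and recall 0 with precision undefined and excluded from aggregation.
Inter-observer agreement is DSC over all unordered observer pairs (10 for
five observers); models are compared against each observer separately
(5 comparisons). Consensus regions use cumulative "at least $k$ of $K$"
voting, so region($K$) ⊆ … ⊆ region(1), and model recall is reported per
level — the agreement-gradient analysis.

Method arms are compared by one-way ANOVA (via `stats::aov`) with Tukey
HSD post hoc pairs (via `stats::TukeyHSD`); the test suite cross-checks
both against independent textbook implementations (sums of squares;
studentized-range probabilities). Summaries are median, range and IQR
with the linear-interpolation quantile rule fixed for reproducibility.
Because clinical-scale cohorts are typically private, internal
consistency — not reproduction of any particular published table — is
the goal of these statistics.
For the manual arm the ANOVA can pool every observer-pair score (default)
or first take one median per subject; both are exposed because the
pooling unit is a genuinely open choice.

## Numerical and degenerate-input choices

* Binarization threshold 0.5, exposed as configuration.
* Soft-Dice smoothing 1; as it tends to 0 the loss tends to the exact
  Dice complement (tested).
* Tumour masks and observer masks are reduced to their largest
  6-connected component; an observer configuration that empties a mask is
  an error, not a silent degenerate.
* The signed-distance observer model reproduces the truth exactly at zero
  jitter and bias; with independent zero-mean fields the unanimous-core ⊆
  truth ⊆ union bracketing holds per voxel only almost surely on a
  discrete grid, and the tests assert it with a small (<0.5%)
  discretization margin.
* Max-pooling gradient ties route to the first maximum in scan order;
  ties occur with probability zero for continuous activations.
* The batch-norm variance uses the biased (population) estimator
  consistently in training statistics and running averages.

## Scaled study sizes

The default `desk_scale` manifest uses 40 source-training subjects, 8
source inter-observer subjects with 5 observers each, 12 target re-train
subjects (30% of the source cohort — the small-local-cohort regime) and
16 target test subjects, at 64×64 pixels and 6–10 slices per subject.
These sizes were chosen once so the complete study — generation, two
training stages, all evaluations and the report — runs in minutes on a
single CPU core while leaving each arm enough subjects for medians and
ANOVA to be meaningful. All sizes are configurable in
`study_manifest()`.

## Known limitations

* The phantom's simplicity inflates absolute scores; only relative
  (model-vs-model, arm-vs-arm) conclusions are meaningful.
* 2D slice-wise segmentation ignores through-plane context by design;
  quasi-3D variants are out of scope.
* The attention-gate channel arithmetic follows the standard additive
  formulation; other gate variants exist.
* Native CPU training is practical at desk scale but not at 512×512
  clinical scale; the `full_scale` preset documents that protocol
  without making it fast.
* Statistical comparisons treat per-subject scores as independent;
  observer-pair scores within a subject are correlated, which the
  pooled-pair ANOVA ignores (the per-subject-median option mitigates
  this).
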