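---
title: "Modelling feature similarity gain attention in a convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling feature similarity gain attention in a convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fsgain)
```

## The model

`fsgain` studies how attention-like gain modulation of a layered visual
model changes task performance. The network is a standard convolutional
stack: at layer $l$, feature map $k$ is

$$x_{ij}^{lk} = \left[(W^{lk} \star X^{l-1})_{ij}\right]_+,$$

a 2-D convolution of the layer below followed by positive rectification,
with 2×2 max-pooling after configured layers. Each feature map is the
model's analogue of a retinotopic population sharing a preferred feature.

**Tuning values.** For spatially averaged responses $r^{lk}(n)$ to images
$n$ with condition labels (here: grating orientations), the tuning value of
map $(l,k)$ for condition $c$ is the mean response to $c$ minus the grand
mean, divided by the population standard deviation over all images. A
map's tuning quality is its maximum absolute tuning value. We use the
population (biased) standard deviation; with the balanced condition
factorial used throughout, tuning values then sum to zero across
conditions up to rounding.

**Gradient values.** The alternative to tuning-guided modulation is
modulation along the loss gradient: $g_c^{lk}$ is the negated error
gradient of the relevant readout's cross-entropy with respect to the map's
unit activities, averaged over space and images. For detection and color
tasks, images the readout already classifies correctly are masked out
before averaging — the stated property is that correct classifications
contribute no gradient, and masking implements that property directly
(cross-entropy gradients are small but not literally zero at correct
decisions). When gradient values drive attention they are normalized per
layer and condition by the maximum absolute value, putting them on the
tuning-value scale.

**Attention.** Attending condition $c$ with strength $\beta$ either
rescales the ReLU slope,

$$x_{ij}^{lk} = (1 + \beta f_c^{lk})\,[I_{ij}^{lk}]_+,$$

(multiplicative), or shifts the pre-activation, $x = [I + \mu_l \beta
f_c^{lk}]_+$ (additive), where $\mu_l$ is the layer's mean activity over a
reference image population. Spatial attention sets the per-unit value to
$+\beta$ inside the attended quadrant and $-\beta$ outside; combined
feature+spatial fields add the two terms under one shared $\beta$ (we read
the combination rule literally as a single strength; a per-component
extension would be straightforward but is not provided). Bidirectional
application uses values as-is; positive-only rectifies them first. We
allow the literal multiplicative form to drive gains negative when
$\beta f < -1$ — the printed equation has no clamp — and document that the
activity ratio identity below still holds in that regime.

## The synthetic stimuli

All experiments run on generated stimuli: sinusoidal gratings at
orientations $0°, 20°, \dots, 160°$ in five fixed RGB colors (pure
red/green/blue, orange $(1, 0.5, 0)$, purple $(0.5, 0, 0.5)$), frequency
0.025 cycles/pixel, rendered as
$\text{rgb} \times (0.5 + 0.5\sin(2\pi\nu(x\cos\theta + y\sin\theta) +
\phi))$ with per-image random phase. Training images are degraded by
zeroing contiguous square blocks (side 4–16 px, uniformly placed, clipped
at borders, overlap allowed) until exactly $\lfloor d \cdot S^2 \rfloor$
unique pixels are dark, $d \sim U(0, 0.7)$ — degradation diversifies
training only; test images are left intact. Detection test scenes place
two half-canvas gratings of different orientation and color in two random
quadrants. Merged images average two stimuli pixel-wise; array images tile
four block-mean-downscaled stimuli 2×2. Detection sets are balanced
exactly (half contain the searched-for orientation).

These stimuli emulate the structure of the original paradigm — composite
scenes that make detection hard, balanced test sets, a fixed palette —
but not natural-image statistics: there is no clutter, no category-level
variability, and color is perfectly diagnostic. Passing tests therefore
demonstrate the mechanics and directional behaviour of the attention
model, not natural-scene performance levels.

## The fixture network

The trainable fixture has 5 convolutional layers of 8/16/16/32/32 feature
maps (3×3 filters, same padding, pools after layers 2 and 4), a softmax
readout over the 45 orientation×color classes on spatially averaged
final-layer features, and is trained with minibatch Adam (batch 15,
learning rate $2\times10^{-3}$, 30 epochs) on 4 images per class at
64×64 px. Per-image (unaveraged) updates at any workable rate collapsed
the deep layers into dead rectifiers; minibatch averaging is the stable
choice. Training is deterministic given the seed and must clear a held-out
accuracy floor (default: twice chance, i.e. 2/45); the canonical seed
reaches roughly 0.39.

Canvas size matters because spatial frequency is fixed in cycles/pixel: at
64 px a full-field grating spans 1.6 periods and a quadrant grating 0.8,
enough to express orientation; at 32 px a quadrant grating shows less than
half a period and orientation becomes nearly unreadable. The test-suite
fixture and the acceptance script therefore use 64 px; smaller sizes
remain available for fast unit-level work.

Detection readouts are per-orientation logistic classifiers fit on
final-layer spatially pooled features of the full-field training gratings;
the color readout is a 5-way multinomial fit on the same features. Both
use a small fixed ridge penalty ($\lambda = 10^{-2}$): gratings are
linearly separable in feature space and the unpenalized maximum-likelihood
weights diverge, which would saturate scores and starve the task
gradients. The softmax readout used for category-style gradients is kept
alongside the detector bank.

The fixture's detectors carry a high decision criterion on composite
scenes (true-positive rates well below 0.5 at threshold 0.5): features of
quadrant scenes are weaker than the full-field training features. This is
the regime the attention analyses are about — moderate feature attention
raises true positives before false positives follow. One practical
consequence: analyses that need images classified as positive (the
vector-angle measure) require reasonably large sets (n ≥ 50) for the
positive-classification direction to be defined.

## Recording protocol and diagnostics

Activity ratios (with-attention / without) are recorded from spatially
averaged feature-map activity on the undegraded full-field factorial,
color-averaged per stimulus orientation, at the protocol strength
$\beta = 0.5$. Maps whose baseline falls below $10^{-8}$ are excluded and
counted. At the applied layer, multiplicative tuning attention gives the
exact identity ratio $= 1 + \beta f$ for every positive-baseline map —
this closed form is the module's primary oracle and is tested at
$10^{-6}$ relative tolerance.

For the slope/intercept diagnostic, each map's nine attended-and-present
ratios are ordered from most to least preferred orientation (preference
from the map's own tuning curve at the recorded layer; ties break by
condition index), collapsed to five points — the most preferred alone at
position 0, then means of successive pairs — and fit by ordinary least
squares. Feature-similarity gain predicts negative slope and intercept
above one; intercepts are reported raw and plotted as the excess over one.
A map displays feature-matching behaviour instead if its modulation
follows the stimulus rather than its preference, operationalized by the
two-ratio criterion on preferred/anti-preferred attention × stimulus
combinations; the second criterion (anti-preferred attended and present
beats preferred present) is what separates feature matching from
feature-similarity gain, and a pure-FSGM ratio table can never satisfy it.

The per-image variant fits ratios against tuning values (slope $= \beta$
exactly at the applied layer) and pairs median slopes with the change in
true-positive rate; the vector-angle measure projects activity onto the
principal components retaining ≥ 90% of the variance of the no-attention
activity over all images (positives and negatives pooled — the fitting
population is our choice, as is fitting the PCA once without attention),
takes the mean reduced activity of classified-positive images as the
positive-classification direction, and compares median cosines with and
without attention. Correlations between measures and performance are
compared with a 100-replicate bootstrap and a two-sided t-test between the
replicate samples; this literal comparison is statistically unconventional
but is the stated procedure, and percentile CIs are returned alongside.
Degenerate bootstrap resamples (zero performance variance) yield NA
correlations and are dropped from the comparison, with a count reported.

## Numerical choices and degenerate inputs

- Signal detection: $\Phi^{-1}$ is `qnorm`; false-positive rates below
  0.01 are floored and true-positive rates above 0.99 capped before the
  transform (asymmetric, exactly as stated, so a detector that never
  fires has $d' = -\infty$ by construction); `symmetric = TRUE` clips
  both tails of both rates, which summary reports use so that criteria
  shifts stay finite for degenerate operating points.
- Dead feature maps (zero response variance) get tuning 0 and a flag;
  zero-baseline maps are excluded from ratio analyses.
- Beta grids step by 0.15 and include 0; the best-performing strength is
  the grid argmax, and matching a behavioral operating point picks the
  nearest discrete sweep sample (ties to the smaller $\beta$), without
  interpolation.
- When attention targets all layers simultaneously, the effective
  strength is $\beta / 10$.
- Per-map tuning–gradient correlations are Pearson across conditions;
  the shuffled control pairs each map's tuning with a random *other*
  map's gradients within the layer.

## Problem sizes

The default experiment scale — 64 px canvases, 180 training images, 30
epochs, 30–50-image detection sets, sweeps over four orientations at two
layers, and 30-shuffle controls — was chosen so a complete pipeline run
finishes in minutes on a single CPU while every directional effect the
model predicts (later-layer attention helping more, negated tuning
suppressing both detection rates, the FSGM ratio signature fading with
distance from the applied layer, feature-matching behaviour emerging
downstream) is resolvable above sampling noise. Two qualitative
expectations from the original large-scale setting do not transfer to a
shallow fixture and are documented rather than asserted: gradient
magnitudes are not smaller at the first layer than the last, and raw
tuning quality does not exceed its cross-map shuffled control.

## Limitations

The network is feed-forward and noiseless; there are no recurrent
dynamics, skip connections, or learned attention policies. Absolute
performance numbers depend on a small fixture trained on synthetic
gratings and are not comparable to large pretrained networks on natural
images; only signs, orderings and closed-form identities are meaningful,
and those are what the test suite asserts.
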