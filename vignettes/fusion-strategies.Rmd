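---
title: "Fusion strategies for retinal OCT classification: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion strategies for retinal OCT classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

FusionOCT implements three ways of combining convolutional base
classifiers for four-class retinal OCT triage (CNV, DME, drusen,
normal), plus the training protocol, evaluation formalism and
explainability tooling around them. This vignette records the models,
the parameters that matter, and the design and numerical choices made
where the design was genuinely open.

## The three fusion models

**FN-F1 (fixed late fusion).** Base classifiers are trained
independently; classifier *i* receives the fixed weight

$$W_i = \frac{F1_i}{\sum_p F1_p} + \left(F1_i - \overline{F1}\right) n,$$

where $F1_i$ is its validation F1 and $n$ expands the differences
between members. Because $\sum_i (F1_i - \overline{F1}) = 0$, the
weights sum to 1 for every $n$; the fused output
$\sum_i W_i \, p_i$ is therefore a probability vector. The package
summarizes validation F1 as the *support-weighted average* over classes
(`weightedAvg` of per-class F1), the same summary used in every report
table; macro-averaged F1 differs only under class imbalance of the
validation split. Negative weights (possible for exotic $n$) are
rejected with an error rather than clipped, since clipping would
silently break the probability-vector contract. The default is $n = 0$:
well-trained members have nearly equal validation F1, so the expansion
term adds variance without signal.

**FN-Weight (trainable late fusion).** Raw scalars $X, Y, Z$ are
normalized to effective weights $X/(X{+}Y{+}Z)$ etc., so only the
*direction* of $(X,Y,Z)$ matters. The per-sample loss is
$-\ln[(X m_t + Y n_t + Z p_t)/(X+Y+Z)]$ with $m_t, n_t, p_t$ the
true-class probabilities of the three members; batches are reduced by
the mean. The closed-form derivatives (e.g.
$\partial L/\partial X = [Y(n_t{-}m_t) + Z(p_t{-}m_t)] /
[(X{+}Y{+}Z)(X m_t {+} Y n_t {+} Z p_t)]$) are used in a plain
gradient-descent update $X \leftarrow X - \eta\, \partial L/\partial X$;
the network parameters may use any optimizer, but the $X,Y,Z$ rule is
fixed. Scale invariance implies the Euler identity
$X\,\mathrm{d}X + Y\,\mathrm{d}Y + Z\,\mathrm{d}Z = 0$, which the test
suite checks to $10^{-12}$ alongside a central-finite-difference oracle
($10^{-5}$ relative over 1000 random draws). Choices made here:
initialization $X=Y=Z=1$ (symmetric start, equal initial weights); no
positivity constraint on the raw scalars — only $|X+Y+Z| > 10^{-8}$ is
enforced, and a fused true-class probability that leaves the simplex
raises an error advising a smaller $\eta$; $\eta$ defaults to the
current phase's network learning rate and is separately configurable.

**FN-Auto (early fusion).** Each backbone's pooled embedding feeds two
fully connected layers: a softmax prediction head and a linear embedding
head of dimension $d$ (default 256 for large backbones; the compact
reference models use $d = 32$ in tests — the head architecture is a free
knob, so parameter counts of any particular published configuration are
not a target). The three embeddings are concatenated and a final dense
softmax head over the $3d$ vector produces the fused prediction — the
model's only prediction surface. Training minimizes the exact sum
$L_1 + L_2 + L_3 + L_4$ of the per-backbone and fused cross-entropies
with equal weights; the three auxiliary terms exist to backpropagate
each trunk directly, and a test verifies that removing them shrinks
early-layer gradient magnitudes. Concatenation (not addition) joins the
embeddings; weighted addition is what the two late-fusion strategies do
to output probabilities. The fused head is *not* in general a convex
combination of the three per-backbone predictions — a test constructs a
counterexample — which is precisely what separates early from late
fusion.

## Base classifiers, CBAM and the backbone contract

A base classifier is a trunk producing a spatial feature map, a CBAM
attention block, and a global-average-pool + dense softmax head. The
contract is pluggable via `registerBackbone()`; the tested default
family is `referenceCNN` (three 3×3 stride-2 convolution blocks → CBAM
→ pooled softmax head) with wider and deeper variants used to diversify
ensembles. The canonical large ImageNet backbone names are registered
as configurations that require an external runtime with pretrained
weights and raise an informative error otherwise; any such
implementation can be plugged in through the registry without touching
the fusion code.

CBAM follows the standard channel-then-spatial formulation: a shared
two-layer MLP over average- and max-pooled channel descriptors gives
per-channel sigmoid coefficients; a convolution over the channel-wise
average and maximum maps gives per-position sigmoid coefficients; both
multiply the feature map, so its shape is preserved and all
coefficients lie strictly in (0, 1). Defaults: reduction ratio 8,
spatial kernel 7 — conventional values, since the block's
hyperparameters are not dictated by anything else in the design. CBAM
sits after the trunk's final feature map and before pooling, once per
base classifier; its parameters train together with the heads during
the transfer phase (they are classifier-side, not trunk-side).

Two numerical choices in the reference architecture deserve a note.
First, the pooled embedding passes through a feature-wise batch
normalization before the dense head: pooled activations of a compact
randomly initialized trunk share a large common mean with tiny
between-image variance, which leaves a bare softmax head badly
conditioned; standardization makes head optimization fast regardless of
trunk activation scale. Training uses batch statistics; inference uses
running statistics, which are recalibrated with one full pass at the
end of each phase so they match the final trunk state. Second, the
trainers apply random horizontal flips (a B-scan and its mirror are
equally plausible) drawn from the seeded training stream; this is the
only augmentation.

## Two-phase training

Phase one (transfer) freezes every trunk convolution parameter —
bit-identical before and after, enforced by checksum tests — and trains
only heads and CBAM. Phase two (fine-tuning) continues from the phase-
one parameters with everything trainable, conventionally at a lower
rate (the configuration validates `lrFinetune <= lrTransfer`). Defaults
are 10 + 10 epochs at $10^{-3}$ / $10^{-4}$ with Adam for network
parameters, reasonable for large pretrained trunks; the compact
reference CNNs are trained from scratch in the examples and tests, where
hotter rates ($10^{-2}$ / $2\times10^{-3}$) and 8 + 8 epochs converge in
seconds. Adam is the network default because untuned SGD is fragile
across the depth range of the registry; plain SGD remains available and
the $X,Y,Z$ update is always plain gradient descent. Everything random —
initialization, shuffling, flips, subsampling, splits — derives from the
configuration seed, and identical configurations reproduce bit-identical
parameters and logs. Validation splits are stratified by class with a
default fraction of 0.1; `runExperiment` additionally offers `limited`
mode (a seeded subsample of k images per class, emulating
balanced-budget training) and `binary` mode (two named classes).

## Evaluation formalism

One-vs-rest reduction of the C×C confusion matrix gives TP, FN, FP, TN
per class, hence accuracy, recall, specificity, precision and
F1 = 2PR/(P+R); AUC is the trapezoidal area under the one-vs-rest ROC,
equal to the Mann–Whitney concordant-pair fraction (ties count half) —
an equivalence the tests verify exhaustively on all small instances.
Summary rows use the support-weighted average
$\sum_i P_i s_i / \sum_i s_i$.

One convention needs stating: in the rendered tables the per-class
"ACC" row reports each class's one-vs-rest *recall*. That is the only
reading under which a multiclass table's ACC and Recall blocks coincide
and the weighted-average ACC equals overall multiclass accuracy, which
is how such tables are conventionally printed; the strict one-vs-rest
accuracy (TP+TN over all) remains available from `perClassMetrics()`.
Ratios with zero denominators are reported as 0 and flagged as
degenerate rather than propagating NaN into reports. Displayed values
are rounded to 3 decimals; internal values keep full precision.

## The synthetic generator

`generateSyntheticDataset` emulates the geometry that drives OCT
reading: a horizontally layered band texture (dark vitreous, alternating
inner retinal bands, a bright RPE line, dimmer choroid) with gentle
sinusoidal curvature, a class motif, and multiplicative log-normal
speckle (default level 0.12, a visually plausible grain). Motifs follow
the qualitative appearance of each category: drusen as small bright
bumps protruding from the RPE band; DME as dark elliptical cysts in the
inner retina; CNV as one irregular bright lesion disrupting the layers
with a darker halo; normal as clean bands. Images are square (default
64 px for desk-scale work; preprocessing supports the conventional
299 px of the large backbones), fully determined by the seed, and
unit-interval.

What the generator does *not* emulate: true OCT speckle statistics,
device differences (e.g. between spectral-domain instruments of
different vendors), anatomical variability beyond band curvature and a
global lesion geometry, mixed pathologies, or the heavy class imbalance
of clinical archives. Passing the end-to-end tests therefore
demonstrates that the machinery — preprocessing, backbones, CBAM, all
three fusion strategies, both training phases, the metrics — is correct
and that the strategies can learn a geometrically OCT-like task at desk
scale; it does not certify clinical performance on real B-scans.

## Problem sizes and numerical details

Test and acceptance runs use 50 images per class at 64×64 with a
stratified 20% holdout, 8 + 8 epochs, batch 16 — sizes chosen so the
whole pipeline (including three independently trained members for the
fixed-fusion strategy) runs in a few minutes on one CPU while leaving a
comfortable margin over the 0.8-accuracy smoke threshold; at these
conditions the three strategies reach weighted-average accuracies of
roughly 0.9–1.0 depending on seed. Remaining numerical conventions:
$10^{-12}$ floor inside every cross-entropy logarithm; $|X+Y+Z| >
10^{-8}$ guard re-checked after every update; min–max normalization of a
constant image returns zeros with a warning; nearest-neighbour resizing
maps output pixel centers to source indices (so no new intensities are
created); hard-vote ties break deterministically to the lowest class
index; Grad-CAM maps are rectified, upsampled by the same
nearest-neighbour rule, and max-normalized unless identically zero.

## Known limitations

The compact reference CNNs stand in for the large ImageNet backbones in
all tests; results on real clinical OCT require plugging in pretrained
trunks through the backbone registry. There is no DICOM or vendor-format
reader (PNG/JPEG/TIFF directories only), no confidence intervals or
significance tests on the reported metrics, and Grad-CAM validation is
qualitative by nature.
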