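---
title: "Methods: hue-preserving enhancement and a lightweight spark-module classifier for dermoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hue-preserving enhancement and a lightweight spark-module classifier for dermoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermlight)
```

## Scope and problem

`dermlight` is a desk-scale pipeline for classifying pigmented skin
lesions (PSLs) into nine diagnostic categories (AK, BCC, BKL, DF, NV,
MEL, SCC, VASC, PBK) from RGB dermoscopy images. It covers the full
chain — perceptual contrast enhancement, a compact convolutional
classifier, class-balancing augmentation, AdaBelief optimization with
weighted cross-entropy, stratified cross-validation, and macro-averaged
multiclass evaluation — and pairs it with a synthetic dermoscopy image
generator so every stage is testable without clinical data. The package
does not ship, download, or depend on any clinical image corpus, and it
makes no claim about accuracy on real dermoscopy data; its quantitative
guarantees are architectural and algorithmic (exact parameter
accounting, exact metric arithmetic, verified hue preservation, a
learning sanity check on separable synthetic classes).

## Hue-preserving perceptual enhancement

Dermoscopic diagnosis leans heavily on colour; an enhancement that
shifts hue can destroy diagnostic patterns. The preprocessing therefore
manipulates only the intensity structure of an image while keeping each
pixel's hue fixed.

The geometric hue of a pixel \((r,g,b)\) is
\(\theta = \arccos\!\big(\tfrac12[(r-g)+(r-b)] \,/\,
\sqrt{(r-g)^2+(r-b)(g-b)}\big)\), reflected to \(2\pi-\theta\) when
\(b>g\), and defined as 0 for achromatic pixels. This quantity is
invariant under any per-pixel map of the form \(x \mapsto a\,x +
t\,(1,1,1)^\top\) with \(a>0\) — the invariance that drives the design
of the reconstruction step.

`enhance_image()` applies, in order:

1. **Optional dominant-region selection.** A configurable center crop
   (`roi_mode = "center_crop"`, off by default) resized back to the
   input geometry. Dermoscopy images concentrate the lesion centrally,
   but no principled region selector is part of this pipeline's scope,
   so the crop is the deliberate, simple default-off choice.
2. **Global min-max stretch** over all three channels jointly,
   \(X' = (X - X_{\min})/(X_{\max} - X_{\min})\). Joint (not
   per-channel) normalization is itself hue-preserving. A constant
   image is mapped to zeros with a warning rather than an error, so
   batch preprocessing survives blank frames.
3. **CIECAM02 decomposition.** The stretched image is converted to the
   CIECAM02 lightness/chroma/hue (JCh) appearance correlates under
   configurable viewing conditions (default: D65 white as realized by
   the sRGB primaries, adapting luminance 64 cd/m², background
   luminance factor 20, average surround). By default the model assumes
   complete chromatic adaptation (`discount_illuminant = TRUE`), which
   is the appropriate assumption for display-referred imagery and makes
   the white point map to zero chroma; the luminance-dependent
   adaptation degree of the standard model is available. The forward
   model reproduces the canonical published test values (J = 41.73,
   C = 0.105, h = 219.05 for the standard test stimulus) and the
   inverse model round-trips in-gamut pixels to better than 1e-4 per
   channel. Normalized planes h/15, and unit-scaled J and C divided by
   0.43, are carried alongside, weighting hue relative to the other
   correlates.
4. **Intensity extraction** with the Rec. 601 luma weights
   \(J = 0.299R + 0.587G + 0.114B\) (weights sum to 1, so gray pixels
   keep their value).
5. **Contrast enhancement with fusion.** A *global* map — a sigmoid
   with gain \(g\) (default 8) and cutoff \(c\) (default 0.5), rescaled
   over the endpoints of the [0,1] domain so it spans [0,1], stays
   strictly monotone, and equals 0.5 at a centered cutoff — and a
   *local* map — contrast-limited tile-wise histogram equalization
   (CLAHE, default 8×8 tiles, clip factor 2) — are fused per pixel:
   \(GI = w\,G_{\text{glob}} + (1-w)\,G_{\text{loc}}\). The default
   weight combines local RMS contrast (5×5 box window, normalized to
   [0,1]) with a brightness term \(1-2|J-\tfrac12|\) that favours the
   global map at mid-tones; a fixed scalar weight is available. The
   hue plane travels with the intensity plane through this stage but
   does not steer the CLAHE tiling: the tile grid is fixed by
   configuration, since the underlying CLAHE implementation exposes no
   tile-origin control and tile alignment is a second-order effect.
   A constant intensity plane has no local contrast; `G_loc` then falls
   back to the global map so the output remains constant.
6. **Hue-preserving reconstruction.** Per pixel,
   \[
   G_c = \begin{cases}
   X'_c \cdot GI/J, & GI \le J\\[2pt]
   \dfrac{1-GI}{1-J}\,(X'_c - J) + GI, & GI > J .
   \end{cases}
   \]
   Both branches are of the hue-invariant form \(a\,x + t\) with the
   same \(a>0\) and gray shift for all three channels, and they agree
   exactly at \(GI = J\). The scale branch darkens towards black; the
   shift-then-scale branch brightens towards white while provably
   staying inside [0,1]. \(J\) is floored at \(10^{-6}\) so
   zero-intensity pixels remain defined, and near-achromatic pixels
   (channel spread below `hue_epsilon`, default 1e-9) are treated as
   hue 0 to keep the arccos stable.

The property the tests enforce end-to-end: for random pixels and random
enhanced intensities, the hue of the reconstruction matches the hue of
the input to 1e-6 radians wherever hue is defined, on both branches.

## The classifier: spark modules

The network is a SqueezeNet-style fully-convolutional classifier. The
classical fire module squeezes the channel dimension with a 1×1
convolution (S channels) and re-expands it through parallel 1×1 (E1)
and 3×3 (E3) convolutions whose outputs are concatenated. The *spark*
module keeps this topology but replaces the 3×3 expand path with a
depthwise-separable convolution — per-channel 3×3 spatial filtering
followed by a 1×1 pointwise projection — and attaches batch
normalization and a GELU activation to every convolution. For a 3×3
expand path with S inputs and E3 outputs this cuts the weight count
from \(E3 \cdot S \cdot 9\) to \(S \cdot 9 + S \cdot E3\) (8,768 vs
73,728 at S = 64, E3 = 128), with the corresponding multiply-accumulate
saving at every spatial position.

The graph is: strided 3×3 stem convolution → max-pool → spark ×2 →
max-pool → spark ×2 → max-pool → spark ×4 → dropout (0.5) → 1×1
convolution onto the 9 class logits → global average pooling → softmax.
Exactly three max-pool stages plus the global pooling stage are used,
the classical SqueezeNet v1.1 pooling plan. All tensors are
channel-first; convolutions are im2col + BLAS matrix products with
hand-written backward passes, verified against finite differences and
a brute-force convolution oracle in the test suite.

### Width calibration

The channel plan is not hand-picked: it is the frozen output of
`calibrate_network_plan()`, which fixes the plan so that the network
holds exactly 3,182,412 trainable parameters at the 512×512×3, 9-class
geometry. The search first scans a coarse width-multiplier grid
(multiples of 0.125 over the v1.1 skeleton, channels rounded to
multiples of 8), then refines to exactness with single-channel integer
adjustments of the stem width and the last spark module's squeeze
width, solving the last module's 1×1 expand width in closed form — the
total is linear in that width with slope \(S_8 + 2 + K\) (squeeze
weights + its BN pair + head weights per channel). Coarse ±8-channel
moves alone cannot land on an arbitrary integer budget, which is why
the refinement works at single-channel granularity. Among exact
solutions the smallest total adjustment wins, making the result
deterministic: stem 252; sparks (S,E1,E3) = (64,240,240)×2,
(120,480,480)×2, (184,720,720)×2, (240,960,960), (218,945,960). The
per-layer ledger (`count_parameters()`) and the number of weights
actually allocated agree exactly, by construction and by test.

FLOP accounting uses the 1 MAC = 2 FLOPs convention and excludes batch
normalization, activations and pooling; the convention is recorded in
every report. Biases are disabled on convolutions followed by batch
normalization (they are redundant with the BN shift); the head keeps
its bias. The serialized-size estimate assumes 4 bytes per parameter.

## Synthetic data generator

The generator emulates the *composition* and *coarse appearance* of a
pooled dermoscopy corpus, not its biology. `generate_manifest()` scales
a fixed nine-class composition (700, 3300, 2600, 200, 12000, 4000, 600,
300, 300 — total 24,000 at scale 1; NV dominant, DF/VASC/PBK rare),
rounding half-up with a one-record floor so tiny manifests keep all
nine classes. `synth_image()` renders a skin-toned background plus one
elliptical lesion with a smoothly irregular border (low-order sinusoidal
radial modulation, amplitude 0.12), class-conditional colour, texture
noise, and optional dark hair strokes. Per-class colour means are
separated by far more than two within-class standard deviations *by
construction*, so the classes are statistically separable; semi-axes
span 15–32% of the image side.

This is what passing tests do and do not show: the generator provides
deterministic, class-separable fixtures, so the tiny-overfit run
demonstrates that the full gradient path — enhancement-compatible
inputs, spark modules, BN, GELU, dropout, weighted loss, AdaBelief —
can drive training accuracy to ≥ 0.95, i.e. the pipeline *learns*. It
does not demonstrate dermatological validity: real lesions are not
ellipses, real class boundaries are not colour-separable, and no
covariate shift, calibration or inter-rater noise is modelled.

Augmentation follows a fixed operating configuration: rotation within
±30°, brightness factor in [0.9, 1.1], zoom and shear magnitude 0.1,
horizontal and vertical flips, constant border fill, 1/255 intensity
rescale (the package works on [0,1] throughout), additive Gaussian
noise with standard deviation 0.45 on that scale, and Gaussian blur
with probability 0.25. The noise value is interpreted as a standard
deviation on the rescaled intensity scale — the magnitude is
configurable since no units accompany the value. Both flips are
implemented and individually toggleable. `balance_classes()` equalizes
class counts by adding augmentation records (source + seed, nothing
rendered until needed), which supports both materialized balancing and
on-the-fly augmentation during training.

## Optimization

AdaBelief adapts the step to the *belief* in the gradient: with EMAs
\(m_t = \beta_1 m_{t-1} + (1-\beta_1) g_t\) and
\(s_t = \beta_2 s_{t-1} + (1-\beta_2)(g_t - m_t)^2\), bias-corrected,
the update is \(\theta \leftarrow \theta - \alpha\,\hat m_t /
(\sqrt{\hat s_t} + \epsilon)\) with \(\beta_1 = 0.9\),
\(\beta_2 = 0.999\), \(\epsilon = 10^{-8}\). Epsilon enters the
denominator only and nothing is added inside the \(s\)-update, so the
single-step hand value \(\theta_1 = 1 - 10^{-3}/0.9 \approx 0.9988889\)
from \(\theta_0 = 1\), \(f = \theta^2/2\) is reproduced exactly; this
pins down the variant.

Defaults: learning rate \(10^{-3}\), 40 epochs, batch 16, step schedule
halving the rate every 10 epochs (the period is a package choice — only
the policy and factor are fixed), decoupled weight decay 0 (available
as a knob), 10-fold stratified cross-validation. Early stopping
(patience on validation loss) is implemented but off by default, so the
default run is the fixed 40-epoch protocol. The loss is weighted
cross-entropy with inverse-frequency class weights
\(w_c = N/(K\,n_c)\), the package's choice of weighting — weights
average 1 on a balanced set, and the loss is linear in the weights.
Probabilities are floored at 1e-12 inside the log.

Stratified folds shuffle within each class and deal records
round-robin, so per-class proportions across folds differ by at most
one record; classes rarer than k records trigger a warning rather than
an error.

## Evaluation

Per class, the confusion matrix is reduced one-vs-rest (TP = diagonal
entry, FN = row remainder, FP = column remainder, TN = rest) and
accuracy, precision, recall/sensitivity, specificity, F1 and MCC are
computed from the counts. Zero-denominator rates are reported as 0 —
an unstated-edge-case convention chosen so batch evaluation is total.
Macro values are unweighted means over the nine classes. Because
macro-averaged one-vs-rest accuracy and plain top-1 accuracy genuinely
differ in multiclass problems, the report carries both, clearly
labeled. AUC is rank-based (Mann–Whitney with mid-ranks for ties,
equivalent to trapezoidal ROC integration) one-vs-rest on softmax
scores; a class absent from the labels yields NA and is excluded from
the macro with a warning. The metric arithmetic is validated against a
brute-force enumeration oracle on 1,000 random confusion matrices at
1e-12, and the AUC against an independent reference implementation.

## Numerical and design choices

* **Problem sizes.** The default desk-scale runs use 64×64 inputs with
  width multiplier 0.25 (≈222k parameters) for training demonstrations,
  and 32×32 for the orchestration smoke runs; these sizes exercise
  every layer type, three pool stages and the full gradient path. The
  full 512×512 configuration is instantiated for parameter accounting,
  where no training is required.
* **Determinism.** Every stochastic stage takes an explicit seed; a
  single experiment seed fans out to stage seeds by fixed offsets.
  Package functions save and restore the caller's RNG state.
* **Degenerate inputs.** Constant images stretch to zeros with a
  warning; constant intensity planes bypass CLAHE; J = 0 pixels are
  floored before the ratio branch; near-achromatic pixels take hue 0;
  pooling rejects odd spatial sizes with a named-dimension error;
  channel mismatches and wrong input geometry report expected vs
  received.
* **Ties.** Max-pool routes the gradient to the first maximal element
  of each 2×2 window; AUC mid-ranks ties (constant scores give exactly
  0.5); argmax predictions take the first maximum.
* **BN placement.** "Batch normalization around each convolution" is
  realized as conv → BN → activation, the placement that keeps the
  module trainable; it is toggleable, and biases appear exactly where
  BN is absent.
* **Known limitations.** No real-data claims (see above); the
  pure-R/BLAS network is CPU-bound and intended for desk-scale
  geometries, not 512×512 training; CIECAM02 is applied pixel-wise
  with no spatial adaptation model; the FLOP figure is a closed-form
  MAC count, not a measured runtime.
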