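---
title: "Class-selective relevance mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-selective relevance mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmap)
```

## The problem

A convolutional network that classifies images — here, the acquisition
modality of a biomedical image (CT, MRI, ultrasound, radiograph,
micrograph, fundus photograph, statistical graph) — gives no account of
*where* in the image its decision came from. Saliency maps answer that
question for the restricted but common architecture in which the last
convolutional layer's feature maps $f_k(x,y)$ (size $u \times v$,
channels $k = 1,\dots,K$) pass through global average pooling (GAP) into
a single dense layer. The pre-activation score of class $c$ is then

$$S_c \;=\; \sum_k w_k^c \, \bar f_k + b_c, \qquad
  \bar f_k = \frac{1}{uv}\sum_{x,y} f_k(x,y),$$

which is linear in every spatial element of every feature map. `crmap`
implements three maps over this head:

* **CAM** — $M_c(x,y) = \sum_k w_k^c f_k(x,y)$, the per-class weighted
  sum. May be negative; no ReLU; the bias is excluded.
* **Grad-CAM** — $\mathrm{ReLU}\!\left(\sum_k \alpha_k^c
  f_k(x,y)\right)$ with $\alpha_k^c = \sum_{x,y} \partial S_c /
  \partial f_k(x,y)$. For a GAP head, $\partial S_c/\partial f_k(x,y) =
  w_k^c/(uv)$, so $\alpha_k^c = w_k^c$ exactly and the ReLU is the only
  difference from CAM. The package exposes both the analytic route and a
  gradient route (the fixture adapter supplies finite-difference
  gradients), and tests that they agree.
* **CRM** — the class-selective relevance map. Element $(l,m)$ is scored
  by the total squared change it induces across *all* $N$ class scores
  when removed from every feature map:
  $$R(l,m) = \sum_{c=1}^{N} \left(S_c - S_c^{(l,m)}\right)^2,$$
  where $S_c^{(l,m)}$ is the score recomputed with $f_k(l,m) = 0$ for
  all $k$ (the GAP divisor stays $uv$; removal drops the term without
  renormalizing). Under the mean-GAP convention this has the closed form
  $$R(l,m) = \sum_c \left(\frac{\sum_k w_k^c f_k(l,m)}{uv}\right)^2
           = \frac{1}{(uv)^2}\sum_c M_c(l,m)^2,$$
  the sum of squared per-class CAM contributions. Biases cancel in the
  difference. Because every output node enters, an element that pushes
  the correct class up *and* pushes competing classes down scores
  doubly: the map is class-discriminative by construction, which is what
  distinguishes CRM from the single-class CAM family.

`brute_force_crm()` realizes the removal definition literally (zero one
element, re-run the head, accumulate squared differences over $uv$
passes). It exists as the independent correctness oracle: the central
test of the package asserts closed form $=$ brute force to $10^{-6}$
relative tolerance on hundreds of randomized instances.

Class-level maps average the CRM over all images of a class
(`average_crm()`; the mean rather than the plain sum — the normalized
heatmap is identical either way), and the class-level ROI is the tight
bounding box of pixels above 70% of the averaged map's maximum.

## Heatmap pipeline and its conventions

Raw maps are normalized to $[0,1]$, upsampled to input resolution, and
thresholded; statistics are computed at input resolution.

* **Normalization.** Non-negative maps (CRM, Grad-CAM) divide by their
  maximum. Maps containing negatives (CAM) are min–max normalized, the
  standard display convention under which the zero level sits at
  mid-gray. An earlier clip-negatives-then-divide variant was rejected:
  it collapses CAM's ROI wherever the map is negative over much of the
  image and inverts the expected CRM-smaller-than-CAM ROI ordering; the
  magnitudes reported for real models (CAM ROIs covering 55–91% of the
  image) are only reproducible under min–max. The two rules coincide
  whenever the map minimum is zero, so identical raw maps are treated
  identically and the CAM/Grad-CAM identity for non-negative weights is
  unaffected. An identically zero map stays zero.
* **Thresholding** is strict (`value > fraction`), with 0.2 as the
  display default ("above 20% of the max") and 0.7 for class-level ROI
  boxes. Retained-pixel counts are monotone non-increasing in the
  fraction.
* **Upsampling** is bilinear by default (nearest-neighbor available)
  using the half-pixel-center convention: source cell $i$ of an
  $n$-cell axis covers output span $((i-1)h, ih]$ and is sampled at its
  center. This keeps the upsampled map registered with the
  receptive-field patch each feature-map cell summarizes; the
  align-corners alternative misregisters by up to half a cell at the
  borders, which measurably displaces the argmax. Constant maps stay
  constant, values stay inside the input range, and same-size
  upsampling is the identity.
* **Order of operations** for ROI statistics: normalize at map
  resolution, upsample, then threshold — pixel counts and ratios are
  quoted at input resolution.

Evaluation (`compare_methods()`) reports, per class and method, the mean
ROI pixel count and ratio and the pooled pixel-score mean and standard
deviation (population denominator; immaterial at pooled-pixel sample
sizes, fixed for determinism). All pixels enter the distribution,
background included. CAM and Grad-CAM target the predicted class; CRM
has no class argument.

## The synthetic world

No external dataset is required. `generate_class_image()` draws one of
seven "modality-like" classes, each with a class-consistent structure at
a known location (the ground-truth mask) on a shared dark field
(intensity 0.07) with shared clutter (three faint Gaussian blobs,
amplitude 0.12) and pixel noise (sd 0.05, the default `noise_level`):

| class | structure (mask) |
|-------|------------------|
| 1 | elliptical ring with interior blobs (CT-like); mask = filled ellipse |
| 2 | two concentric lobed ellipses (MRI-like); mask = outer lobe |
| 3 | speckled fan with bright near-field apex (ultrasound-like); mask = fan |
| 4 | two dark lobes in a bright body (chest-radiograph-like); mask = body |
| 5 | 4–7 soft-edged bright blobs (fluorescence-like); mask = blob support |
| 6 | shaded disc with a small bright disc on a random side (fundus-like); mask = small disc |
| 7 | bright axes plus a random-walk polyline (graph-like); mask = strokes |

Structures are jittered per image: rotation in $[-5, 5]$ degrees, shifts
in $[-3, 3]$ pixels (the augmentation ranges used for the real data the
package emulates), scale in $[0.88, 1.12]$. Every rendering passes
through a Gaussian point-spread blur ($\sigma = 1.2$ px) — real imaging
chains have no hard edges. Masks are the drawn structure dilated by half
a feature-map cell (4 px at the default stride of 8), the localization
tolerance inherent to saliency maps computed at map resolution, in the
spirit of the pointing game's tolerance margin. The generator enforces a
mask-area invariant of 2–60% of the image; the graph polyline is a
bounded random walk and the fluorescence recipe budgets each blob's
dilated footprint so the invariant holds by construction for every seed.

Several of these choices were forced by observing what a small,
from-scratch CNN actually learns. With class-specific background levels
the network classified by global intensity and the relevance maps spread
everywhere; per-image mean-centering at the model input (standard
preprocessing for modality classifiers) and a single shared background
removed that shortcut. With any class visually
distinguished by its empty corners, the most class-selective cells were
*background* cells carrying anti-evidence ("no ring arc here"), and the
CRM peak sat 20 px outside the object; equalizing background statistics
across all seven classes — including rendering the graph class
dark-theme — eliminated it. These failure modes are worth knowing about:
they are properties of small models trained on small data, not of the
mapping algorithms.

**What a green test establishes, and what it does not.** The synthetic
world demonstrates that the three maps are computed correctly, that CRM
localizes the class evidence of a genuinely trained CAM-compatible
model, and that the qualitative comparisons (CRM ROIs smaller than CAM's;
CAM and Grad-CAM near-identical) reproduce directionally. It does not
calibrate any quantitative claim about real medical images: structures
here are geometric, clutter is benign, intra-class variation is
parametric jitter, and the classifier is far stronger relative to its
task than any real modality classifier.

## The fixture CNN

`tiny_model_spec()` describes a network of three 3×3-conv + 2×2-max-pool
blocks (8, 16, 32 channels), a final 3×3 convolution to $K = 64$
channels at $8 \times 8$, then GAP and a dense 7-class layer — the
CAM-compatible head at desk scale. Convolution forward/backward are
im2col + BLAS products in compiled code; gradients are verified against
finite differences in the test suite. Training
(`train_fixture_model()`) minimizes softmax cross-entropy with Adam
(learning rate $10^{-3}$, mini-batch 10), plus a 12 px random-erasing
(cutout) augmentation. Cutout plays the role that large-scale
pretraining plays for a full-size backbone: it penalizes reliance on any
single context location, pushing class evidence onto the redundant
structure itself; without it the network repeatedly latched onto one
boundary cell per class. Everything derives from one seed (weight
initialization, shuffling, cutout placement), so a fixed seed reproduces
training bit-for-bit on a fixed platform.

Defaults were pinned after one calibration run: 50/10/10 images per
class per split at $64 \times 64$, 30 epochs, about two minutes on one
CPU, reaching test accuracy 1.00 at the pinned seeds with CRM argmax
localization 91% and all directional method comparisons holding in all
seven classes.

## Numerical and interface choices

* GAP uses the mean (divide by $uv$); every normalized or thresholded
  product is invariant to this positive factor, and CRM's closed form
  absorbs it as $(uv)^{-2}$.
* Biases are included in class scores (they matter for the argmax) but
  cancel in every score difference the maps use; CAM excludes them.
* Argmax ties break to the lowest class index; R's 1-based indices are
  used throughout the API, with JSON sidecars serializing bounding boxes
  0-based inclusive.
* Degenerate inputs: all-zero maps normalize to zero (no division) and
  make class-ROI extraction an error (`empty ROI`); $N = 1$ heads are
  permitted, where CRM reduces to $M_1^2/(uv)^2$.
* Image I/O uses the portable anymap formats (PGM/PPM, binary and
  ASCII): the deployment environment provides no PNG/JPEG codec for R,
  and the netpbm header-plus-raster layout is trivial to read anywhere.
* Errors are classed conditions (`crmap_invalid_input`,
  `crmap_contract_violation`, `crmap_range_error`,
  `crmap_unsupported_architecture`) so callers can distinguish bad data
  from broken contracts.

## Known limitations

* Only the conv → GAP → single-dense head is supported; multi-layer
  dense heads would break the linearity that CAM and the CRM closed form
  rely on, and `extract()` rejects adapters whose logits disagree with
  the GAP-head recomputation.
* The removal semantics zero a spatial element without renormalizing the
  pool; alternative semantics (renormalized mean, patch occlusion at
  input resolution) are out of scope.
* Class-level ROI extraction returns a single bounding box (the hull of
  suprathreshold pixels), not connected components.
* The fixture CNN is deliberately small; its receptive field (~38 px of
  a 64 px image) lower-bounds how sharply any map can localize, and the
  half-cell mask margin reflects exactly that.
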