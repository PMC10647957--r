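---
title: "Unsupervised affine co-registration with a differentiable MI loss: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised affine co-registration with a differentiable MI loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mireg)
```

## The registration model

`mireg` aligns a multimodal pair — a fixed image $F$ (CT-like) and a
moving image $M$ (MR-like) of the same anatomy — with a six-parameter
2D affine transform $T_\mu$, $\mu = (a_{11}, a_{12}, a_{21}, a_{22},
t_x, t_y)$. The architecture is a regularized spatial transformer with
four stages:

1. **Concatenator.** Both images are z-scored (dataset-level pooled
   statistics per modality when training a corpus, per-image statistics
   at single-pair inference, where pooled statistics do not exist) and
   stacked into one 2-channel input. Multimodal corpora mix scanners
   and procedures, so raw intensity ranges vary wildly; standardization
   is what keeps the conv stack's operating point sane.
2. **Localization network.** A CNN maps the stack to $\mu$ in one shot:
   stride-2 same-padded $3\times3$ convolutions (filters
   $[32,32,32,32,32]$ by default), leaky-ReLU slope $0.2$, He-normal
   weights, a flatten, and one dense layer to 6 outputs. At a
   $256\times256$ input the five halvings give an $8\times8\times32$
   map, a flatten length of $2048$, and $49{,}894$ trainable
   parameters; swapping the first filter count to 16 gives $44{,}982$.
   These totals are exactly reproduced by
   `count_parameters(network_config(...))` and pin down two choices the
   architecture description leaves open: the kernel is $3\times3$ and
   the padding "same" — no other standard combination reproduces both
   printed totals and the flatten length.
3. **Affine-to-field layer.** The six parameters are "decrypted" into a
   dense displacement field $u(x) = A(x-c) + c + t - x$ on the pixel
   grid. Smoothness regularizers are defined on fields, not on the
   encrypted parameter vector, so this layer is what makes a
   field-space penalty applicable to an affine model at all. The map is
   linear in $\mu$; its Jacobian is the closed-form basis the training
   loop chains through.
4. **Resampler.** Backward bilinear warping,
   $\hat M(x) = M(x + u(x))$, with a constant fill (default 0) outside
   the frame. It is linear in intensities and piecewise differentiable
   in the field; the analytic spatial gradients are exposed and are
   verified against central differences to a relative error below
   $10^{-3}$ on smooth images (the check avoids integer sample
   positions, where bilinear interpolation genuinely kinks).

### The loss

Training minimizes $-\mathrm{MI}(F, \hat M) + \lambda R(u)$ with no
ground-truth deformations. MI is computed from a joint intensity
histogram; hard counts have zero gradient, so each pixel pair spreads
unit mass over neighboring bins with a triangular (linear B-spline)
Parzen kernel, bandwidth 1 bin. This makes the table — and MI — exactly
differentiable in the warped intensities. Conventions, each of them a
deliberate choice where the method description is silent:

* **Bins**: 64 by default. **Log base**: 2, so closed-form test values
  read as bits (1 bit for two matched equiprobable symbols,
  $\log_2 k$ for a $k$-symbol diagonal).
* **Bin range**: per-image min/max, widened by a relative $10^{-6}$
  so extremal pixels stay interior, recomputed every forward pass.
  Fixed global ranges are fragile across heterogeneous scanners. The
  range is treated as a constant in the gradient; only the two
  extremal pixels of an image feel the difference.
* **Per-pixel weight normalization**: kernel weights are normalized to
  sum to one per pixel, which conserves total mass and makes marginals
  exact soft histograms. A consequence worth knowing: at bandwidth
  $\le 0.5$ the normalized kernel degenerates to nearest-bin hard
  assignment, so the soft histogram *equals* the hard one — the
  bandwidth sweep in the tests converges to zero error, not just
  toward it. Pixels whose shrunken kernel support contains no bin
  center fall back to their nearest bin with zero local gradient.
* **Plain vs normalized MI**: the loss is plain MI as printed in the
  method's objective; a normalized-MI variant
  $(H(F)+H(M))/H(F,M)$ sits behind `mi_config(normalized = TRUE)`
  (with its own analytic gradient) since the literature uses both and
  the source is ambiguous about which was trained.

### The regularizer

The method never names its regularizer term. The default is **bending
energy** (mean squared second finite differences of the field,
$u_{rr}^2 + 2u_{rc}^2 + u_{cc}^2$ summed over components) on the
size-normalized field with $\lambda = 0.01$: it is the standard field
smoothness penalty, and affine fields lie exactly in its null space, so
it cannot bias the affine solution — it penalizes only non-affine
pathologies of the decoding pathway. Because the energy is identically
zero *as a function of the six parameters*, its parameter gradient is
exactly zero and is not back-propagated. `l2-displacement` (mean
squared displacement, which does pull toward the identity) is available
where an explicit shrinkage prior is wanted; the tests use it to show
regularizer dominance collapses the transform to the identity.

### Training and decoding

Adam (learning rate $10^{-4}$, 500 epochs, batch 4, full images, no
augmentation — the published recipe) updates all weights through the
chain loss → resampler → field → parameters → dense → convs. The dense
output is decoded as a *residual from the identity*, with the final
layer zero-initialized: an untrained network is then exactly the
identity warp and the initial loss equals $-\mathrm{MI}(F, M)$, the
standard stabilization without which MI-driven training does not
converge from a cold start. He-normal initialization applies everywhere
else. One integer seed fixes weight initialization and data order.

## The direct per-pair optimizer

`optimize_single_pair()` performs the same MI maximization over $\mu$
without any network, from an identity start, with Adam on a
coarse-to-fine pyramid (blur + 2× downsampling per level; translations
rescaled between levels). Defaults: 150 iterations per level, learning
rate 0.02 at the finest level and double that on coarser ones, decaying
exponentially to a tenth within each level — large early steps cover
the capture range, small late steps settle the flat rotation/shear
directions of the MI surface. Pyramid depth adapts so the coarsest
level is about 32 px; the histogram bin count halves per level so
coarse joint histograms stay populated. This routine doubles as the
independent oracle for the loss/transform stack in the test suite and
as a practical one-pair registrar.

## Evaluation metrics

* **TRE**: per-landmark Euclidean distance in mm between identically
  named points, plus the mean. The direction convention is fixed as
  forward-mapping of *moving* landmarks into fixed space; since the
  resampler is a backward warp, that mapping is the centered inverse of
  the recovered parameters, and `evaluate_pair()` applies it.
* **Dice** $2|A\cap B|/(|A|+|B|)$ and **Jaccard** $|A\cap B|/|A\cup B|$
  on binary masks, related by $J = D/(2-D)$ (verified on random masks).
  Two empty masks score 1 with a warning — reachable on tumor-free
  strata.
* **Hausdorff**: symmetric max-min distance between 8-connected mask
  boundaries, scaled by pixel spacing; exact against an $O(n^2)$
  brute-force oracle.
* Physical-coordinate policy: transforms act in pixels, metrics report
  mm, and the conversion happens exactly once, at the landmark/mask
  boundary, using header spacing.

## The synthetic phantom

The generator stands in for a private clinical corpus, so its realism
is deliberately minimal — ellipses plus noise — and its purpose is
precise: a registration problem whose answer is known exactly. One
anatomy (elliptical skull ring, brain, two ventricles, midline falx,
optional tumor) is rendered through two label-to-intensity maps that
order tissues differently (skull brightest on CT-like, ventricles and
tumor brightest on MR-like), blurred ($\sigma = 1$ px) and given
additive Gaussian noise (sd 0.02 / 0.03 of the unit intensity scale for
the CT-like / MR-like channel — the MR-like map gets slightly more, as
soft-tissue-weighted acquisitions are the noisier ones after
standardization). The cross-modality relation is non-affine by
construction: a pixelwise linear regression between the two renderings
leaves most of the variance unexplained, so correlation-based losses
would fail while MI does not.

One subtlety shaped the geometry. Any ellipse-to-ellipse map is exactly
reproducible by an affine transform, so a phantom dominated by the
skull ellipse leaves rotation almost unidentifiable — early versions
placed the MI optimum at the wrong rotation. The interior therefore
carries deliberate rotational anchors: elongated ventricles tilted
±18° and shifted anteriorly, and a falx stripe with asymmetric
anterior/posterior extent and contrast in both modalities. With these,
hard-histogram MI peaks at the true alignment on every generated pair
(a property the test suite asserts).

The moving image is built by warping the MR-like rendering with the
*centered inverse* of a randomly drawn affine, so the resampling
parameters that re-align it onto the fixed image are exactly the drawn
truth — no inverse bookkeeping leaks into user code. Landmarks (9
skull/midline/center, 5 tumor) are placed analytically from the
resolved geometry and carried in both spaces; masks likewise. Draw
bounds default to translation ±10 px, rotation ±15°, isotropic scale
0.9–1.1, shear ±0.05 — within the capture range of an
identity-initialized model, as misalignments after clinical
slice-selection typically are. Everything is a pure function of one
seed.

What passing tests on the phantom do **not** show: robustness to MR
bias fields, CT beam hardening, anatomy that differs between the two
acquisitions (resection, tumor growth), or multi-scanner intensity
heterogeneity beyond per-modality noise. Conclusions about clinical
data require clinical data.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a single CPU: phantoms
are generated at $128\times128$ (the generator also runs at
$256\times256$, mirroring clinical slice size), the direct optimizer
and its oracle sweeps run at that resolution, and the trained-network
demonstration uses $64\times64$ smoothed half-resolution inputs with a
$[16,16,16,16]$-filter network (8.8k parameters), 150 epochs at
learning rate $10^{-3}$ — a deliberately scaled-down study whose
predicted translations are doubled back to the native grid. On 20
seeded pairs this setup recovers translations to well under a pixel,
rotations to well under a degree, and cuts median landmark TRE by
roughly 90%. Degenerate inputs are handled explicitly: constant images
park all histogram mass in one bin (and refuse self-normalization),
singular linear parts are rejected at construction, out-of-bounds
samples take the fill value with zero gradient, and both-empty mask
pairs score perfect overlap with a warning.

## Scope and limitations

The pipeline is 2D end to end, matching the slice-based setting and the
printed architecture arithmetic (the parameter totals are only
consistent with 2D convolutions and a 6-parameter affine). Non-affine
(deformable) fields, folding detection, inverse-consistent estimation,
DICOM ingestion and 95th-percentile Hausdorff are out of scope. The
unsupervised loss makes in-cohort evaluation legitimate (no labels are
consumed), but the small trained networks shown here are
demonstrations of the training mechanics, not pretrained models;
anyone registering real data should train on their own corpus at full
resolution or use the per-pair optimizer.
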