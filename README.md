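# mireg

Unsupervised affine co-registration of multimodal (CT/MR-like) brain
images in R.

Radiotherapy planning routinely fuses CT (geometry, electron density)
with MR (soft-tissue contrast) of the same patient. Because the two
modalities render the same anatomy through unrelated intensity maps,
alignment cannot be driven by intensity differences or correlation;
mutual information (MI) is the similarity of choice. `mireg` implements
a regularized spatial-transformer registration model for this setting,
for researchers who want a fully inspectable, dependency-light
implementation of every stage: no deep-learning framework is involved —
the network, its backpropagation, the differentiable resampler and the
soft-histogram MI loss are all plain, vectorized R.

## The model

A localization CNN `g_θ` maps the concatenated, z-scored pair `(F, M)`
to the six parameters `μ = (a11, a12, a21, a22, tx, ty)` of a 2D affine
transform `T_μ : M → F` in a single forward pass. An **affine-to-field
layer** expands `μ` into a dense displacement field

    u(x) = A (x − c) + c + t − x

over the pixel grid (linear in `μ`, hence trivially differentiable), so
that field-space regularizers — which cannot act on the six encrypted
parameters — apply to an affine transform; a differentiable bilinear
resampler then warps the moving image. Training needs no ground-truth
deformations: Adam minimizes

    L(θ) = −MI(F, T_μ(M)) + λ · R(u),    μ = g_θ(F, M)

where MI is a 64-bin soft (triangular Parzen) joint-histogram mutual
information, differentiable with respect to the warped intensities, and
`R` is bending energy (whose null space contains every affine field) or
mean squared displacement. The proposed architecture — five 3×3 stride-2
same-padded convolutions with filters [32, 32, 32, 32, 32], leaky-ReLU
slope 0.2, He-normal init, flatten (2048 features at a 256×256 input),
one dense layer to 6 — has 49,894 trainable parameters; the 16-filter
first-layer baseline has 44,982. The dense layer is zero-initialized so
an untrained network is exactly the identity warp.

The package also ships the four standard evaluation metrics (landmark
TRE, Dice, Jaccard, boundary Hausdorff, all spacing-aware), a
network-free per-pair MI optimizer used as an oracle and practical
fallback, and a seeded multimodal head-phantom generator with exact
ground truth (affine, 14 named landmarks, whole-region and tumor masks)
so the whole pipeline is testable without any data download.

## Worked example

```r
library(mireg)

# a 128x128 multimodal pair with a known misalignment
pair <- make_pair(phantom_spec(size = 128), affine_ranges(), seed = 7)
unclass(pair$truth$params)
#>        a11        a12        a21        a22         tx         ty
#>  1.0478744 -0.0535194  0.0177612  1.0472683 -6.7661915  3.3418358

# network-free MI maximization over the 6 parameters
rec <- optimize_single_pair(pair$fixed, pair$moving)
unclass(rec)
#>        a11        a12        a21        a22         tx         ty
#>  1.0425025 -0.0424091  0.0126731  1.0361888 -6.7560868  3.3210052

# evaluate pre/post registration
evaluate_pair(pair$fixed, pair$moving, rec,
              pair$truth$lm_fixed, pair$truth$lm_moving,
              pair$truth$mask_fixed, pair$truth$mask_moving,
              stratum = "tumor")
#> # A tibble: 1 x 9
#>   stratum tre_pre tre_post dice_pre dice_post jaccard_pre jaccard_post
#>   <chr>     <dbl>    <dbl>    <dbl>     <dbl>       <dbl>        <dbl>
#> 1 tumor      8.08    0.374    0.906     0.993       0.827        0.985
#> # i 2 more variables: hausdorff_pre <dbl>, hausdorff_post <dbl>
```

The recovered translation matches the truth to ~0.02 px; mean landmark
TRE drops from 8.1 mm to 0.37 mm and whole-region Dice rises from 0.91
to 0.99.

Training the network end-to-end works the same way at corpus scale:

```r
corpus <- lapply(1:12, function(i) {
  p <- make_pair(seed = i)
  list(fixed = p$fixed, moving = p$moving)
})
fit <- train(corpus, network_config(input_size = c(128, 128)),
             train_config(epochs = 50, seed = 1))
glance(fit)          # final loss, parameter count
register_pair(fit, corpus[[1]]$fixed, corpus[[1]]$moving)
```

A thin command-line interface (`inst/cli/mireg`, or `mireg_cli()` from
R) chains the stages: `simulate`, `train`, `register`, `evaluate`.

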