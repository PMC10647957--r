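#' Multimodal head-phantom specification
#'
#' Geometry and noise model of the synthetic brain-like phantom that
#' stands in for a private clinical CT/MR corpus: an elliptical skull
#' ring, brain interior, two ventricles, a midline falx stripe and an
#' optional tumor blob, all expressed as fractions of the image size so
#' one spec scales between the 128 px test resolution and the 256 px
#' clinical-mirroring resolution. A per-pair seed plus `jitter` perturbs
#' the geometry so corpus entries differ; the seed fully determines the
#' output.
#'
#' @param size image side in pixels (default 128; use 256 to mirror
#'   clinical slice size).
#' @param spacing mm per pixel (row, column).
#' @param skull_center skull center as (row, col) fractions of `size`.
#' @param skull_semi outer skull semi-axes as fractions of `size`.
#' @param skull_thickness skull-ring thickness as a fraction of `size`.
#' @param ventricle_offset lateral-ventricle center offset from the skull
#'   center as (row, col) fractions; the column offset is mirrored for the
#'   two ventricles.
#' @param ventricle_semi ventricle semi-axes (fractions); the ventricles
#'   are elongated and tilted (`ventricle_angle_deg`, mirrored) so small
#'   rotations of the head are identifiable from interior structure, not
#'   just the (rotationally affine-ambiguous) skull ellipse.
#' @param ventricle_angle_deg tilt of each ventricle's long axis.
#' @param falx_halfwidth falx stripe half-width in pixels.
#' @param falx_extent falx reach along the midline as (anterior,
#'   posterior) fractions of the inner skull semi-axis; the asymmetric
#'   default breaks front/back symmetry.
#' @param tumor logical: include a tumor blob.
#' @param tumor_center tumor center offset from skull center (fractions).
#' @param tumor_semi tumor semi-axes (fractions).
#' @param noise_ct,noise_mr additive Gaussian noise sd per modality (on
#'   the unit intensity scale).
#' @param blur_sigma partial-volume smoothing in pixels.
#' @param jitter relative geometry jitter applied per pair.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 128L, spacing = c(1, 1),
                         skull_center = c(0.5, 0.5),
                         skull_semi = c(0.40, 0.33),
                         skull_thickness = 0.045,
                         ventricle_offset = c(-0.05, 0.085),
                         ventricle_semi = c(0.16, 0.05),
                         ventricle_angle_deg = 18,
                         falx_halfwidth = 1.5,
                         falx_extent = c(0.55, 0.85),
                         tumor = TRUE,
                         tumor_center = c(0.10, 0.16),
                         tumor_semi = c(0.085, 0.065),
                         noise_ct = 0.02, noise_mr = 0.03,
                         blur_sigma = 1.0, jitter = 0.05) {
  size <- as.integer(size)
  if (size < 16L) stop_invalid("phantom size must be >= 16 px")
  s <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_geometry(s)
  s
}

validate_phantom_geometry <- function(spec) {
  reach <- max(spec$skull_center + spec$skull_semi,
               1 - spec$skull_center + spec$skull_semi)
  if (reach >= 0.995)
    stop_invalid("skull ellipse does not fit inside the frame")
  if (spec$tumor) {
    tr <- abs(spec$tumor_center) + spec$tumor_semi
    if (any(tr >= spec$skull_semi - spec$skull_thickness))
      stop_invalid("tumor geometry extends outside the brain")
  }
  invisible(spec)
}

# Concrete per-pair geometry: relative jitter on skull axes and tumor
# placement, drawn from the current RNG stream.
jitter_spec <- function(spec) {
  j <- spec$jitter
  if (j <= 0) return(spec)
  spec$skull_semi <- spec$skull_semi * (1 + runif(2, -j, j))
  spec$skull_center <- spec$skull_center + runif(2, -j / 4, j / 4)
  if (spec$tumor) {
    spec$tumor_center <- spec$tumor_center * (1 + runif(2, -2 * j, 2 * j))
    spec$tumor_semi <- spec$tumor_semi * (1 + runif(2, -j, j))
  }
  validate_phantom_geometry(spec)
  spec
}

LABELS <- c(background = 0L, skull = 1L, brain = 2L, ventricle = 3L,
            falx = 4L, tumor = 5L)

inside_ellipse <- function(r, c_, center, semi, angle_deg = 0) {
  if (angle_deg != 0) {
    th <- angle_deg * pi / 180
    dr <- r - center[1]; dc <- c_ - center[2]
    r_ <- cos(th) * dr + sin(th) * dc
    c_ <- -sin(th) * dr + cos(th) * dc
    return((r_ / semi[1])^2 + (c_ / semi[2])^2 <= 1)
  }
  ((r - center[1]) / semi[1])^2 + ((c_ - center[2]) / semi[2])^2 <= 1
}

#' Render the phantom anatomy as an integer label raster
#'
#' Labels: 0 background, 1 skull ring, 2 brain interior, 3 ventricles,
#' 4 falx stripe, 5 tumor (when present). Purely deterministic given the
#' spec (jitter is resolved upstream, in [make_pair()]).
#'
#' @param spec a [phantom_spec()].
#' @return integer matrix of labels, `size x size`.
#' @export
render_anatomy <- function(spec) {
  validate_phantom_geometry(spec)
  n <- spec$size
  g <- make_identity_grid(n, n)
  r <- g[, , 1]; c_ <- g[, , 2]
  ctr <- spec$skull_center * n
  outer_semi <- spec$skull_semi * n
  inner_semi <- (spec$skull_semi - spec$skull_thickness) * n
  lab <- matrix(LABELS[["background"]], n, n)
  lab[inside_ellipse(r, c_, ctr, outer_semi)] <- LABELS[["skull"]]
  brain <- inside_ellipse(r, c_, ctr, inner_semi)
  lab[brain] <- LABELS[["brain"]]
  for (sgn in c(-1, 1)) {
    vc <- ctr + c(spec$ventricle_offset[1], sgn * spec$ventricle_offset[2]) * n
    lab[inside_ellipse(r, c_, vc, spec$ventricle_semi * n,
                       sgn * spec$ventricle_angle_deg) & brain] <-
      LABELS[["ventricle"]]
  }
  falx_rows <- (r - ctr[1]) >= -spec$falx_extent[1] * inner_semi[1] &
    (r - ctr[1]) <= spec$falx_extent[2] * inner_semi[1]
  falx <- abs(c_ - ctr[2]) <= spec$falx_halfwidth & falx_rows & brain
  lab[falx & lab != LABELS[["ventricle"]]] <- LABELS[["falx"]]
  if (spec$tumor) {
    tc <- ctr + spec$tumor_center * n
    lab[inside_ellipse(r, c_, tc, spec$tumor_semi * n) & brain] <-
      LABELS[["tumor"]]
  }
  lab
}

# Label -> intensity lookup per modality. The two maps order the tissues
# differently (skull brightest on CT-like, ventricle/tumor brightest on
# MR-like), so the pixelwise intensity relation across modalities is far
# from affine and MI -- not correlation -- is the informative similarity.
MODALITY_LUT <- list(
  "ct-like" = c(0.00, 1.00, 0.35, 0.18, 0.62, 0.46),
  "mr-like" = c(0.00, 0.08, 0.55, 0.95, 0.25, 0.88))

#' Render a labeled anatomy through one modality's intensity map
#'
#' Applies the modality's label-to-intensity lookup, partial-volume
#' smoothing, and additive Gaussian noise.
#'
#' @param labels integer label raster from [render_anatomy()].
#' @param modality `"ct-like"` or `"mr-like"`.
#' @param noise_sd additive noise standard deviation.
#' @param seed optional seed for the noise draw.
#' @param blur_sigma smoothing in pixels.
#' @param spacing mm per pixel.
#' @return an [image_grid()].
#' @export
apply_modality <- function(labels, modality = c("ct-like", "mr-like"),
                           noise_sd = 0.02, seed = NULL, blur_sigma = 1.0,
                           spacing = c(1, 1)) {
  modality <- match.arg(modality)
  if (!is.null(seed)) set.seed(seed)
  lut <- MODALITY_LUT[[modality]]
  img <- matrix(lut[labels + 1L], nrow(labels), ncol(labels))
  img <- gaussian_blur(img, blur_sigma)
  if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
  image_grid(img, spacing)
}

#' Geometric landmark placement on the phantom
#'
#' The 9 skull/midline/center landmarks are computed analytically from the
#' resolved geometry (extremal points of the outer skull ellipse, inner
#' skull points, falx midpoint, image center) and, when the spec carries a
#' tumor, `tmr1..tmr4` at the tumor's extremal points plus `ctmr` at its
#' center.
#'
#' @param spec a resolved [phantom_spec()].
#' @param with_tumor request tumor landmarks (default: follow the spec).
#' @return a [landmark_set()] in mm.
#' @export
place_landmarks <- function(spec, with_tumor = spec$tumor) {
  if (with_tumor && !spec$tumor)
    stop_invalid("tumor landmarks requested but the spec has no tumor")
  n <- spec$size
  ctr <- spec$skull_center * n
  a <- spec$skull_semi * n
  ai <- (spec$skull_semi - spec$skull_thickness) * n
  pts <- rbind(
    up   = c(ctr[1] - a[1], ctr[2]),
    dp   = c(ctr[1] + a[1], ctr[2]),
    lp   = c(ctr[1], ctr[2] - a[2]),
    rp   = c(ctr[1], ctr[2] + a[2]),
    midd = c(ctr[1] + mean(c(-spec$falx_extent[1], spec$falx_extent[2])) *
               ai[1], ctr[2]),
    cntr = c((n - 1) / 2, (n - 1) / 2),
    B4   = c(ctr[1], ctr[2] + ai[2]),
    B9   = c(ctr[1], ctr[2] - ai[2]),
    B0   = c(ctr[1] - ai[1], ctr[2]))
  if (with_tumor) {
    tc <- ctr + spec$tumor_center * n
    ts <- spec$tumor_semi * n
    pts <- rbind(pts,
                 tmr1 = c(tc[1] - ts[1], tc[2]),
                 tmr2 = c(tc[1] + ts[1], tc[2]),
                 tmr3 = c(tc[1], tc[2] + ts[2]),
                 tmr4 = c(tc[1], tc[2] - ts[2]),
                 ctmr = tc)
  }
  landmark_set(tibble::tibble(name = rownames(pts),
                              x_mm = unname(pts[, 1]) * spec$spacing[1],
                              y_mm = unname(pts[, 2]) * spec$spacing[2]))
}

#' Misalignment draw bounds for the generator
#'
#' Defaults span clinically plausible slice misalignments: translation up
#' to 10 px per axis, rotation up to 15 degrees, isotropic scale in
#' 0.9--1.1, shear up to 0.05.
#'
#' @param translation max |translation| in pixels per axis.
#' @param rotation max |rotation| in degrees.
#' @param scale length-2 scale range.
#' @param shear max |shear|.
#' @return a list of class `affine_ranges`.
#' @export
affine_ranges <- function(translation = 10, rotation = 15,
                          scale = c(0.9, 1.1), shear = 0.05) {
  structure(list(translation = translation, rotation = rotation,
                 scale = scale, shear = shear), class = "affine_ranges")
}

draw_affine <- function(ranges) {
  affine_from_components(
    rotation_deg = runif(1, -ranges$rotation, ranges$rotation),
    scale = runif(1, ranges$scale[1], ranges$scale[2]),
    shear = runif(1, -ranges$shear, ranges$shear),
    translation = runif(2, -ranges$translation, ranges$translation))
}

warp_mask <- function(mask, params) {
  (warp_with_affine(mask * 1, params)$pixels > 0.5) * 1
}

#' Generate one multimodal phantom pair with known ground truth
#'
#' Renders one (jittered) anatomy through both modality maps, then warps
#' the MR-like image by the centered inverse of a randomly drawn affine so
#' that the resampling parameters that re-align moving onto fixed are
#' exactly the drawn truth. Landmarks and masks are carried in both
#' spaces; moving landmarks are by construction
#' `transform_landmarks(fixed landmarks, truth)`.
#'
#' @param spec a [phantom_spec()].
#' @param ranges an [affine_ranges()]; all-zero bounds give an identity
#'   truth.
#' @param seed integer seed determining jitter, noise and the affine draw.
#' @return a list of class `phantom_pair`: `fixed`, `moving`
#'   ([image_grid()]s) and `truth` (params, landmark sets and masks in
#'   both spaces), plus the resolved spec and stratum tag.
#' @export
make_pair <- function(spec = phantom_spec(), ranges = affine_ranges(),
                      seed = 1L) {
  set.seed(seed)
  rspec <- jitter_spec(spec)
  labels <- render_anatomy(rspec)
  fixed <- apply_modality(labels, "ct-like", rspec$noise_ct,
                          blur_sigma = rspec$blur_sigma,
                          spacing = rspec$spacing)
  mr <- apply_modality(labels, "mr-like", rspec$noise_mr,
                       blur_sigma = rspec$blur_sigma,
                       spacing = rspec$spacing)
  truth <- draw_affine(ranges)
  inv <- invert_affine(truth)
  n <- rspec$size
  moving <- resample(mr, affine_to_field(inv, n, n))
  lm_fixed <- place_landmarks(rspec)
  lm_moving <- transform_landmarks(lm_fixed, truth, rspec$spacing, c(n, n))
  whole_fixed <- (labels > 0) * 1
  structure(list(
    fixed = fixed, moving = moving,
    truth = list(
      params = truth,
      lm_fixed = lm_fixed, lm_moving = lm_moving,
      mask_fixed = segmentation_mask(whole_fixed, rspec$spacing),
      mask_moving = segmentation_mask(warp_mask(whole_fixed, inv),
                                      rspec$spacing),
      tumor_mask_fixed = if (rspec$tumor)
        segmentation_mask((labels == LABELS[["tumor"]]) * 1, rspec$spacing,
                          "tumor"),
      tumor_mask_moving = if (rspec$tumor)
        segmentation_mask(warp_mask((labels == LABELS[["tumor"]]) * 1, inv),
                          rspec$spacing, "tumor")),
    spec = rspec, seed = as.integer(seed),
    stratum = if (rspec$tumor) "tumor" else "healthy"),
    class = "phantom_pair")
}

#' Generate a seeded corpus of phantom pairs with a manifest
#'
#' Pairs are generated with per-pair seeds derived deterministically from
#' the master seed; a stated `tumor_fraction` of them carry a tumor
#' (count = `round(n * fraction)`). The manifest records each pair's seed,
#' stratum, train/validation/test split (proportions 60:20:30 by default,
#' assigned floor-first with the remainder going to the earliest splits)
#' and true parameters.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param tumor_fraction fraction of tumor cases.
#' @param spec,ranges templates passed to [make_pair()].
#' @param seed master seed; the entire corpus is a pure function of it.
#' @param split_prop length-3 proportions for train/val/test.
#' @return list of class `phantom_corpus`: `pairs` and `manifest`
#'   (tibble).
#' @export
make_corpus <- function(n_pairs, tumor_fraction = 0.5, spec = phantom_spec(),
                        ranges = affine_ranges(), seed = 1L,
                        split_prop = c(60, 20, 30) / 110) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) stop_invalid("n_pairs must be >= 1")
  set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1L, n_pairs)
  n_tumor <- round(n_pairs * tumor_fraction)
  tumor_flags <- rep(FALSE, n_pairs)
  if (n_tumor > 0) tumor_flags[sample.int(n_pairs, n_tumor)] <- TRUE
  split_prop <- split_prop / sum(split_prop)
  counts <- floor(n_pairs * split_prop)
  rem <- n_pairs - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  split <- rep(c("train", "val", "test"), counts)
  pairs <- vector("list", n_pairs)
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    sp <- spec; sp$tumor <- tumor_flags[i]
    pairs[[i]] <- make_pair(sp, ranges, seed = pair_seeds[i])
    tp <- unclass(pairs[[i]]$truth$params)
    rows[[i]] <- tibble::tibble(
      id = sprintf("pair%03d", i), seed = pair_seeds[i],
      stratum = pairs[[i]]$stratum, split = split[i],
      a11 = tp[["a11"]], a12 = tp[["a12"]], a21 = tp[["a21"]],
      a22 = tp[["a22"]], tx = tp[["tx"]], ty = tp[["ty"]])
  }
  structure(list(pairs = pairs, manifest = do.call(rbind, rows)),
            class = "phantom_corpus")
}
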