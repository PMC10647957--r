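test_that("anatomy rendering is deterministic and geometrically sane", {
  spec <- phantom_spec(size = 96, tumor = FALSE)
  lab <- render_anatomy(spec)
  expect_false(any(lab == 5))
  expect_identical(render_anatomy(spec), lab)
  # skull ring area vs the analytic ellipse-ring area
  ring <- sum(lab == 1)
  a <- spec$skull_semi * 96
  inner <- (spec$skull_semi - spec$skull_thickness) * 96
  analytic <- pi * (a[1] * a[2] - inner[1] * inner[2])
  expect_lt(abs(ring - analytic) / analytic, 0.1)
  expect_error(phantom_spec(skull_semi = c(0.6, 0.5)), "fit")
})

test_that("modality maps are label-constant, discordant, and MI-informative", {
  spec <- phantom_spec(size = 96)
  lab <- render_anatomy(spec)
  ct0 <- apply_modality(lab, "ct-like", noise_sd = 0, blur_sigma = 0)
  mr0 <- apply_modality(lab, "mr-like", noise_sd = 0, blur_sigma = 0)
  for (l in unique(as.vector(lab))) {
    expect_equal(length(unique(ct0$pixels[lab == l])), 1L)
    expect_equal(length(unique(mr0$pixels[lab == l])), 1L)
  }
  # the two maps order tissues differently
  expect_false(identical(order(unique(ct0$pixels)), order(unique(mr0$pixels))))
  # realistic rendering: linear regression across modalities leaves > 20%
  # of the variance unexplained
  ct <- apply_modality(lab, "ct-like", spec$noise_ct, seed = 1,
                       blur_sigma = spec$blur_sigma)
  mr <- apply_modality(lab, "mr-like", spec$noise_mr, seed = 2,
                       blur_sigma = spec$blur_sigma)
  r2 <- summary(lm(as.vector(mr$pixels) ~ as.vector(ct$pixels)))$r.squared
  expect_lt(r2, 0.8)
  # MI at alignment beats MI at a 10 px offset (hard-histogram oracle)
  off <- warp_with_affine(mr, affine_params(tx = 10))
  mi0 <- oracle_mi_bits(oracle_hard_joint(ct$pixels, mr$pixels, 16))
  mi10 <- oracle_mi_bits(oracle_hard_joint(ct$pixels, off$pixels, 16))
  expect_gt(mi0, mi10)
  expect_error(apply_modality(lab, "pet"), "arg")
})

test_that("landmarks sit at analytic anatomical positions", {
  spec <- phantom_spec(size = 128, skull_semi = c(0.35, 0.35), jitter = 0)
  lm <- place_landmarks(spec)
  expect_setequal(lm$name, c(mireg:::CORE_LANDMARKS, mireg:::TUMOR_LANDMARKS))
  pt <- function(n) unlist(lm[lm$name == n, c("x_mm", "y_mm")], use.names = FALSE)
  ctr <- spec$skull_center * 128
  # circular skull: the four extremal points are symmetric about the center
  expect_equal(pt("up") + pt("dp"), 2 * ctr)
  expect_equal(pt("lp") + pt("rp"), 2 * ctr)
  expect_equal(pt("cntr"), c(63.5, 63.5))
  expect_equal(pt("ctmr"), ctr + spec$tumor_center * 128, tolerance = 0.5)
  healthy <- phantom_spec(size = 128, tumor = FALSE)
  expect_equal(nrow(place_landmarks(healthy)), 9L)
  expect_error(place_landmarks(healthy, with_tumor = TRUE), "tumor")
})

test_that("pair generation carries exact ground truth in both spaces", {
  # identity ranges: moving landmarks equal fixed landmarks
  p0 <- aligned_phantom(size = 64, seed = 61)
  expect_equal(p0$truth$lm_moving$x_mm, p0$truth$lm_fixed$x_mm)
  expect_identical(unclass(p0$truth$params), unclass(affine_identity()))
  # translation-only draw: every landmark offset by the drawn translation
  pt <- make_pair(phantom_spec(size = 64),
                  affine_ranges(translation = 8, rotation = 0,
                                scale = c(1, 1), shear = 0), seed = 62)
  tp <- unclass(pt$truth$params)
  expect_equal(pt$truth$lm_moving$x_mm - pt$truth$lm_fixed$x_mm,
               rep(tp[["tx"]], nrow(pt$truth$lm_fixed)))
  expect_equal(pt$truth$lm_moving$y_mm - pt$truth$lm_fixed$y_mm,
               rep(tp[["ty"]], nrow(pt$truth$lm_fixed)))
  # moving landmarks are exactly the transformed fixed landmarks
  pg <- make_pair(seed = 63)
  expect_equal(pg$truth$lm_moving,
               transform_landmarks(pg$truth$lm_fixed, pg$truth$params,
                                   pg$spec$spacing,
                                   dim(pg$fixed$pixels)))
  # warping moving back with the truth recovers the fixed-space mask
  back <- (warp_with_affine(pg$truth$mask_moving$pixels,
                            pg$truth$params)$pixels > 0.5) * 1
  expect_gte(dice(back, pg$truth$mask_fixed$pixels), 0.98)
})

test_that("pre-registration TRE agrees with a Monte-Carlo draw oracle", {
  ranges <- affine_ranges()
  pairs <- lapply(1:20, function(i) make_pair(seed = 700 + i, ranges = ranges))
  observed <- mean(sapply(pairs, function(p)
    tre(p$truth$lm_moving, p$truth$lm_fixed)$mean))
  # oracle: draw many affines, apply them to a reference landmark set
  set.seed(99)
  lm <- place_landmarks(phantom_spec(size = 128, jitter = 0))
  draws <- replicate(400, {
    t <- mireg:::draw_affine(ranges)
    tre(transform_landmarks(lm, t, c(1, 1), c(128, 128)), lm)$mean
  })
  means20 <- replicate(300, mean(sample(draws, 20, TRUE)))
  expect_gt(observed, quantile(means20, 0.005))
  expect_lt(observed, quantile(means20, 0.995))
})

test_that("corpus generation is seeded, stratified and split as documented", {
  spec <- phantom_spec(size = 32)
  c1 <- make_corpus(10, 0.5, spec, seed = 77)
  expect_equal(sum(c1$manifest$stratum == "tumor"), 5L)
  c2 <- make_corpus(10, 0.5, spec, seed = 77)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$pairs[[3]]$fixed$pixels, c2$pairs[[3]]$fixed$pixels)
  # floor + remainder split policy
  expect_equal(as.vector(table(c1$manifest$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L))
  c3 <- make_corpus(11, 0, spec, seed = 78)
  expect_equal(sum(c3$manifest$split == "train"), 6L)
  expect_true(all(c3$manifest$stratum == "healthy"))
})

test_that("every generated pair poses a well-posed MI registration problem", {
  for (s in c(81, 82, 83)) {
    p <- make_pair(seed = s)
    f <- p$fixed$pixels
    aligned <- warp_with_affine(p$moving, p$truth$params)$pixels
    off <- warp_with_affine(p$moving,
                            compose_affine(affine_params(tx = 5),
                                           p$truth$params))$pixels
    mi_t <- oracle_mi_bits(oracle_hard_joint(f, aligned, 16))
    mi_o <- oracle_mi_bits(oracle_hard_joint(f, off, 16))
    expect_gt(mi_t, mi_o)
  }
})
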