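random_landmarks <- function(n_seed) {
  set.seed(n_seed)
  names <- c(mireg:::CORE_LANDMARKS, mireg:::TUMOR_LANDMARKS)[1:12]
  landmark_set(tibble::tibble(name = names,
                              x_mm = runif(12, 0, 100),
                              y_mm = runif(12, 0, 100)),
               require_core = FALSE)
}

test_that("landmark transforms follow the centered affine point map", {
  lm <- random_landmarks(1)
  same <- transform_landmarks(lm, affine_identity(), c(1, 1), c(128, 128))
  expect_equal(same$x_mm, lm$x_mm)
  shifted <- transform_landmarks(lm, affine_params(tx = 3, ty = 4),
                                 c(1, 1), c(128, 128))
  expect_equal(shifted$x_mm, lm$x_mm + 3)
  expect_equal(shifted$y_mm, lm$y_mm + 4)
  # 90 degree rotation: center point fixed, corner checked by matrix oracle
  r90 <- affine_from_components(rotation_deg = 90)
  ctr <- landmark_set(tibble::tibble(name = c("cntr", "up"),
                                     x_mm = c(63.5, 0), y_mm = c(63.5, 0)),
                      require_core = FALSE)
  out <- transform_landmarks(ctr, r90, c(1, 1), c(128, 128))
  expect_equal(c(out$x_mm[1], out$y_mm[1]), c(63.5, 63.5))
  oracle <- matrix(c(0, -1, 1, 0), 2, 2, byrow = TRUE) %*%
    (c(0, 0) - c(63.5, 63.5)) + c(63.5, 63.5)
  expect_equal(c(out$x_mm[2], out$y_mm[2]), as.numeric(oracle))
})

test_that("TRE is the per-name Euclidean distance in mm", {
  lm <- random_landmarks(2)
  expect_equal(tre(lm, lm)$mean, 0)
  one <- lm; one$x_mm[3] <- one$x_mm[3] + 3; one$y_mm[3] <- one$y_mm[3] + 4
  r <- tre(lm, one)
  expect_equal(r$per_landmark$tre_mm[3], 5)
  other <- random_landmarks(3)
  oracle <- mean(sapply(seq_len(12), function(i) {
    j <- which(other$name == lm$name[i])
    sqrt((lm$x_mm[i] - other$x_mm[j])^2 + (lm$y_mm[i] - other$y_mm[j])^2)
  }))
  expect_equal(tre(lm, other)$mean, oracle)
  expect_error(tre(lm, lm[-1, ]), "missing")
})

test_that("Dice and Jaccard honor their definitions and identity", {
  a <- matrix(0, 6, 6); a[2:3, 2:3] <- 1
  b <- matrix(0, 6, 6); b[4:5, 4:5] <- 1
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  half_a <- matrix(0, 6, 6); half_a[1, 1:2] <- 1
  half_b <- matrix(0, 6, 6); half_b[1, 2:3] <- 1
  expect_equal(dice(half_a, half_b), 0.5)
  expect_equal(jaccard(half_a, half_b), 1 / 3)
  expect_warning(d0 <- dice(matrix(0, 3, 3), matrix(0, 3, 3)), "empty")
  expect_equal(d0, 1)
  set.seed(19)
  for (i in 1:100) {
    ma <- matrix(rbinom(64, 1, 0.4), 8, 8)
    mb <- matrix(rbinom(64, 1, 0.4), 8, 8)
    if (sum(pmax(ma, mb)) == 0) next
    d <- dice(ma, mb)
    expect_equal(jaccard(ma, mb), d / (2 - d), tolerance = 1e-12)
    expect_equal(d, dice(mb, ma))
  }
})

test_that("Hausdorff equals the brute-force max-min oracle", {
  m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1
  expect_equal(hausdorff(m, m), 0)
  expect_equal(hausdorff_points(rbind(c(0, 0)), rbind(c(3, 0))), 3)
  set.seed(20)
  for (i in 1:10) {
    pa <- matrix(runif(2 * sample(5:50, 1), 0, 20), ncol = 2)
    pb <- matrix(runif(2 * sample(5:50, 1), 0, 20), ncol = 2)
    expect_equal(hausdorff_points(pa, pb), oracle_hausdorff(pa, pb),
                 tolerance = 1e-12)
  }
  # spacing scales distances: same masks, 0.5 mm pixels
  shifted <- matrix(0, 8, 8); shifted[3:5, 5:7] <- 1
  expect_equal(hausdorff(m, shifted, spacing = c(0.5, 0.5)),
               hausdorff(m, shifted, spacing = c(1, 1)) / 2)
  expect_error(hausdorff(m, matrix(0, 8, 8)), "non-empty")
})

test_that("overlap decays and Hausdorff grows under progressive translation", {
  m <- matrix(0, 32, 32); m[8:24, 10:22] <- 1
  dices <- numeric(6); hds <- numeric(6)
  for (k in 0:5) {
    shifted <- matrix(0, 32, 32)
    shifted[, (1 + k):32] <- m[, 1:(32 - k)]
    dices[k + 1] <- dice(m, shifted)
    hds[k + 1] <- hausdorff(m, shifted)
  }
  expect_true(all(diff(dices) <= 0))
  expect_true(all(diff(hds) >= 0))
})

test_that("evaluate_pair assembles consistent pre/post records", {
  pair <- make_pair(phantom_spec(size = 64),
                    affine_ranges(translation = 6, rotation = 8,
                                  scale = c(0.95, 1.05), shear = 0.02),
                    seed = 51)
  # identity registration: post equals pre
  rec_id <- evaluate_pair(pair$fixed, pair$moving, affine_identity(),
                          pair$truth$lm_fixed, pair$truth$lm_moving,
                          pair$truth$mask_fixed, pair$truth$mask_moving,
                          stratum = "tumor")
  expect_equal(rec_id$tre_post, rec_id$tre_pre)
  expect_equal(rec_id$dice_post, rec_id$dice_pre)
  # exact truth: near-perfect post metrics
  rec <- evaluate_pair(pair$fixed, pair$moving, pair$truth$params,
                       pair$truth$lm_fixed, pair$truth$lm_moving,
                       pair$truth$mask_fixed, pair$truth$mask_moving,
                       stratum = "tumor")
  expect_lt(rec$tre_post, 0.5)
  expect_gt(rec$dice_post, 0.97)
  expect_gt(rec$tre_pre, rec$tre_post)
  # perfectly aligned scenario: Dice 1, TRE 0, Hausdorff 0, Jaccard 1
  aligned <- aligned_phantom(size = 64, seed = 52)
  rec0 <- evaluate_pair(aligned$fixed, aligned$moving, affine_identity(),
                        aligned$truth$lm_fixed, aligned$truth$lm_moving,
                        aligned$truth$mask_fixed, aligned$truth$mask_moving,
                        stratum = "tumor")
  expect_equal(c(rec0$tre_post, rec0$hausdorff_post), c(0, 0))
  expect_equal(c(rec0$dice_post, rec0$jaccard_post), c(1, 1))
  summ <- summarize_evaluation(rbind(rec, rec0))
  expect_true(all(c("stratum", "metric", "mean", "sd") %in% names(summ)))
})
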