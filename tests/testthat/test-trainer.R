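test_that("field regularizers honor their closed forms and null spaces", {
  zero <- array(0, c(8, 8, 2))
  expect_equal(field_regularizer(zero, "l2-displacement"), 0)
  expect_equal(field_regularizer(zero, "bending-energy"), 0)
  const <- affine_to_field(affine_params(tx = 3), 8, 8)
  expect_equal(field_regularizer(const, "l2-displacement"), 9)
  expect_equal(field_regularizer(const, "bending-energy"), 0)
  # every affine-generated field lies in the bending-energy null space
  set.seed(12)
  for (i in 1:20) {
    p <- affine_params(1 + rnorm(1, 0, 0.2), rnorm(1, 0, 0.2),
                       rnorm(1, 0, 0.2), 1 + rnorm(1, 0, 0.2),
                       rnorm(1, 0, 5), rnorm(1, 0, 5))
    f <- affine_to_field(p, 12, 15)
    expect_lt(field_regularizer(f, "bending-energy"), 1e-10)
  }
  expect_error(field_regularizer(zero, "ridge"), "arg")
})

test_that("training starts at -MI of the unwarped pair and reduces the loss", {
  pair <- aligned_phantom(size = 32, seed = 41, tumor = FALSE)
  corpus <- list(list(fixed = pair$fixed, moving = pair$moving))
  cfg <- network_config(input_size = c(32, 32), conv_filters = c(8, 8))
  tcfg <- train_config(learning_rate = 1e-4, epochs = 2L, batch_size = 1L,
                       lambda = 0, seed = 3L, loss = mi_config(n_bins = 16))
  fit <- train(corpus, cfg, tcfg)
  # identity start: first-epoch loss equals -MI(F, M) under pooled stats
  f <- normalize(pair$fixed, fit$stats$fixed)
  m <- normalize(pair$moving, fit$stats$moving)
  expect_equal(fit$history$loss[1], mi_loss(f, m, tcfg$loss),
               tolerance = 1e-6)
  # from a misaligned start the loss decreases over a 100-step window
  moved <- warp_with_affine(pair$moving,
                            invert_affine(affine_params(tx = 4, ty = 2)))
  fit2 <- train(list(list(fixed = pair$fixed, moving = moved)), cfg,
                train_config(learning_rate = 2.5e-3, epochs = 100L,
                             batch_size = 1L, lambda = 0, seed = 3L,
                             loss = mi_config(n_bins = 16)))
  expect_lt(fit2$history$loss[100], fit2$history$loss[1])
  expect_error(train(list(), cfg, tcfg), "non-empty")
})

test_that("a small network trained on one translated pair recovers the shift", {
  base <- aligned_phantom(size = 64, seed = 43, tumor = FALSE)
  truth <- affine_params(tx = 5, ty = 3)
  moving <- warp_with_affine(base$moving, invert_affine(truth))
  corpus <- list(list(fixed = base$fixed, moving = moving))
  cfg <- network_config(input_size = c(64, 64), conv_filters = c(8, 8, 8))
  fit <- train(corpus, cfg,
               train_config(learning_rate = 2.5e-3, epochs = 300L,
                            batch_size = 1L, lambda = 0.01, seed = 5L,
                            loss = mi_config(n_bins = 32)))
  rec <- register_pair(fit, base$fixed, moving)$params
  expect_lt(max(abs(unclass(rec)[5:6] - c(5, 3))), 1)
})

test_that("a dominant regularizer pins the transform at the identity", {
  base <- aligned_phantom(size = 32, seed = 44, tumor = FALSE)
  moving <- warp_with_affine(base$moving,
                             invert_affine(affine_params(tx = 4, ty = -3)))
  corpus <- list(list(fixed = base$fixed, moving = moving))
  cfg <- network_config(input_size = c(32, 32), conv_filters = c(8, 8))
  fit <- train(corpus, cfg,
               train_config(learning_rate = 2e-3, epochs = 60L,
                            batch_size = 1L, lambda = 1e4,
                            regularizer = "l2-displacement", seed = 6L,
                            loss = mi_config(n_bins = 16)))
  reg <- register_pair(fit, base$fixed, moving)
  disp <- sqrt(mean(reg$field[, , 1]^2 + reg$field[, , 2]^2))
  expect_lt(disp, 0.5)
})

test_that("register_pair is the exact identity for a fresh network and is self-consistent", {
  pair <- aligned_phantom(size = 32, seed = 45)
  cfg <- network_config(input_size = c(32, 32), conv_filters = c(8, 8))
  net <- build_network(cfg, seed = 1)
  reg <- register_pair(net, pair$fixed, pair$moving)
  expect_identical(reg$warped$pixels, pair$moving$pixels)
  d <- dim(pair$fixed$pixels)
  expect_equal(unclass(reg$field),
               unclass(affine_to_field(reg$params, d[1], d[2])),
               ignore_attr = TRUE)
})

test_that("a network trained on a translation corpus generalizes to a held-out pair", {
  # 12 training pairs and one held-out pair, translation-only truths;
  # the network sees smoothed half-resolution inputs and its predicted
  # translations are rescaled to the native grid
  ds <- function(img) image_grid(mireg:::downsample2(img$pixels),
                                 img$spacing * 2)
  ranges <- affine_ranges(translation = 10, rotation = 0,
                          scale = c(1, 1), shear = 0)
  pairs <- lapply(1:13, function(i)
    make_pair(phantom_spec(tumor = FALSE), ranges, seed = 460 + i))
  corpus <- lapply(pairs[1:12], function(p)
    list(fixed = ds(p$fixed), moving = ds(p$moving)))
  cfg <- network_config(input_size = c(64, 64),
                        conv_filters = c(16, 16, 16, 16))
  fit <- train(corpus, cfg,
               train_config(learning_rate = 1e-3, epochs = 250L,
                            batch_size = 4L, lambda = 0.01, seed = 8L,
                            loss = mi_config(n_bins = 32)))
  held <- pairs[[13]]
  reg <- register_pair(fit, ds(held$fixed), ds(held$moving))
  rp <- unclass(reg$params)
  rp[5:6] <- rp[5:6] * 2
  params <- mireg:::as_affine_params(rp)
  pre <- tre(held$truth$lm_moving, held$truth$lm_fixed)$mean
  post <- tre(transform_landmarks(held$truth$lm_moving,
                                  invert_affine(params),
                                  held$fixed$spacing,
                                  dim(held$fixed$pixels)),
              held$truth$lm_fixed)$mean
  expect_lt(post, 0.2 * pre)
})

test_that("direct per-pair MI optimization recovers known transforms", {
  # already aligned: stays near the identity
  pair <- aligned_phantom(size = 64, seed = 47)
  rec <- optimize_single_pair(pair$fixed, pair$moving)
  expect_lt(max(abs(unclass(rec)[5:6])), 0.5)
  # pure translation (7, -4)
  t <- affine_params(tx = 7, ty = -4)
  moved <- warp_with_affine(pair$moving, invert_affine(t))
  rec_t <- optimize_single_pair(pair$fixed, moved)
  expect_lt(max(abs(unclass(rec_t)[5:6] - c(7, -4))), 1)
  # 10 degree rotation about the center
  r <- affine_from_components(rotation_deg = 10)
  rot <- warp_with_affine(pair$moving, invert_affine(r))
  rec_r <- optimize_single_pair(pair$fixed, rot)
  expect_lt(abs(affine_rotation_deg(rec_r) - 10), 1)
})
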