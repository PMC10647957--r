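#' Training configuration
#'
#' Defaults mirror the published recipe: Adam, learning rate `1e-4`,
#' 500 epochs, full images (no patches), no augmentation, batch size 4,
#' and a bending-energy field regularizer with weight `lambda = 0.01`
#' applied to the size-normalized displacement field. One integer seed
#' controls weight initialization and data order.
#'
#' @param learning_rate positive Adam step size.
#' @param epochs number of passes over the corpus (>= 1).
#' @param batch_size pairs per gradient step.
#' @param lambda regularizer weight (>= 0).
#' @param regularizer `"bending-energy"` or `"l2-displacement"`.
#' @param seed integer master seed.
#' @param loss an [mi_config()].
#' @return a list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 500L, batch_size = 4L,
                         lambda = 0.01, regularizer = c("bending-energy",
                                                        "l2-displacement"),
                         seed = 1L, loss = mi_config()) {
  regularizer <- match.arg(regularizer)
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop_invalid("learning_rate must be > 0")
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop_invalid("epochs must be >= 1")
  if (!is.finite(lambda) || lambda < 0) stop_invalid("lambda must be >= 0")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = as.integer(batch_size), lambda = lambda,
                 regularizer = regularizer, seed = as.integer(seed),
                 loss = loss),
            class = "train_config")
}

#' Field-space regularizers
#'
#' Penalties applied to the dense displacement field the Affine-to-Field
#' layer emits. `"l2-displacement"` is the mean squared displacement
#' magnitude (pixels^2); `"bending-energy"` is the mean squared second
#' finite difference (`u_rr^2 + 2 u_rc^2 + u_cc^2`, summed over both
#' components). Affine fields lie exactly in the null space of the bending
#' energy, so that penalty leaves the affine family untouched and
#' suppresses only non-affine pathologies of the decoding pathway; both
#' are zero for the identity field.
#'
#' @param field a `(H, W, 2)` displacement field.
#' @param kind regularizer tag.
#' @return non-negative scalar.
#' @examples
#' f <- affine_to_field(affine_params(tx = 3), 8, 8)
#' field_regularizer(f, "l2-displacement")   # 9
#' field_regularizer(f, "bending-energy")    # 0
#' @export
field_regularizer <- function(field, kind = c("bending-energy",
                                              "l2-displacement")) {
  kind <- match.arg(kind)
  validate_field(field)
  if (kind == "l2-displacement")
    return(mean(field[, , 1]^2 + field[, , 2]^2))
  h <- dim(field)[1]; w <- dim(field)[2]
  if (h < 3L || w < 3L) return(0)
  acc <- 0; n_terms <- 0
  for (comp in 1:2) {
    u <- field[, , comp]
    urr <- u[3:h, , drop = FALSE] - 2 * u[2:(h - 1), , drop = FALSE] +
      u[1:(h - 2), , drop = FALSE]
    ucc <- u[, 3:w, drop = FALSE] - 2 * u[, 2:(w - 1), drop = FALSE] +
      u[, 1:(w - 2), drop = FALSE]
    urc <- u[2:h, 2:w, drop = FALSE] - u[2:h, 1:(w - 1), drop = FALSE] -
      u[1:(h - 1), 2:w, drop = FALSE] + u[1:(h - 1), 1:(w - 1), drop = FALSE]
    acc <- acc + sum(urr^2) + sum(ucc^2) + 2 * sum(urc^2)
    n_terms <- n_terms + length(urr) + length(ucc) + 2 * length(urc)
  }
  acc / n_terms
}

# ---- Adam over nested weight lists ------------------------------------

tree_zeros <- function(x) {
  if (is.list(x)) lapply(x, tree_zeros) else x * 0
}

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_binary <- function(f, a, b) {
  if (is.list(a)) Map(function(x, y) tree_binary(f, x, y), a, b) else f(a, b)
}

adam_init <- function(weights) {
  list(m = tree_zeros(weights), v = tree_zeros(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_binary(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- tree_binary(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_binary(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     state$m, state$v)
  list(weights = tree_binary(`-`, weights, upd), state = state)
}

# Regularizer value and its gradient wrt the 6 affine params, computed on
# the size-normalized field (components divided by max(H, W)). Bending
# energy of an affine field is identically zero for every parameter value,
# so its gradient vanishes exactly and is not propagated.
regularizer_term <- function(field, basis, kind) {
  s <- max(dim(field)[1:2])
  if (kind == "bending-energy") {
    list(value = field_regularizer(field, kind) / s^2, grad = numeric(6))
  } else {
    f1 <- field[, , 1]; f2 <- field[, , 2]
    n <- length(f1)
    g <- vapply(1:6, function(k) {
      2 * sum(f1 * basis$dR[[k]] + f2 * basis$dC[[k]]) / (n * s^2)
    }, numeric(1))
    list(value = mean(f1^2 + f2^2) / s^2, grad = g)
  }
}

# Loss and d(loss)/d(params) for one normalized pair at given affine params.
pair_objective <- function(fixed_px, moving_px, params, basis, cfg_loss,
                           lambda, reg_kind) {
  d <- dim(fixed_px)
  field <- affine_to_field(params, d[1], d[2])
  rg <- resample_gradients(image_grid(moving_px), field)
  mi <- mi_loss_with_gradient(image_grid(fixed_px), rg$warped, cfg_loss)
  gW <- mi$grad_warped
  dR_img <- gW * rg$dR; dC_img <- gW * rg$dC
  g <- vapply(1:6, function(k) {
    sum(dR_img * basis$dR[[k]]) + sum(dC_img * basis$dC[[k]])
  }, numeric(1))
  loss <- mi$loss
  if (lambda > 0) {
    rt <- regularizer_term(field, basis, reg_kind)
    loss <- loss + lambda * rt$value
    g <- g + lambda * rt$grad
  }
  list(loss = loss, grad = g, warped = rg$warped)
}

pooled_stats <- function(imgs) {
  v <- unlist(lapply(imgs, function(im) as.numeric(im$pixels)))
  normalization_stats(mean(v), sd(v), "per-dataset")
}

#' Train the localization network without ground truth
#'
#' End-to-end unsupervised training: for every pair the network predicts 6
#' affine parameters, the Affine-to-Field layer expands them to a dense
#' field, the resampler warps the moving image, and Adam minimizes the
#' mean of `-MI(fixed, warped) + lambda * regularizer(field)` over the
#' corpus by back-propagation through all stages. Images are normalized
#' with dataset-level per-modality statistics (fixed images pooled
#' together, moving images pooled together).
#'
#' @param corpus non-empty list of pairs, each `list(fixed=, moving=)` of
#'   same-shape [image_grid()]s.
#' @param net_cfg a [network_config()] whose `input_size` matches the
#'   corpus.
#' @param cfg a [train_config()].
#' @param validation optional held-out corpus evaluated (forward only)
#'   each epoch.
#' @param verbose print per-epoch losses.
#' @return object of class `mireg_fit`: `net` (trained `network_params`),
#'   `history` (tibble: epoch, loss, val_loss, seconds) and the configs.
#' @export
train <- function(corpus, net_cfg, cfg = train_config(), validation = NULL,
                  verbose = FALSE) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop_invalid("corpus must be a non-empty list of fixed/moving pairs")
  shapes <- vapply(corpus, function(p)
    paste(dim(as_image_grid(p$fixed)$pixels)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_invalid("corpus images must all share one shape (got ",
                 paste(unique(shapes), collapse = ", "), ")")
  set.seed(cfg$seed)
  net <- build_network(net_cfg, seed = cfg$seed)
  sf <- pooled_stats(lapply(corpus, function(p) as_image_grid(p$fixed)))
  sm <- pooled_stats(lapply(corpus, function(p) as_image_grid(p$moving)))
  prep <- function(set) lapply(set, function(p) {
    f <- normalize(as_image_grid(p$fixed), sf)
    m <- normalize(as_image_grid(p$moving), sm)
    list(f = f$pixels, m = m$pixels)
  })
  data <- prep(corpus)
  val <- if (!is.null(validation)) prep(validation)
  d <- dim(data[[1]]$f)
  basis <- affine_field_basis(d[1], d[2])
  weights <- list(conv = lapply(net$conv, function(l) l[c("W", "b")]),
                  dense = net$dense[c("W", "b")])
  st <- adam_init(weights)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(length(data))
    ep_loss <- 0
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      gsum <- NULL
      for (i in batch) {
        px <- array(0, c(d[1], d[2], 2L))
        px[, , 1] <- data[[i]]$f; px[, , 2] <- data[[i]]$m
        fw <- network_forward(net, px, keep_cache = TRUE)
        obj <- pair_objective(data[[i]]$f, data[[i]]$m,
                              as_affine_params(fw$params), basis,
                              cfg$loss, cfg$lambda, cfg$regularizer)
        if (!is.finite(obj$loss))
          stop("training diverged: non-finite loss at epoch ", ep)
        g <- network_backward(net, fw$cache, obj$grad)
        gsum <- if (is.null(gsum)) g else tree_binary(`+`, gsum, g)
        ep_loss <- ep_loss + obj$loss
      }
      gmean <- tree_map(function(g) g / length(batch), gsum)
      res <- adam_step(weights, gmean, st, cfg$learning_rate)
      weights <- res$weights; st <- res$state
      for (l in seq_along(net$conv)) net$conv[[l]][c("W", "b")] <- weights$conv[[l]]
      net$dense[c("W", "b")] <- weights$dense
    }
    vl <- NA_real_
    if (!is.null(val)) {
      vl <- mean(vapply(val, function(p) {
        px <- array(0, c(d[1], d[2], 2L))
        px[, , 1] <- p$f; px[, , 2] <- p$m
        fw <- network_forward(net, px)
        pair_objective(p$f, p$m, as_affine_params(fw$params), basis,
                       cfg$loss, cfg$lambda, cfg$regularizer)$loss
      }, numeric(1)))
    }
    hist[[ep]] <- c(loss = ep_loss / length(data), val_loss = vl,
                    seconds = proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val %.4f", ep,
                      hist[[ep]][["loss"]], vl))
  }
  hm <- do.call(rbind, hist)
  history <- tibble::tibble(epoch = seq_len(cfg$epochs),
                            loss = hm[, "loss"], val_loss = hm[, "val_loss"],
                            seconds = hm[, "seconds"])
  class(history) <- c("train_history", class(history))
  structure(list(net = net, history = history, config = cfg,
                 net_config = net_cfg,
                 stats = list(fixed = sf, moving = sm)),
            class = "mireg_fit")
}

#' One-shot registration of a single pair
#'
#' A single forward pass: the network predicts the affine parameters, the
#' Affine-to-Field layer expands them, and the resampler warps the moving
#' image (in its original intensity units). With a freshly initialized
#' network this is exactly the identity warp.
#'
#' @param net a `network_params` object (or a `mireg_fit`, whose trained
#'   network and pooled normalization statistics are then used).
#' @param fixed,moving same-shape [image_grid()]s.
#' @return object of class `registration`: `warped`, `params`, `field`,
#'   plus the input pair.
#' @export
register_pair <- function(net, fixed, moving) {
  stats_f <- NULL; stats_m <- NULL
  if (inherits(net, "mireg_fit")) {
    stats_f <- net$stats$fixed; stats_m <- net$stats$moving
    net <- net$net
  }
  fixed <- as_image_grid(fixed); moving <- as_image_grid(moving)
  pair <- concatenate_pair(fixed, moving, stats_f, stats_m)
  params <- predict_affine(net, pair)
  d <- dim(fixed$pixels)
  field <- affine_to_field(params, d[1], d[2])
  structure(list(warped = resample(moving, field), params = params,
                 field = field, fixed = fixed, moving = moving),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  cat("<registration>\n  params: ")
  print(x$params)
  invisible(x)
}

#' Network-free MI maximization over the 6 affine parameters
#'
#' Gradient-based registration of one pair without any network: Adam
#' ascends the soft-histogram MI of `(fixed, warp(moving, mu))` over the 6
#' parameters from an identity start, on a 3-level coarse-to-fine pyramid
#' (blur + 2x downsampling, translations rescaled between levels) so the
#' capture range covers clinically plausible misalignments. Serves both as
#' a practical single-pair registrar and as the test oracle for the
#' loss/transform stack.
#'
#' @param fixed,moving same-shape [image_grid()]s.
#' @param cfg a [train_config()]; `epochs` is the iteration count per
#'   pyramid level and `learning_rate` the Adam step size at the finest
#'   level (coarser levels use twice the rate). The defaults here are
#'   tuned for direct optimization, not network training.
#' @param levels integer pyramid depth; by default chosen so the coarsest
#'   level is about 32 px across (3 levels at 128 px, 2 at 64 px).
#' @return the best-found [affine_params()], with the achieved loss in
#'   attribute `"loss"`.
#' @export
optimize_single_pair <- function(fixed, moving,
                                 cfg = train_config(learning_rate = 0.02,
                                                    epochs = 150L,
                                                    lambda = 0,
                                                    loss = mi_config(n_bins = 32)),
                                 levels = NULL) {
  fixed <- as_image_grid(fixed); moving <- as_image_grid(moving)
  if (!all(dim(fixed$pixels)[1:2] == dim(moving$pixels)[1:2]))
    stop_invalid("fixed and moving images must have the same shape")
  if (is.null(levels)) {
    levels <- max(1L, min(3L, floor(log2(min(dim(fixed$pixels)[1:2]) / 32)) + 1L))
  }
  fx <- normalize(fixed)$pixels
  mv <- normalize(moving)$pixels
  pyr <- vector("list", levels)
  pyr[[1]] <- list(f = fx, m = mv)
  if (levels > 1) for (l in 2:levels) {
    pyr[[l]] <- list(f = downsample2(gaussian_blur(pyr[[l - 1]]$f, 1)),
                     m = downsample2(gaussian_blur(pyr[[l - 1]]$m, 1)))
  }
  theta <- c(1, 0, 0, 1, 0, 0)
  for (l in rev(seq_len(levels))) {
    f <- pyr[[l]]$f; m <- pyr[[l]]$m
    d <- dim(f)
    # coarse levels have few pixels: halve the bin count per level so the
    # joint histogram stays adequately populated
    loss_l <- cfg$loss
    loss_l$n_bins <- max(8L, loss_l$n_bins %/% 2L^(l - 1L))
    basis <- affine_field_basis(d[1], d[2])
    st <- adam_init(theta)
    lr0 <- cfg$learning_rate * (if (l > 1) 2 else 1)
    best <- list(loss = Inf, theta = theta)
    for (it in seq_len(cfg$epochs)) {
      obj <- pair_objective(f, m, as_affine_params(theta), basis,
                            loss_l, cfg$lambda, cfg$regularizer)
      if (!is.finite(obj$loss))
        stop("single-pair optimization diverged at level ", l,
             " iteration ", it, ": loss = ", obj$loss,
             "; params = ", paste(signif(theta, 4), collapse = ", "))
      if (obj$loss < best$loss) best <- list(loss = obj$loss, theta = theta)
      # exponential decay to a tenth of the initial rate within the level:
      # large early steps cover the capture range, small late steps settle
      # the flat rotation/shear directions of the MI surface
      lr <- lr0 * 0.1^((it - 1) / max(cfg$epochs - 1, 1))
      res <- adam_step(theta, obj$grad, st, lr)
      theta <- res$weights; st <- res$state
    }
    theta <- best$theta
    if (l > 1) theta[5:6] <- theta[5:6] * 2  # translations to finer level
  }
  out <- as_affine_params(theta)
  attr(out, "loss") <- best$loss
  out
}
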