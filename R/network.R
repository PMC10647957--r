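#' Localization-network architecture configuration
#'
#' Describes the one-shot CNN that maps a 2-channel fixed+moving stack to
#' the 6 affine parameters: a stack of stride-2 same-padded square
#' convolutions with leaky-rectifier activations and He-normal
#' initialization, a flatten, and a single dense layer to `output_dim`.
#' The defaults are the proposed architecture (five 3x3 convs with
#' filters `[32,32,32,32,32]`, stride 2, slope 0.2, dense to 6), under
#' which a 256x256 input flattens to 2048 features and the network has
#' 49,894 trainable parameters; swapping the first filter count to 16
#' gives the 44,982-parameter baseline variant.
#'
#' @param input_size length-2 integer, spatial size (H, W) of the input.
#' @param conv_filters integer vector, output channels of each conv layer.
#' @param kernel_size odd integer, square kernel side (default 3).
#' @param stride integer stride shared by all conv layers (default 2).
#' @param leaky_slope negative-part slope of the leaky rectifier
#'   (default 0.2).
#' @param initializer weight initializer tag (only `"he-normal"`).
#' @param output_dim number of transform parameters emitted (default 6).
#' @param in_channels input channels (default 2: fixed + moving).
#' @return a list of class `network_config` with the resolved per-layer
#'   spatial sizes and flatten length.
#' @examples
#' cfg <- network_config()
#' cfg$flatten_length            # 2048
#' count_parameters(cfg)         # 49894
#' @export
network_config <- function(input_size = c(256L, 256L),
                           conv_filters = rep(32L, 5),
                           kernel_size = 3L, stride = 2L,
                           leaky_slope = 0.2, initializer = "he-normal",
                           output_dim = 6L, in_channels = 2L) {
  input_size <- as.integer(input_size)
  conv_filters <- as.integer(conv_filters)
  if (length(conv_filters) < 1L || any(conv_filters < 1L))
    stop_invalid("need at least one conv layer with positive filter count")
  if (stride < 1L) stop_invalid("stride must be >= 1")
  if (!identical(initializer, "he-normal"))
    stop_invalid("unsupported initializer: ", initializer)
  sizes <- vector("list", length(conv_filters) + 1L)
  sizes[[1]] <- input_size
  for (l in seq_along(conv_filters)) {
    sizes[[l + 1L]] <- as.integer(ceiling(sizes[[l]] / stride))
    if (any(sizes[[l + 1L]] < 1L))
      stop_invalid("spatial map collapses below 1x1 at conv layer ", l)
  }
  flat <- prod(sizes[[length(sizes)]]) * conv_filters[length(conv_filters)]
  structure(list(input_size = input_size, conv_filters = conv_filters,
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride), leaky_slope = leaky_slope,
                 initializer = initializer, output_dim = as.integer(output_dim),
                 in_channels = as.integer(in_channels),
                 spatial_sizes = sizes, flatten_length = as.integer(flat)),
            class = "network_config")
}

#' Trainable-parameter count of a network configuration
#'
#' Pure function of the architecture:
#' `sum over conv layers of (k^2 c_in c_out + c_out)` plus the dense
#' layer's `flatten x output_dim + output_dim`.
#'
#' @param config a [network_config()].
#' @return integer parameter count.
#' @export
count_parameters <- function(config) {
  k <- config$kernel_size
  cin <- c(config$in_channels, head(config$conv_filters, -1L))
  conv <- sum(k * k * cin * config$conv_filters + config$conv_filters)
  as.integer(conv + config$flatten_length * config$output_dim + config$output_dim)
}

#' Build (initialize) a localization network
#'
#' Conv kernels are He-normal (`sd = sqrt(2 / fan_in)`), conv biases zero.
#' The final dense layer is initialized to exactly zero so the untrained
#' network predicts a zero offset from the identity transform -- the
#' standard stabilization that makes the initial loss equal the similarity
#' of the unwarped pair and lets MI-driven training start from a sensible
#' operating point.
#'
#' @param config a [network_config()].
#' @param seed optional integer seed for the weight draw.
#' @return object of class `network_params`: per-layer weights plus the
#'   config and total parameter count.
#' @export
build_network <- function(config, seed = NULL) {
  if (!inherits(config, "network_config")) stop_invalid("need a network_config")
  if (!is.null(seed)) set.seed(seed)
  k <- config$kernel_size
  cin <- c(config$in_channels, head(config$conv_filters, -1L))
  conv <- vector("list", length(config$conv_filters))
  for (l in seq_along(conv)) {
    fan_in <- k * k * cin[l]
    conv[[l]] <- list(
      W = matrix(rnorm(fan_in * config$conv_filters[l], sd = sqrt(2 / fan_in)),
                 fan_in, config$conv_filters[l]),
      b = numeric(config$conv_filters[l]))
  }
  dense <- list(W = matrix(0, config$flatten_length, config$output_dim),
                b = numeric(config$output_dim))
  structure(list(config = config, conv = conv, dense = dense,
                 n_params = count_parameters(config)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> %d conv layer(s) [%s], flatten %d, dense -> %d; %s trainable parameters\n",
              length(x$conv), paste(x$config$conv_filters, collapse = ","),
              x$config$flatten_length, x$config$output_dim,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

#' Stack a fixed/moving pair into the network's 2-channel input
#'
#' Normalizes each image (per-image statistics unless pooled stats are
#' supplied) and concatenates them along a channel axis: channel 1 is the
#' fixed image, channel 2 the moving image.
#'
#' @param fixed,moving same-shape [image_grid()]s.
#' @param stats_fixed,stats_moving optional [normalization_stats()] for
#'   dataset-level (per-modality) normalization.
#' @return an [image_grid()] whose `pixels` is an `(H, W, 2)` array.
#' @export
concatenate_pair <- function(fixed, moving, stats_fixed = NULL,
                             stats_moving = NULL) {
  fixed <- as_image_grid(fixed); moving <- as_image_grid(moving)
  if (!all(dim(fixed$pixels)[1:2] == dim(moving$pixels)[1:2]))
    stop_invalid("fixed and moving images must have the same spatial shape")
  f <- normalize(fixed, stats_fixed)
  m <- normalize(moving, stats_moving)
  d <- dim(f$pixels)
  px <- array(0, c(d[1], d[2], 2L))
  px[, , 1] <- f$pixels
  px[, , 2] <- m$pixels
  image_grid(px, fixed$spacing)
}

# TF-style "same" padding amounts for one axis
same_pad <- function(n, k, s) {
  out <- ceiling(n / s)
  total <- max((out - 1L) * s + k - n, 0L)
  beg <- total %/% 2L
  c(beg = beg, end = total - beg, out = out)
}

# One conv layer forward: x (H,W,C) -> list(a = (oh,ow,F), cache)
conv_forward <- function(x, layer, k, stride, slope) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  pr <- same_pad(H, k, stride); pc <- same_pad(W, k, stride)
  oh <- pr[["out"]]; ow <- pc[["out"]]
  xp <- array(0, c(H + pr[["beg"]] + pr[["end"]], W + pc[["beg"]] + pc[["end"]], C))
  xp[pr[["beg"]] + seq_len(H), pc[["beg"]] + seq_len(W), ] <- x
  r0 <- (seq_len(oh) - 1L) * stride + 1L
  c0 <- (seq_len(ow) - 1L) * stride + 1L
  col <- matrix(0, oh * ow, k * k * C)
  blk <- 0L
  for (dc in seq_len(k)) for (dr in seq_len(k)) {
    sl <- xp[r0 + dr - 1L, c0 + dc - 1L, , drop = FALSE]
    col[, blk + seq_len(C)] <- matrix(sl, oh * ow, C)
    blk <- blk + C
  }
  Z <- col %*% layer$W
  Z <- Z + matrix(layer$b, nrow(Z), ncol(Z), byrow = TRUE)
  mask <- ifelse(Z > 0, 1, slope)
  A <- Z * mask
  list(a = array(A, c(oh, ow, ncol(Z))),
       cache = list(col = col, mask = mask, in_dim = d, pr = pr, pc = pc,
                    r0 = r0, c0 = c0, oh = oh, ow = ow))
}

# Backward through one conv layer. dA: (oh*ow, F) matrix. Returns
# list(dW, db, dx = (H,W,C)).
conv_backward <- function(layer, cache, dA, k, stride) {
  dZ <- dA * cache$mask
  dW <- crossprod(cache$col, dZ)
  db <- colSums(dZ)
  dcol <- dZ %*% t(layer$W)
  d <- cache$in_dim; C <- d[3]
  dxp <- array(0, c(d[1] + cache$pr[["beg"]] + cache$pr[["end"]],
                    d[2] + cache$pc[["beg"]] + cache$pc[["end"]], C))
  blk <- 0L
  for (dc in seq_len(k)) for (dr in seq_len(k)) {
    piece <- array(dcol[, blk + seq_len(C)], c(cache$oh, cache$ow, C))
    rows <- cache$r0 + dr - 1L; cols <- cache$c0 + dc - 1L
    dxp[rows, cols, ] <- dxp[rows, cols, ] + piece
    blk <- blk + C
  }
  dx <- dxp[cache$pr[["beg"]] + seq_len(d[1]),
            cache$pc[["beg"]] + seq_len(d[2]), , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

# Full forward pass. pair_px: (H, W, in_channels) array.
# Returns list(offset, params, cache) -- cache only when requested.
network_forward <- function(net, pair_px, keep_cache = FALSE) {
  cfg <- net$config
  d <- dim(pair_px)
  if (length(d) != 3L || !all(d[1:2] == cfg$input_size) || d[3] != cfg$in_channels)
    stop_invalid("input shape (", paste(d, collapse = "x"),
                 ") does not match network input (",
                 paste(c(cfg$input_size, cfg$in_channels), collapse = "x"), ")")
  x <- pair_px
  caches <- if (keep_cache) vector("list", length(net$conv)) else NULL
  for (l in seq_along(net$conv)) {
    cf <- conv_forward(x, net$conv[[l]], cfg$kernel_size, cfg$stride,
                       cfg$leaky_slope)
    x <- cf$a
    if (keep_cache) caches[[l]] <- cf$cache
  }
  z <- as.vector(x)
  offset <- drop(crossprod(net$dense$W, z)) + net$dense$b
  base <- c(1, 0, 0, 1, 0, 0)[seq_len(cfg$output_dim)]
  params <- base + offset
  out <- list(offset = offset, params = params)
  if (keep_cache) out$cache <- list(convs = caches, z = z, feat_dim = dim(x))
  out
}

# Backward pass from d(loss)/d(offset) (length output_dim). Returns
# gradient list shaped like the network's weights.
network_backward <- function(net, cache, doffset) {
  cfg <- net$config
  gd <- list(W = cache$z %o% doffset, b = doffset)
  dz <- drop(net$dense$W %*% doffset)
  dA <- array(dz, cache$feat_dim)
  gconv <- vector("list", length(net$conv))
  for (l in rev(seq_along(net$conv))) {
    dA_mat <- matrix(dA, prod(dim(dA)[1:2]), dim(dA)[3])
    cb <- conv_backward(net$conv[[l]], cache$convs[[l]], dA_mat,
                        cfg$kernel_size, cfg$stride)
    gconv[[l]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dx
  }
  list(conv = gconv, dense = gd)
}

#' Predict affine parameters for one image pair
#'
#' Single forward pass of the localization network. The dense output is
#' decoded as an offset from the identity transform, so a freshly built
#' network (zeroed final layer) returns exactly the identity parameters.
#'
#' @param net a [build_network()] result (possibly trained).
#' @param pair a 2-channel [image_grid()] from [concatenate_pair()], or a
#'   bare `(H, W, 2)` array.
#' @return an [affine_params()] object.
#' @export
predict_affine <- function(net, pair) {
  px <- if (inherits(pair, "image_grid")) pair$pixels else pair
  fw <- network_forward(net, px)
  if (any(!is.finite(fw$params))) stop_invalid("network emitted non-finite parameters")
  as_affine_params(fw$params)
}

#' Save / load a network checkpoint
#'
#' Weights go to `weights.rds` (R's native serialization) and the
#' architecture to a human-readable `config.json` sidecar so a checkpoint
#' is self-describing.
#'
#' @param net a `network_params` object.
#' @param dir checkpoint directory (created if missing).
#' @return `save_checkpoint()` the directory, invisibly;
#'   `load_checkpoint()` the restored `network_params`.
#' @export
save_checkpoint <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(net[c("conv", "dense", "n_params")], file.path(dir, "weights.rds"))
  cfg <- net$config
  jsonlite::write_json(
    list(input_size = cfg$input_size, conv_filters = cfg$conv_filters,
         kernel_size = cfg$kernel_size, stride = cfg$stride,
         leaky_slope = cfg$leaky_slope, initializer = cfg$initializer,
         output_dim = cfg$output_dim, in_channels = cfg$in_channels),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg_j <- jsonlite::read_json(file.path(dir, "config.json"),
                               simplifyVector = TRUE)
  cfg <- network_config(input_size = cfg_j$input_size,
                        conv_filters = cfg_j$conv_filters,
                        kernel_size = cfg_j$kernel_size,
                        stride = cfg_j$stride,
                        leaky_slope = cfg_j$leaky_slope,
                        initializer = cfg_j$initializer,
                        output_dim = cfg_j$output_dim,
                        in_channels = cfg_j$in_channels)
  w <- readRDS(file.path(dir, "weights.rds"))
  structure(list(config = cfg, conv = w$conv, dense = w$dense,
                 n_params = w$n_params),
            class = "network_params")
}
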