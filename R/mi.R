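#' Mutual-information loss configuration
#'
#' @param n_bins number of histogram bins per image (default 64).
#' @param bandwidth triangular Parzen kernel half-width in bin units
#'   (default 1, the linear B-spline whose per-pixel weights sum to 1).
#' @param base logarithm base for entropy/MI (default 2: bits).
#' @param normalized if `TRUE` use the normalized-MI variant
#'   `(H(F)+H(M))/H(F,M)` instead of plain MI.
#' @return a list of class `mi_config`.
#' @export
mi_config <- function(n_bins = 64L, bandwidth = 1, base = 2, normalized = FALSE) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop_invalid("n_bins must be >= 2")
  if (!is.finite(bandwidth) || bandwidth <= 0) stop_invalid("bandwidth must be > 0")
  if (!is.finite(base) || base <= 1) stop_invalid("log base must be > 1")
  structure(list(n_bins = n_bins, bandwidth = bandwidth, base = base,
                 normalized = isTRUE(normalized)), class = "mi_config")
}

# Soft bin weights of one intensity vector. Returns dense N x B weight
# matrix W (rows sum to 1) and, if gradients, dW = d(normalized weight)/dv.
# The bin coordinate is u = (v - lo)/(hi - lo) * B - 1/2, so bin centers
# sit at integers 0..B-1; the epsilon-widened range keeps extremal pixels
# strictly inside. The range is treated as a constant during
# differentiation.
bin_weights <- function(v, n_bins, bandwidth, gradients = FALSE,
                        range_lim = NULL) {
  v <- as.numeric(v)
  n <- length(v)
  if (is.null(range_lim)) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      # constant image: park all mass exactly on the first bin center
      lo <- lo - 0.5; hi <- lo + n_bins
    } else {
      pad <- 1e-6 * (hi - lo)
      lo <- lo - pad; hi <- hi + pad
    }
  } else {
    lo <- range_lim[1]; hi <- range_lim[2]
  }
  scale <- n_bins / (hi - lo)
  u <- pmin(pmax((v - lo) * scale - 0.5, -0.5 + 1e-9), n_bins - 0.5 - 1e-9)
  j0 <- floor(u)
  K <- as.integer(ceiling(bandwidth))
  offs <- seq(-K, K + 1L)         # covers all bins with |u - j| < bandwidth
  W <- matrix(0, n, n_bins)
  raw <- list(); js <- list()
  ssum <- numeric(n)
  for (i in seq_along(offs)) {
    j <- j0 + offs[i]
    w <- pmax(0, 1 - abs(u - j) / bandwidth)
    raw[[i]] <- w; js[[i]] <- j
    ssum <- ssum + w
  }
  idx_all <- seq_len(n)
  # pixels whose kernel support (bandwidth < 1) contains no bin center
  # collapse onto their nearest bin -- the exact hard-histogram limit
  empty <- ssum == 0
  ssafe <- ifelse(empty, 1, ssum)
  for (i in seq_along(offs)) {
    jc <- pmin(pmax(js[[i]], 0), n_bins - 1)  # clamp stray edge bins
    w <- raw[[i]] / ssafe
    keep <- w > 0
    if (any(keep)) {
      ii <- idx_all[keep]
      W[cbind(ii, jc[keep] + 1L)] <- W[cbind(ii, jc[keep] + 1L)] + w[keep]
    }
  }
  if (any(empty)) {
    jn <- pmin(pmax(round(u[empty]), 0), n_bins - 1)
    W[cbind(idx_all[empty], jn + 1L)] <- 1
  }
  out <- list(W = W, lo = lo, hi = hi, scale = scale)
  if (gradients) {
    dW <- matrix(0, n, n_bins)
    dsum <- numeric(n)
    draw <- list()
    for (i in seq_along(offs)) {
      d <- ifelse(raw[[i]] > 0, -sign(u - js[[i]]) / bandwidth, 0)
      draw[[i]] <- d
      dsum <- dsum + d
    }
    for (i in seq_along(offs)) {
      jc <- pmin(pmax(js[[i]], 0), n_bins - 1)
      # quotient rule for the per-pixel normalization; nearest-bin
      # fallback pixels are locally constant (zero derivative)
      dv <- (draw[[i]] - (raw[[i]] / ssafe) * dsum) / ssafe
      dv[empty] <- 0
      keep <- dv != 0
      if (any(keep)) {
        ii <- idx_all[keep]
        dW[cbind(ii, jc[keep] + 1L)] <- dW[cbind(ii, jc[keep] + 1L)] + dv[keep]
      }
    }
    out$dW <- dW * scale   # chain through u(v)
  }
  out
}

#' Soft (Parzen) joint intensity histogram
#'
#' The differentiable joint probability table underlying the MI loss: each
#' pixel pair spreads unit mass over neighboring bin pairs with triangular
#' kernel weights, making the table -- and hence MI -- differentiable with
#' respect to both images' intensities. Bin ranges are the per-image
#' min/max, epsilon-widened.
#'
#' @param fixed,warped same-shape [image_grid()]s (or matrices).
#' @param n_bins bins per axis (default 64).
#' @param bandwidth kernel half-width in bin units (default 1).
#' @return object of class `joint_histogram`: a list with `probs`
#'   (`n_bins x n_bins`, sums to 1; rows index fixed-image bins),
#'   `n_bins`, `bandwidth` and the bin `ranges` used.
#' @examples
#' a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
#' h <- soft_joint_histogram(a, b, n_bins = 8)
#' sum(h$probs)
#' @export
soft_joint_histogram <- function(fixed, warped, n_bins = 64L, bandwidth = 1) {
  fixed <- as_image_grid(fixed); warped <- as_image_grid(warped)
  if (!all(dim(fixed$pixels)[1:2] == dim(warped$pixels)[1:2]))
    stop_invalid("fixed and warped images must have the same shape")
  cfg <- mi_config(n_bins = n_bins, bandwidth = bandwidth)
  bf <- bin_weights(fixed$pixels, cfg$n_bins, cfg$bandwidth)
  bm <- bin_weights(warped$pixels, cfg$n_bins, cfg$bandwidth)
  P <- crossprod(bf$W, bm$W) / length(fixed$pixels)
  structure(list(probs = P, n_bins = cfg$n_bins, bandwidth = cfg$bandwidth,
                 ranges = list(fixed = c(bf$lo, bf$hi),
                               warped = c(bm$lo, bm$hi))),
            class = "joint_histogram")
}

validate_histogram <- function(hist) {
  if (!inherits(hist, "joint_histogram")) {
    if (is.matrix(hist)) {
      hist <- structure(list(probs = hist, n_bins = nrow(hist), bandwidth = NA),
                        class = "joint_histogram")
    } else stop_invalid("expected a joint_histogram or probability matrix")
  }
  P <- hist$probs
  if (any(P < -1e-12)) stop_invalid("joint histogram has negative entries")
  if (abs(sum(P) - 1) > 1e-6)
    stop_invalid("joint histogram is not normalized (sum = ", format(sum(P)), ")")
  hist
}

entropy_bits <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Mutual information of a joint histogram
#'
#' `MI = sum p(f,m) log[ p(f,m) / (p(f) p(m)) ]` with `0 log 0 = 0`,
#' reported in `base`-logarithm units (bits by default). Marginals are the
#' row/column sums of the joint table.
#'
#' @param hist a `joint_histogram` (or bare probability matrix summing
#'   to 1).
#' @param base logarithm base (default 2).
#' @return non-negative scalar MI.
#' @examples
#' mutual_information(diag(2) / 2)  # 1 bit
#' @export
mutual_information <- function(hist, base = 2) {
  hist <- validate_histogram(hist)
  P <- hist$probs
  p <- rowSums(P); q <- colSums(P)
  pos <- P > 0
  mi <- sum(P[pos] * log(P[pos] / (p[row(P)[pos]] * q[col(P)[pos]]))) / log(base)
  max(mi, 0)
}

#' Differentiable mutual-information loss
#'
#' The training objective: `-MI(fixed, warped)` computed through the soft
#' joint histogram, so minimizing the loss maximizes image similarity.
#' With `normalized = TRUE` in the config the loss is `-(H(F)+H(M))/H(F,M)`.
#'
#' @param fixed,warped same-shape images.
#' @param config an [mi_config()].
#' @return scalar loss (negative MI).
#' @export
mi_loss <- function(fixed, warped, config = mi_config()) {
  h <- soft_joint_histogram(fixed, warped, config$n_bins, config$bandwidth)
  if (config$normalized) {
    P <- h$probs
    hf <- entropy_bits(rowSums(P), config$base)
    hm <- entropy_bits(colSums(P), config$base)
    hj <- entropy_bits(P, config$base)
    -(hf + hm) / hj
  } else {
    -mutual_information(h, config$base)
  }
}

# Loss and its gradient with respect to each warped-image pixel.
# d(loss)/dm_k = -(1/N) a_k' G b'_k where a_k are the fixed-image bin
# weights, b'_k the derivative of the warped-image bin weights, and G the
# appropriate per-cell MI derivative (terms constant in total mass drop
# because per-pixel weights always sum to 1).
mi_loss_with_gradient <- function(fixed, warped, config = mi_config()) {
  fixed <- as_image_grid(fixed); warped <- as_image_grid(warped)
  if (!all(dim(fixed$pixels)[1:2] == dim(warped$pixels)[1:2]))
    stop_invalid("fixed and warped images must have the same shape")
  n <- length(fixed$pixels)
  bf <- bin_weights(fixed$pixels, config$n_bins, config$bandwidth)
  bm <- bin_weights(warped$pixels, config$n_bins, config$bandwidth,
                    gradients = TRUE)
  P <- crossprod(bf$W, bm$W) / n
  p <- rowSums(P); q <- colSums(P)
  ln_base <- log(config$base)
  if (config$normalized) {
    hf <- entropy_bits(p, config$base)
    hm <- entropy_bits(q, config$base)
    hj <- entropy_bits(P, config$base)
    dHm <- matrix(rep(ifelse(q > 0, -(log(q) + 1) / ln_base, 0),
                      each = config$n_bins), config$n_bins)
    dHj <- matrix(0, config$n_bins, config$n_bins)
    pos <- P > 0
    dHj[pos] <- -(log(P[pos]) + 1) / ln_base
    G <- (dHm * hj - (hf + hm) * dHj) / hj^2
    loss <- -(hf + hm) / hj
  } else {
    G <- matrix(0, config$n_bins, config$n_bins)
    pos <- P > 0
    G[pos] <- log(P[pos] / (p[row(P)[pos]] * q[col(P)[pos]])) / ln_base
    loss <- -sum(P[pos] * log(P[pos] / (p[row(P)[pos]] * q[col(P)[pos]]))) / ln_base
  }
  grad <- -rowSums((bf$W %*% G) * bm$dW) / n
  list(loss = loss,
       grad_warped = matrix(grad, nrow(fixed$pixels), ncol(fixed$pixels)))
}
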