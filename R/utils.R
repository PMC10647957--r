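#' @importFrom stats rnorm runif sd setNames coef lm var
#' @importFrom utils read.csv write.csv head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("mireg_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Separable Gaussian blur of a matrix
#'
#' Used by the phantom generator (partial-volume-like smoothing) and by the
#' coarse levels of the per-pair optimizer. Border handling is replicate
#' padding, kernel radius `ceiling(3*sigma)`.
#'
#' @param x numeric matrix.
#' @param sigma standard deviation of the Gaussian kernel in pixels;
#'   `sigma <= 0` returns `x` unchanged.
#' @return a matrix of the same dimension as `x`.
#' @keywords internal
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  conv1 <- function(m) {
    # convolve along rows (dim 1) with replicate padding
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(x))))
}

# 2x box downsampling (mean of 2x2 blocks); odd trailing row/col dropped
downsample2 <- function(x) {
  h <- (nrow(x) %/% 2L) * 2L
  w <- (ncol(x) %/% 2L) * 2L
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  (x[seq(1L, h, 2L), seq(1L, w, 2L)] + x[seq(2L, h, 2L), seq(1L, w, 2L)] +
    x[seq(1L, h, 2L), seq(2L, w, 2L)] + x[seq(2L, h, 2L), seq(2L, w, 2L)]) / 4
}
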