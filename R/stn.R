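#' Identity sampling grid
#'
#' The grid-generator half of the spatial transformer: per-pixel source
#' coordinates, initialized so pixel (i, j) samples exactly from (i, j) in
#' 0-based coordinates. Layout is `(H, W, 2)` with components ordered
#' (row, column).
#'
#' @param height,width image dimensions in pixels (>= 2... >= 1 for widths
#'   of degenerate test grids; both must be positive integers >= 1).
#' @return array of dim `(height, width, 2)`, class `sampling_grid`.
#' @examples
#' g <- make_identity_grid(3, 2)
#' g[2, 1, ]  # c(1, 0): 0-based (row, col)
#' @export
make_identity_grid <- function(height, width) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L)
    stop_invalid("grid dimensions must be positive")
  g <- array(0, c(height, width, 2L))
  g[, , 1] <- matrix(seq_len(height) - 1, height, width)
  g[, , 2] <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
  class(g) <- c("sampling_grid", class(g))
  g
}

#' Affine-to-Field layer: expand 6 affine parameters to a dense field
#'
#' The layer that "decrypts" the network's 6-vector into a per-pixel
#' displacement field so that field-space regularizers can be applied to an
#' affine transform. With `x` the (optionally centered) pixel coordinate,
#' the displacement at `x` is `A x_c + c0 + t - x` (centered mode) or
#' `A x + t - x` (origin mode). The output is linear in all 6 parameters,
#' hence trivially differentiable; [affine_field_basis()] returns the exact
#' Jacobian structure used during back-propagation.
#'
#' @param params an [affine_params()] object (or 6 numbers in serialization
#'   order).
#' @param height,width output field dimensions.
#' @param center if `TRUE` (default) the linear part acts about the
#'   geometric image center `((H-1)/2, (W-1)/2)`; otherwise about the
#'   origin.
#' @return array of dim `(height, width, 2)`, class `displacement_field`;
#'   component 1 is row displacement, component 2 column displacement,
#'   both in pixels.
#' @examples
#' f <- affine_to_field(affine_params(tx = 3), 4, 4)
#' range(f[, , 1])  # 3 3
#' @export
affine_to_field <- function(params, height, width, center = TRUE) {
  params <- as_affine_params(params)
  g <- make_identity_grid(height, width)
  r <- g[, , 1]; c_ <- g[, , 2]
  if (center) {
    c0 <- c((height - 1) / 2, (width - 1) / 2)
  } else {
    c0 <- c(0, 0)
  }
  xr <- r - c0[1]; xc <- c_ - c0[2]
  p <- unclass(params)
  f <- array(0, c(height, width, 2L))
  f[, , 1] <- p[["a11"]] * xr + p[["a12"]] * xc + c0[1] + p[["tx"]] - r
  f[, , 2] <- p[["a21"]] * xr + p[["a22"]] * xc + c0[2] + p[["ty"]] - c_
  structure(f, class = c("displacement_field", "array"),
            params = params, center = center)
}

# Per-pixel derivative of the sampled source coordinate wrt each of the 6
# parameters. Returns list(dR = H x W x 6, dC = H x W x 6) in the order
# (a11, a12, a21, a22, tx, ty). Shared by the resampler backward pass and
# the direct per-pair optimizer.
affine_field_basis <- function(height, width, center = TRUE) {
  g <- make_identity_grid(height, width)
  if (center) c0 <- c((height - 1) / 2, (width - 1) / 2) else c0 <- c(0, 0)
  xr <- g[, , 1] - c0[1]; xc <- g[, , 2] - c0[2]
  one <- matrix(1, height, width); zero <- matrix(0, height, width)
  list(dR = list(xr, xc, zero, zero, one, zero),
       dC = list(zero, zero, xr, xc, zero, one))
}

validate_field <- function(field, dims = NULL) {
  d <- dim(field)
  if (length(d) != 3L || d[3] != 2L)
    stop_invalid("displacement field must have shape (H, W, 2)")
  if (any(!is.finite(field)))
    stop_invalid("displacement field contains non-finite entries")
  if (!is.null(dims) && !all(d[1:2] == dims))
    stop_invalid("field shape (", d[1], "x", d[2],
                 ") does not match image shape (", dims[1], "x", dims[2], ")")
  invisible(field)
}

# Bilinear sampling core. Returns the interpolated values and, if
# gradients = TRUE, also the analytic d(value)/d(row-coordinate) and
# d(value)/d(col-coordinate). Out-of-bounds source positions take `fill`
# and have zero spatial gradient.
bilinear_sample <- function(px, R, C, fill = 0, gradients = FALSE) {
  h <- nrow(px); w <- ncol(px)
  r0 <- floor(R); c0 <- floor(C)
  fr <- R - r0; fc <- C - c0
  # value at integer offset (dr, dc) from (r0, c0), fill outside
  gather <- function(dr, dc) {
    ri <- r0 + dr; ci <- c0 + dc
    ok <- ri >= 0 & ri <= (h - 1) & ci >= 0 & ci <= (w - 1)
    v <- matrix(fill, nrow(R), ncol(R))
    idx <- which(ok)
    v[idx] <- px[cbind(ri[idx] + 1L, ci[idx] + 1L)]
    v
  }
  v00 <- gather(0, 0); v01 <- gather(0, 1)
  v10 <- gather(1, 0); v11 <- gather(1, 1)
  top <- v00 * (1 - fc) + v01 * fc
  bot <- v10 * (1 - fc) + v11 * fc
  out <- list(value = top * (1 - fr) + bot * fr)
  if (gradients) {
    out$dR <- bot - top
    out$dC <- (v01 - v00) * (1 - fr) + (v11 - v10) * fr
  }
  out
}

#' Differentiable bilinear resampler
#'
#' Warps the moving image with a dense displacement field (backward
#' warping): `output(x) = moving(x + field(x))`, bilinearly interpolated.
#' Source positions falling outside the image take the constant `fill`
#' value. The operation is linear in the image intensities and piecewise
#' differentiable in the field; [resample_gradients()] exposes the analytic
#' spatial gradients the training loop chains through.
#'
#' @param moving an [image_grid()] (or matrix).
#' @param field a `(H, W, 2)` displacement field matching the image shape.
#' @param fill intensity used for out-of-bounds samples (default 0).
#' @return the warped [image_grid()].
#' @examples
#' img <- image_grid(matrix(1:16, 4, 4) * 1.0)
#' z <- array(0, c(4, 4, 2))
#' identical(resample(img, z)$pixels, img$pixels)
#' @export
resample <- function(moving, field, fill = 0) {
  moving <- as_image_grid(moving)
  validate_field(field, dim(moving$pixels)[1:2])
  g <- make_identity_grid(nrow(moving$pixels), ncol(moving$pixels))
  R <- g[, , 1] + field[, , 1]
  C <- g[, , 2] + field[, , 2]
  image_grid(bilinear_sample(moving$pixels, R, C, fill)$value, moving$spacing)
}

#' @rdname resample
#' @description `resample_gradients()` additionally returns
#'   `dR`/`dC`, the per-pixel derivative of the warped intensity with
#'   respect to the row/column displacement component at that pixel.
#' @export
resample_gradients <- function(moving, field, fill = 0) {
  moving <- as_image_grid(moving)
  validate_field(field, dim(moving$pixels)[1:2])
  g <- make_identity_grid(nrow(moving$pixels), ncol(moving$pixels))
  R <- g[, , 1] + field[, , 1]
  C <- g[, , 2] + field[, , 2]
  bs <- bilinear_sample(moving$pixels, R, C, fill, gradients = TRUE)
  list(warped = image_grid(bs$value, moving$spacing), dR = bs$dR, dC = bs$dC)
}

#' Warp an image with a 6-parameter affine
#'
#' Exact composition `resample(moving, affine_to_field(params, ...))`; the
#' direct-affine path of the transformer.
#'
#' @inheritParams resample
#' @inheritParams affine_to_field
#' @return the warped [image_grid()].
#' @export
warp_with_affine <- function(moving, params, center = TRUE, fill = 0) {
  moving <- as_image_grid(moving)
  d <- dim(moving$pixels)
  resample(moving, affine_to_field(params, d[1], d[2], center), fill)
}

# d(warped pixel)/d(param k), k = 1..6: chains the bilinear spatial
# gradient with the affine field basis. Returns list(warped, jac = list of
# six H x W matrices).
warp_affine_jacobian <- function(moving, params, center = TRUE, fill = 0) {
  moving <- as_image_grid(moving)
  d <- dim(moving$pixels)
  field <- affine_to_field(params, d[1], d[2], center)
  rg <- resample_gradients(moving, field, fill)
  basis <- affine_field_basis(d[1], d[2], center)
  jac <- lapply(1:6, function(k) rg$dR * basis$dR[[k]] + rg$dC * basis$dC[[k]])
  list(warped = rg$warped, jac = jac, dR = rg$dR, dC = rg$dC)
}
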