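#' Six-parameter 2D affine transform
#'
#' The parameter vector the localization network emits: a 2x2 linear map
#' `A = [a11 a12; a21 a22]` (dimensionless) plus a translation `(tx, ty)`
#' in pixels. The map acts on 0-based (row, column) pixel coordinates
#' `p = (r, c)`:
#' \deqn{p' = A (p - c_0) + c_0 + t}
#' where `c_0` is the geometric image center when applied in centered mode
#' (the default everywhere in the package) or the origin otherwise. `tx`
#' translates along the row axis, `ty` along the column axis. The identity
#' is `(1, 0, 0, 1, 0, 0)`; serialization order is always
#' `(a11, a12, a21, a22, tx, ty)`.
#'
#' @param a11,a12,a21,a22 linear-map entries.
#' @param tx,ty translation in pixels along (row, column).
#' @return an object of class `affine_params` (named numeric of length 6).
#' @examples
#' affine_identity()
#' affine_params(tx = 3, ty = -1)   # pure translation
#' @export
affine_params <- function(a11 = 1, a12 = 0, a21 = 0, a22 = 1, tx = 0, ty = 0) {
  v <- c(a11 = unname(a11), a12 = unname(a12), a21 = unname(a21),
         a22 = unname(a22), tx = unname(tx), ty = unname(ty))
  if (length(v) != 6L || any(!is.finite(v)))
    stop_invalid("affine parameters must be 6 finite scalars")
  det <- v[["a11"]] * v[["a22"]] - v[["a12"]] * v[["a21"]]
  if (!is.finite(det) || abs(det) < .Machine$double.eps)
    stop_invalid("affine linear part is singular (det = ", format(det), ")")
  structure(v, class = "affine_params")
}

#' @rdname affine_params
#' @export
affine_identity <- function() affine_params()

#' @export
print.affine_params <- function(x, ...) {
  cat("<affine_params>  A = [", sprintf("%.5g", x[1:2]), ";",
      sprintf("%.5g", x[3:4]), "]  t = (",
      sprintf("%.5g", x[5]), ",", sprintf("%.5g", x[6]), ") px\n")
  invisible(x)
}

as_affine_params <- function(x) {
  if (inherits(x, "affine_params")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L) stop_invalid("expected 6 affine parameters")
  affine_params(x[1], x[2], x[3], x[4], x[5], x[6])
}

affine_A <- function(p) matrix(unclass(p)[1:4], 2, 2, byrow = TRUE)
affine_t <- function(p) unclass(p)[5:6]

#' Compose affine transforms out of interpretable motion components
#'
#' Builds `A = R(theta) %*% diag(scale) %*% Shear(shear)` with the rotation
#' acting in the (row, column) plane. Positive angles rotate the row axis
#' toward the column axis.
#'
#' @param rotation_deg rotation angle in degrees.
#' @param scale length-1 or length-2 scale factor(s).
#' @param shear off-diagonal shear coefficient.
#' @param translation length-2 translation in pixels (row, column).
#' @return an [affine_params()] object.
#' @export
affine_from_components <- function(rotation_deg = 0, scale = 1, shear = 0,
                                   translation = c(0, 0)) {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  s <- rep_len(scale, 2L)
  Sh <- matrix(c(1, shear, 0, 1), 2, 2, byrow = TRUE)
  A <- R %*% diag(s) %*% Sh
  affine_params(A[1, 1], A[1, 2], A[2, 1], A[2, 2], translation[1], translation[2])
}

#' Invert an affine transform (centered convention)
#'
#' For `p' = A(p - c0) + c0 + t` the inverse in the same convention is
#' `A' = A^-1`, `t' = -A^-1 t`; this holds for any center `c0`, so the
#' inverse is valid in both centered and origin modes.
#'
#' @param params an [affine_params()] object.
#' @return the inverse [affine_params()].
#' @export
invert_affine <- function(params) {
  params <- as_affine_params(params)
  Ai <- solve(affine_A(params))
  ti <- -Ai %*% affine_t(params)
  affine_params(Ai[1, 1], Ai[1, 2], Ai[2, 1], Ai[2, 2], ti[1], ti[2])
}

#' Compose two affine transforms
#'
#' Returns the transform equivalent to applying `q` first and then `p`
#' (both in the same centered convention): `A = A_p A_q`,
#' `t = A_p t_q + t_p`.
#'
#' @param p,q [affine_params()] objects.
#' @return the composed [affine_params()].
#' @export
compose_affine <- function(p, q) {
  p <- as_affine_params(p); q <- as_affine_params(q)
  A <- affine_A(p) %*% affine_A(q)
  t <- affine_A(p) %*% affine_t(q) + affine_t(p)
  affine_params(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t[1], t[2])
}

#' Rotation angle of the linear part
#'
#' Extracts the rotation component of `A` by polar decomposition
#' (`A = R P` with `R` the closest rotation, via SVD), in degrees. Used to
#' compare a recovered transform against a ground-truth rotation when scale
#' and shear are also present.
#'
#' @param params an [affine_params()] object.
#' @return rotation angle in degrees, in (-180, 180].
#' @export
affine_rotation_deg <- function(params) {
  params <- as_affine_params(params)
  sv <- svd(affine_A(params))
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) { # reflection: flip the smallest singular direction
    sv$v[, 2] <- -sv$v[, 2]
    R <- sv$u %*% t(sv$v)
  }
  atan2(R[2, 1], R[1, 1]) * 180 / pi
}
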