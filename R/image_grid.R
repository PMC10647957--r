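#' Image raster with physical spacing
#'
#' The unit every transform in the package acts on: a 2D matrix of
#' intensities (arbitrary units) plus the physical size of a pixel along
#' each axis. Coordinates are 0-based and pixel-centered; axis 1 is the
#' matrix row axis, axis 2 the column axis, and all point/field components
#' are ordered (row, column) throughout the package.
#'
#' @param pixels numeric matrix (2D) of intensities, or a 3D array for a
#'   multi-channel stack (e.g. the concatenated fixed+moving input).
#' @param spacing length-2 positive numeric, physical size of one pixel in
#'   mm along (row, column).
#' @return an object of class `image_grid`.
#' @examples
#' img <- image_grid(matrix(runif(64), 8, 8), spacing = c(1, 1))
#' dim(img$pixels)
#' @export
image_grid <- function(pixels, spacing = c(1, 1)) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stop_invalid("`pixels` must be a numeric matrix or 3D array")
  if (any(dim(pixels)[1:2] < 2L))
    stop_invalid("image dimensions must all be >= 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_invalid("`spacing` must be two strictly positive finite numbers")
  structure(list(pixels = pixels, spacing = spacing), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<image_grid> %d x %d px, %d channel(s), spacing %.3g x %.3g mm/px\n",
              d[1], d[2], ch, x$spacing[1], x$spacing[2]))
  rng <- range(x$pixels)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

as_image_grid <- function(x, spacing = c(1, 1)) {
  if (inherits(x, "image_grid")) x else image_grid(x, spacing)
}

#' Intensity normalization statistics
#'
#' Mean/standard-deviation pair used to standardize intensities before they
#' enter the network or the mutual-information loss. The `scope` tag records
#' whether the statistics came from a single image or were pooled over a
#' modality's whole corpus (the latter is the training-time default, the
#' former the single-pair inference default).
#'
#' @param mean,std numeric scalars; `std` must be strictly positive.
#' @param scope `"per-image"` or `"per-dataset"`.
#' @return an object of class `normalization_stats`.
#' @export
normalization_stats <- function(mean, std, scope = c("per-image", "per-dataset")) {
  scope <- match.arg(scope)
  if (!is.finite(mean) || !is.finite(std))
    stop_invalid("normalization statistics must be finite")
  if (std <= 0)
    stop_invalid("normalization std must be strictly positive (got ", std, ")")
  structure(list(mean = as.numeric(mean), std = as.numeric(std), scope = scope),
            class = "normalization_stats")
}

#' Standardize image intensities
#'
#' Subtracts the mean and divides by the standard deviation of the pixel
#' intensities. With `stats = NULL` the statistics are computed from the
#' image itself (per-image scope); pass pooled [normalization_stats()] to
#' standardize a whole corpus consistently per modality.
#'
#' @param image an [image_grid()] (or bare matrix).
#' @param stats optional [normalization_stats()].
#' @return the normalized [image_grid()].
#' @examples
#' img <- image_grid(matrix(rnorm(100, 50, 5), 10, 10))
#' z <- normalize(img)
#' c(mean(z$pixels), sd(z$pixels))  # ~0, ~1
#' @export
normalize <- function(image, stats = NULL) {
  image <- as_image_grid(image)
  if (is.null(stats)) {
    m <- mean(image$pixels)
    s <- sqrt(mean((image$pixels - m)^2))
    if (s <= 0)
      stop_invalid("cannot self-normalize a constant image (std = 0)")
    stats <- normalization_stats(m, s, "per-image")
  }
  if (!inherits(stats, "normalization_stats"))
    stop_invalid("`stats` must be a normalization_stats object")
  image_grid((image$pixels - stats$mean) / stats$std, image$spacing)
}
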