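CORE_LANDMARKS <- c("up", "dp", "lp", "rp", "midd", "cntr", "B4", "B9", "B0")
TUMOR_LANDMARKS <- c("tmr1", "tmr2", "tmr3", "tmr4", "ctmr")

#' Named anatomical landmark set
#'
#' Landmarks in physical (mm) coordinates: `x_mm` along the row axis,
#' `y_mm` along the column axis (pixel index times spacing). The canonical
#' schema has 9 skull/midline/center names always present
#' (`up, dp, lp, rp, midd, cntr, B4, B9, B0`) and 5 tumor names present
#' only for tumor cases (`tmr1..tmr4` at the tumor's extremal points,
#' `ctmr` at its center).
#'
#' @param df data frame with columns `name`, `x_mm`, `y_mm`.
#' @param require_core error if any of the 9 core names is missing.
#' @return a tibble of class `landmark_set`.
#' @export
landmark_set <- function(df, require_core = TRUE) {
  df <- tibble::as_tibble(df)
  if (!all(c("name", "x_mm", "y_mm") %in% names(df)))
    stop_invalid("landmarks need columns name, x_mm, y_mm")
  df$name <- as.character(df$name)
  if (anyDuplicated(df$name))
    stop_invalid("duplicate landmark names: ",
                 paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  unknown <- setdiff(df$name, c(CORE_LANDMARKS, TUMOR_LANDMARKS))
  if (length(unknown))
    stop_invalid("unknown landmark names: ", paste(unknown, collapse = ", "))
  if (require_core) {
    missing <- setdiff(CORE_LANDMARKS, df$name)
    if (length(missing))
      stop_invalid("missing required landmarks: ",
                   paste(missing, collapse = ", "))
  }
  if (any(!is.finite(df$x_mm)) || any(!is.finite(df$y_mm)))
    stop_invalid("landmark coordinates must be finite")
  class(df) <- c("landmark_set", class(df))
  df
}

has_tumor_landmarks <- function(lm) any(TUMOR_LANDMARKS %in% lm$name)

#' Map landmarks through an affine transform
#'
#' Applies the same centered affine point map the generator uses to place
#' moving-space landmarks: mm coordinates are converted to pixels, mapped
#' by `p' = A(p - c0) + c0 + t`, and converted back to mm. Note the
#' direction: the resampler is a backward warp, so mapping landmarks from
#' the moving image into the fixed (warped) image uses the *inverse* of
#' the recovered resampling parameters ([invert_affine()]); [evaluate_pair()]
#' does this for you.
#'
#' @param lm a [landmark_set()].
#' @param params an [affine_params()] object.
#' @param spacing mm per pixel along (row, column).
#' @param size image size in pixels (row, column); needed for the center.
#' @param center apply the linear part about the image center (default).
#' @return the transformed [landmark_set()].
#' @export
transform_landmarks <- function(lm, params, spacing = c(1, 1), size,
                                center = TRUE) {
  params <- as_affine_params(params)
  if (center && missing(size))
    stop_invalid("`size` is required for the centered convention")
  px <- cbind(lm$x_mm / spacing[1], lm$y_mm / spacing[2])
  c0 <- if (center) c((size[1] - 1) / 2, (size[2] - 1) / 2) else c(0, 0)
  A <- affine_A(params); t <- affine_t(params)
  mapped <- sweep(sweep(px, 2, c0) %*% t(A), 2, c0 + t, `+`)
  out <- lm
  out$x_mm <- mapped[, 1] * spacing[1]
  out$y_mm <- mapped[, 2] * spacing[2]
  out
}

#' Target registration error between two landmark sets
#'
#' Per-landmark Euclidean distance in mm between identically named points,
#' plus their mean. Lower is better; a perfectly recovered transform gives
#' zero everywhere.
#'
#' @param lm_a,lm_b [landmark_set()]s sharing the same names.
#' @return a list of class `tre`: `per_landmark` (tibble name/tre_mm) and
#'   `mean` (scalar mm).
#' @examples
#' a <- landmark_set(data.frame(name = "cntr", x_mm = 0, y_mm = 0),
#'                   require_core = FALSE)
#' b <- landmark_set(data.frame(name = "cntr", x_mm = 3, y_mm = 4),
#'                   require_core = FALSE)
#' tre(a, b)$mean  # 5
#' @export
tre <- function(lm_a, lm_b) {
  miss_b <- setdiff(lm_a$name, lm_b$name)
  miss_a <- setdiff(lm_b$name, lm_a$name)
  if (length(miss_a) || length(miss_b))
    stop_invalid("landmark names do not match; missing: ",
                 paste(unique(c(miss_a, miss_b)), collapse = ", "))
  b <- lm_b[match(lm_a$name, lm_b$name), ]
  d <- sqrt((lm_a$x_mm - b$x_mm)^2 + (lm_a$y_mm - b$y_mm)^2)
  structure(list(per_landmark = tibble::tibble(name = lm_a$name, tre_mm = d),
                 mean = mean(d)),
            class = "tre")
}

#' @export
print.tre <- function(x, ...) {
  cat(sprintf("<tre> mean %.3f mm over %d landmarks\n", x$mean,
              nrow(x$per_landmark)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param pixels matrix of 0/1 (logicals and 0/1 numerics accepted).
#' @param spacing mm per pixel along (row, column).
#' @param role `"whole-brain"` or `"tumor"`.
#' @return a list of class `segmentation_mask`.
#' @export
segmentation_mask <- function(pixels, spacing = c(1, 1),
                              role = c("whole-brain", "tumor")) {
  role <- match.arg(role)
  if (is.logical(pixels)) pixels <- pixels * 1
  if (!is.matrix(pixels) || !all(pixels %in% c(0, 1)))
    stop_invalid("mask pixels must be a 0/1 matrix")
  structure(list(pixels = pixels, spacing = as.numeric(spacing), role = role),
            class = "segmentation_mask")
}

as_mask_matrix <- function(x) {
  if (inherits(x, "segmentation_mask")) x$pixels
  else if (is.logical(x)) x * 1
  else x
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop_invalid("masks must have the same shape")
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` in `[0, 1]`; 1 is a perfect match, 0 no
#' overlap. Two empty masks score 1 (perfect agreement) with a warning.
#'
#' @param a,b same-shape binary masks ([segmentation_mask()] or 0/1
#'   matrices).
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  check_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a * b) / (sa + sb)
}

#' Jaccard overlap coefficient
#'
#' `|A n B| / |A u B|`; related to Dice by `J = D / (2 - D)`. Two empty
#' masks score 1 with a warning.
#'
#' @inheritParams dice
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  check_same_shape(a, b)
  uni <- sum(pmax(a, b))
  if (uni == 0) {
    warning("both masks empty; Jaccard defined as 1")
    return(1)
  }
  sum(a * b) / uni
}

# 8-connected boundary: foreground pixels with any background (or
# off-image) pixel among their 8 neighbors.
mask_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  mp <- matrix(0, h + 2, w + 2)
  mp[2:(h + 1), 2:(w + 1)] <- m
  inner_min <- matrix(1, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    inner_min <- pmin(inner_min, mp[2:(h + 1) + dr, 2:(w + 1) + dc])
  }
  which(m == 1 & inner_min == 0, arr.ind = TRUE)
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric Hausdorff distance: the greatest of all distances from a
#' boundary point in one mask to the closest boundary point of the other,
#' in mm (boundary points are extracted 8-connected and scaled by the
#' pixel spacing).
#'
#' @inheritParams dice
#' @param spacing mm per pixel (taken from the masks if they are
#'   [segmentation_mask()]s).
#' @return scalar distance in mm.
#' @export
hausdorff <- function(a, b, spacing = NULL) {
  if (is.null(spacing)) {
    spacing <- if (inherits(a, "segmentation_mask")) a$spacing else c(1, 1)
  }
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  check_same_shape(a, b)
  if (sum(a) == 0 || sum(b) == 0)
    stop_invalid("Hausdorff distance needs two non-empty masks")
  pa <- mask_boundary(a); pb <- mask_boundary(b)
  hausdorff_points(sweep(pa, 2, spacing, `*`), sweep(pb, 2, spacing, `*`))
}

#' @rdname hausdorff
#' @description `hausdorff_points()` computes the same quantity directly
#'   on two point sets (n x 2 matrices, already in mm).
#' @param pa,pb point matrices (rows are points).
#' @export
hausdorff_points <- function(pa, pb) {
  pa <- as.matrix(pa); pb <- as.matrix(pb)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  max(max(sqrt(apply(d2, 1, min))), max(sqrt(apply(d2, 2, min))))
}

#' Assemble the full pre/post evaluation record for one pair
#'
#' Computes TRE, Dice, Jaccard and Hausdorff before registration (moving
#' vs fixed) and after (moving mapped through the recovered transform vs
#' fixed), as one tidy row. Landmarks are forward-mapped from moving to
#' fixed space with the centered inverse of the recovered resampling
#' parameters; masks are warped with the parameters directly (backward
#' warp) and re-binarized at 0.5.
#'
#' @param fixed,moving the image pair ([image_grid()]s).
#' @param params recovered [affine_params()] (resampler convention:
#'   `warp_with_affine(moving, params)` aligns moving to fixed).
#' @param lm_fixed,lm_moving [landmark_set()]s in fixed/moving space.
#' @param mask_fixed,mask_moving whole-region [segmentation_mask()]s.
#' @param stratum label recorded in the output (`"tumor"`/`"healthy"`).
#' @return one-row tibble with pre/post values of all four metrics.
#' @export
evaluate_pair <- function(fixed, moving, params, lm_fixed, lm_moving,
                          mask_fixed, mask_moving,
                          stratum = c("healthy", "tumor")) {
  stratum <- match.arg(stratum)
  fixed <- as_image_grid(fixed); moving <- as_image_grid(moving)
  d <- dim(fixed$pixels)
  sp <- fixed$spacing
  inv <- invert_affine(params)
  lm_post <- transform_landmarks(lm_moving, inv, sp, d)
  mf <- as_mask_matrix(mask_fixed); mm <- as_mask_matrix(mask_moving)
  warped_mask <- (warp_with_affine(mm, params)$pixels > 0.5) * 1
  tibble::tibble(
    stratum = stratum,
    tre_pre = tre(lm_moving, lm_fixed)$mean,
    tre_post = tre(lm_post, lm_fixed)$mean,
    dice_pre = dice(mm, mf),
    dice_post = dice(warped_mask, mf),
    jaccard_pre = jaccard(mm, mf),
    jaccard_post = jaccard(warped_mask, mf),
    hausdorff_pre = hausdorff(mm, mf, sp),
    hausdorff_post = hausdorff(warped_mask, mf, sp))
}

#' Aggregate pair-level evaluation records per stratum
#'
#' Cohort-style summary: mean and standard deviation of every metric
#' within each stratum, mirroring the usual "mean (std)" reporting of
#' registration studies.
#'
#' @param records tibble of rows from [evaluate_pair()].
#' @return tibble with one row per stratum per metric.
#' @export
summarize_evaluation <- function(records) {
  metrics <- setdiff(names(records), "stratum")
  out <- lapply(split(records, records$stratum), function(g) {
    tibble::tibble(stratum = g$stratum[1], metric = metrics,
                   mean = vapply(metrics, function(m) mean(g[[m]]), numeric(1)),
                   sd = vapply(metrics, function(m)
                     if (nrow(g) > 1) sd(g[[m]]) else NA_real_, numeric(1)))
  })
  do.call(rbind, out)
}
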