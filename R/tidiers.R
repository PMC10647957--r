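#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training history out of a fit
#'
#' @param x a `mireg_fit` from [train()].
#' @param ... unused.
#' @return tibble with one row per epoch (epoch, loss, val_loss, seconds).
#' @method tidy mireg_fit
#' @export
tidy.mireg_fit <- function(x, ...) tibble::as_tibble(x$history)

#' @rdname tidy.mireg_fit
#' @return `glance()`: one-row tibble with the architecture and final
#'   losses.
#' @method glance mireg_fit
#' @export
glance.mireg_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_loss = h$loss[nrow(h)],
                 final_val_loss = h$val_loss[nrow(h)],
                 n_params = x$net$n_params,
                 learning_rate = x$config$learning_rate,
                 lambda = x$config$lambda)
}

#' Tidy the recovered transform of a registration
#'
#' @param x a `registration` from [register_pair()].
#' @param ... unused.
#' @return tibble of the six parameters (term, estimate).
#' @method tidy registration
#' @export
tidy.registration <- function(x, ...) {
  tibble::tibble(term = names(unclass(x$params)),
                 estimate = as.numeric(unclass(x$params)))
}

#' @rdname tidy.registration
#' @return `glance()`: one-row tibble with the MI of the pair before and
#'   after warping (64-bin soft histogram, bits) and the transform's
#'   rotation angle.
#' @method glance registration
#' @export
glance.registration <- function(x, ...) {
  f <- normalize(x$fixed); m <- normalize(x$moving); w <- normalize(x$warped)
  tibble::tibble(
    mi_before = mutual_information(soft_joint_histogram(f, m)),
    mi_after = mutual_information(soft_joint_histogram(f, w)),
    rotation_deg = affine_rotation_deg(x$params),
    tx = unclass(x$params)[["tx"]],
    ty = unclass(x$params)[["ty"]])
}

raster_df <- function(img, label) {
  px <- as_image_grid(img)$pixels
  tibble::tibble(row = as.vector(row(px)), col = as.vector(col(px)),
                 intensity = as.vector(px), panel = label)
}

#' Plot training and validation loss curves
#'
#' @param object a `train_history` tibble (or `mireg_fit`).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot train_history
#' @export
autoplot.train_history <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "epoch", y = "loss (-MI + λ reg)",
                  title = "Unsupervised training loss") +
    ggplot2::theme_minimal()
  if (any(is.finite(df$val_loss)))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$val_loss),
                                color = "#de2d26", linetype = 2)
  p
}

#' @method autoplot mireg_fit
#' @export
autoplot.mireg_fit <- function(object, ...) autoplot(object$history, ...)

#' Panel view of a registration result
#'
#' Fixed, moving, warped and the fixed-warped difference as intensity
#' rasters.
#'
#' @param object a `registration` from [register_pair()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot registration
#' @export
autoplot.registration <- function(object, ...) {
  f <- normalize(object$fixed); m <- normalize(object$moving)
  w <- normalize(object$warped)
  df <- rbind(raster_df(f, "fixed"), raster_df(m, "moving"),
              raster_df(w, "warped"),
              raster_df(image_grid(f$pixels - w$pixels), "fixed - warped"))
  df$panel <- factor(df$panel,
                     levels = c("fixed", "moving", "warped", "fixed - warped"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
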