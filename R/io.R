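#' Read a grayscale image (NIfTI or PNG)
#'
#' NIfTI spacing comes from the header; 3D volumes must be sliced with
#' `slice` (along the last axis) in this 2D pipeline. PNGs default to
#' 1 mm/px with a warning (color PNGs are collapsed to the channel mean).
#'
#' @param path file path (`.nii`, `.nii.gz` or `.png`).
#' @param slice optional 1-based slice index for 3D NIfTI volumes.
#' @return an [image_grid()].
#' @export
read_image <- function(path, slice = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    im <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(im)
    arr <- as.array(im)
    if (length(dim(arr)) == 3L) {
      if (is.null(slice))
        stop("3D volume ", path, ": supply `slice` to pick a 2D slice")
      arr <- arr[, , slice]
    }
    image_grid(arr, sp[1:2])
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3])],
                                             c(1, 2), mean)
    warning("PNG carries no spacing; assuming 1 mm/px")
    image_grid(arr, c(1, 1))
  } else stop("unsupported image format: ", path)
}

#' Write an image to NIfTI or PNG
#'
#' NIfTI keeps the physical spacing in the header. PNG rescales to
#' `[0, 1]` when intensities fall outside it (with a warning).
#'
#' @param image an [image_grid()].
#' @param path destination (`.nii`, `.nii.gz` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_image_grid(image)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    im <- RNifti::asNifti(image$pixels)
    RNifti::pixdim(im) <- c(image$spacing,
                            rep(1, length(dim(image$pixels)) - 2L))
    RNifti::writeNifti(im, path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- image$pixels
    if (min(px) < 0 || max(px) > 1) {
      warning("rescaling intensities to [0, 1] for PNG")
      px <- (px - min(px)) / max(max(px) - min(px), .Machine$double.eps)
    }
    png::writePNG(px, path)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' Displacement-field serialization
#'
#' Fields are stored as a NIfTI volume with the two displacement
#' components stacked along the third axis (component 1 = row
#' displacement, 2 = column displacement, both in pixels).
#'
#' @param field a `(H, W, 2)` displacement field.
#' @param path destination `.nii`/`.nii.gz`.
#' @return `read_field()` returns the field array.
#' @export
write_field <- function(field, path) {
  validate_field(field)
  RNifti::writeNifti(RNifti::asNifti(unclass(field)), path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  validate_field(arr)
  structure(arr, class = c("displacement_field", "array"))
}

#' Affine-parameter CSV serialization
#'
#' One row in the canonical order `(a11, a12, a21, a22, tx, ty)`.
#'
#' @param params an [affine_params()] object.
#' @param path CSV path.
#' @return `read_affine_csv()` returns the [affine_params()].
#' @export
write_affine_csv <- function(params, path) {
  params <- as_affine_params(params)
  df <- as.data.frame(as.list(unclass(params)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_affine_csv
#' @export
read_affine_csv <- function(path) {
  df <- read.csv(path)
  as_affine_params(unlist(df[1, c("a11", "a12", "a21", "a22", "tx", "ty")]))
}

#' Landmark CSV input/output
#'
#' CSV schema: header `name,x_mm,y_mm`, names validated against the
#' canonical landmark list (9 core names required; the 5 tumor names
#' optional as a block).
#'
#' @param path CSV path.
#' @param lm a [landmark_set()].
#' @return `read_landmarks()` returns a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  landmark_set(df)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  write.csv(as.data.frame(lm[, c("name", "x_mm", "y_mm")]), path,
            row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' One nested list holding every knob of a run; the defaults reproduce
#' the proposed recipe exactly (filters `[32 x 5]`, kernel 3, stride 2,
#' Leaky-ReLU 0.2, He-normal, no pooling/dropout, 64 MI bins, Adam at
#' learning rate `1e-4`, 500 epochs). Serializes to YAML or JSON;
#' parse -> serialize -> parse is idempotent.
#'
#' @param mode `"2d"` (the implemented pipeline).
#' @param network,loss,train,paths overrides merged over the defaults.
#' @return a list of class `run_config`.
#' @export
run_config <- function(mode = "2d", network = list(), loss = list(),
                       train = list(), paths = list()) {
  if (!identical(mode, "2d")) stop_invalid("only mode '2d' is implemented")
  base <- list(
    mode = "2d",
    network = list(input_size = c(256L, 256L), conv_filters = rep(32L, 5),
                   kernel_size = 3L, stride = 2L, leaky_slope = 0.2,
                   initializer = "he-normal", output_dim = 6L,
                   in_channels = 2L),
    loss = list(n_bins = 64L, bandwidth = 1, base = 2, normalized = FALSE),
    train = list(learning_rate = 1e-4, epochs = 500L, batch_size = 4L,
                 lambda = 0.01, regularizer = "bending-energy", seed = 1L),
    paths = list(corpus = NULL, out = NULL))
  base$network <- modifyList(base$network, network)
  base$loss <- modifyList(base$loss, loss)
  base$train <- modifyList(base$train, train)
  base$paths <- modifyList(base$paths, paths)
  structure(base, class = "run_config")
}

#' @rdname run_config
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: ", path)
  run_config(mode = raw$mode %||% "2d", network = raw$network %||% list(),
             loss = raw$loss %||% list(), train = raw$train %||% list(),
             paths = raw$paths %||% list())
}

#' @rdname run_config
#' @param config a `run_config` to write.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$paths <- plain$paths[!vapply(plain$paths, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(plain, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config format: ", path)
  invisible(path)
}

#' Write a phantom corpus to disk
#'
#' Directory layout: `manifest.csv` plus one `pairNNN/` directory per pair
#' holding `fixed.nii.gz`, `moving.nii.gz`, whole-region and (when
#' present) tumor masks in both spaces, fixed/moving landmark CSVs and a
#' `truth.json` with the ground-truth parameters.
#'
#' @param corpus a [make_corpus()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(corpus$manifest), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  for (i in seq_along(corpus$pairs)) {
    p <- corpus$pairs[[i]]
    pd <- file.path(dir, corpus$manifest$id[i])
    dir.create(pd, showWarnings = FALSE)
    write_image(p$fixed, file.path(pd, "fixed.nii.gz"))
    write_image(p$moving, file.path(pd, "moving.nii.gz"))
    write_image(image_grid(p$truth$mask_fixed$pixels, p$spec$spacing),
                file.path(pd, "mask_fixed.nii.gz"))
    write_image(image_grid(p$truth$mask_moving$pixels, p$spec$spacing),
                file.path(pd, "mask_moving.nii.gz"))
    if (!is.null(p$truth$tumor_mask_fixed)) {
      write_image(image_grid(p$truth$tumor_mask_fixed$pixels, p$spec$spacing),
                  file.path(pd, "tumor_mask_fixed.nii.gz"))
      write_image(image_grid(p$truth$tumor_mask_moving$pixels, p$spec$spacing),
                  file.path(pd, "tumor_mask_moving.nii.gz"))
    }
    write_landmarks(p$truth$lm_fixed, file.path(pd, "landmarks_fixed.csv"))
    write_landmarks(p$truth$lm_moving, file.path(pd, "landmarks_moving.csv"))
    jsonlite::write_json(list(params = unclass(p$truth$params),
                              seed = p$seed, stratum = p$stratum),
                         file.path(pd, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read a phantom corpus written by [write_corpus()]
#'
#' @param dir corpus directory.
#' @return list with `manifest` (tibble) and `pairs` (fixed/moving images,
#'   landmarks, masks and truth params per pair).
#' @export
read_corpus <- function(dir) {
  mf <- tibble::as_tibble(read.csv(file.path(dir, "manifest.csv"),
                                   stringsAsFactors = FALSE))
  pairs <- lapply(mf$id, function(id) {
    pd <- file.path(dir, id)
    tj <- jsonlite::read_json(file.path(pd, "truth.json"),
                              simplifyVector = TRUE)
    fixed <- read_image(file.path(pd, "fixed.nii.gz"))
    tmf <- file.path(pd, "tumor_mask_fixed.nii.gz")
    list(fixed = fixed,
         moving = read_image(file.path(pd, "moving.nii.gz")),
         truth = list(
           params = as_affine_params(unlist(tj$params)),
           lm_fixed = read_landmarks(file.path(pd, "landmarks_fixed.csv")),
           lm_moving = read_landmarks(file.path(pd, "landmarks_moving.csv")),
           mask_fixed = segmentation_mask(
             (read_image(file.path(pd, "mask_fixed.nii.gz"))$pixels > 0.5) * 1,
             fixed$spacing),
           mask_moving = segmentation_mask(
             (read_image(file.path(pd, "mask_moving.nii.gz"))$pixels > 0.5) * 1,
             fixed$spacing),
           tumor_mask_fixed = if (file.exists(tmf)) segmentation_mask(
             (read_image(tmf)$pixels > 0.5) * 1, fixed$spacing, "tumor"),
           tumor_mask_moving = if (file.exists(tmf)) segmentation_mask(
             (read_image(file.path(pd, "tumor_mask_moving.nii.gz"))$pixels
              > 0.5) * 1, fixed$spacing, "tumor")),
         stratum = tj$stratum)
  })
  list(manifest = mf, pairs = pairs)
}
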