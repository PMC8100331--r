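#' Read an MNIST-style IDX image/label file pair
#'
#' Parses the big-endian IDX container in which the MNIST-family data sets are
#' distributed: magic `0x00000803` for images (dimensions `n x rows x cols`,
#' one unsigned byte per pixel, row-major) and `0x00000801` for labels. Pixel
#' bytes are rescaled to `[0, 1]` by dividing by 255, so downstream consumers
#' all see one input convention.
#'
#' @param images Path to the image file.
#' @param labels Optional path to the matching label file.
#' @return A tibble with feature columns `x1..xp` (`p = rows * cols`) and,
#'   when labels are supplied, an integer `class` column. Attributes record
#'   the source file and the original scale (255).
#' @export
read_idx <- function(images, labels = NULL) {
  img <- read_idx_images(images)
  out <- tibble::as_tibble(as.data.frame(img$X), .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(ncol(img$X)))
  if (!is.null(labels)) {
    lab <- read_idx_labels(labels)
    if (length(lab) != nrow(out)) {
      abort(sprintf("IDX count mismatch: %d images but %d labels",
                    nrow(out), length(lab)))
    }
    out$class <- lab
  }
  attr(out, "source") <- images
  attr(out, "scale_max") <- 255
  out
}

read_idx_images <- function(path) {
  if (!file.exists(path)) abort(sprintf("IDX file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L)) {
    abort(sprintf("bad IDX image magic 0x%08x at offset 0 in %s", magic, path))
  }
  dims <- readBin(con, "integer", 3, size = 4, endian = "big")
  if (length(dims) < 3) abort(sprintf("short IDX header at offset 4 in %s", path))
  n <- dims[1]; rows <- dims[2]; cols <- dims[3]
  want <- n * rows * cols
  px <- readBin(con, "integer", want, size = 1, signed = FALSE)
  if (length(px) != want) {
    abort(sprintf("short IDX image payload at offset %d in %s (got %d of %d bytes)",
                  16 + length(px), path, length(px), want))
  }
  # row-major flattening: pixels of one image stay contiguous
  X <- matrix(px / 255, nrow = n, ncol = rows * cols, byrow = TRUE)
  list(X = X, rows = rows, cols = cols)
}

read_idx_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("IDX file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2049L)) {
    abort(sprintf("bad IDX label magic 0x%08x at offset 0 in %s", magic, path))
  }
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  lab <- readBin(con, "integer", n, size = 1, signed = FALSE)
  if (length(lab) != n) {
    abort(sprintf("short IDX label payload at offset %d in %s",
                  8 + length(lab), path))
  }
  as.integer(lab)
}

#' Read a samples-by-features CSV data set
#'
#' Expects one sample per row; a column named `class` (or `label`) is treated
#' as the integer class. Feature values must be non-negative; if any exceed 1
#' the whole feature block is rescaled by its maximum so every consumer sees
#' the `[0, 1]` convention, with the original maximum recorded in the
#' `scale_max` attribute.
#'
#' @param path CSV file path.
#' @return A tibble of features (plus `class` when present).
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("CSV file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  lab_col <- intersect(c("class", "label"), names(df))[1]
  cls <- NULL
  if (!is.na(lab_col)) {
    cls <- as.integer(df[[lab_col]])
    df[[lab_col]] <- NULL
  }
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  if (anyNA(X)) abort(sprintf("missing feature values in %s", path))
  if (any(X < 0)) abort(sprintf("negative feature values in %s", path))
  mx <- max(X)
  if (mx > 1) X <- X / mx
  out <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  if (!is.null(cls)) out$class <- cls
  attr(out, "source") <- path
  attr(out, "scale_max") <- max(mx, 1)
  out
}

#' Write a data set to CSV
#'
#' @param data Tibble/data frame of features (optionally with `class`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a fitted model
#'
#' Serializes the full model state — weights, thresholds, configuration, win
#' counts, metrics log and (if present) the neuron labeling — to a versioned
#' JSON container. Numbers are written with 17 significant digits, so
#' `load_model(save_model(x))` reproduces every array bitwise.
#'
#' @param model A `crba` model.
#' @param path Output file path.
#' @return `path` invisibly (`save_model`); the restored model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "crba"))
  payload <- list(
    format = "crba-model",
    version = MODEL_FORMAT_VERSION,
    p = nrow(model$W),
    m = ncol(model$W),
    W = as.vector(model$W),
    theta = model$theta,
    config = unclass(model$config),
    presentations = model$presentations,
    win_counts = model$win_counts,
    metrics = as.list(model$metrics),
    labeling = if (is.null(model$labeling)) NULL else list(
      labels = model$labeling$labels,
      classes = model$labeling$classes,
      activity = as.vector(model$labeling$activity)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "crba-model")) {
    abort(sprintf("not a crba model container: %s", path))
  }
  if (!identical(as.integer(obj$version), MODEL_FORMAT_VERSION)) {
    abort(sprintf("model format version %s not supported (expected %d)",
                  obj$version, MODEL_FORMAT_VERSION))
  }
  cfg <- obj$config
  cfg$m <- as.integer(cfg$m); cfg$n <- as.integer(cfg$n)
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("t", "lambda", "alpha_s", "alpha_w", "alpha_theta", "theta_0",
              "theta_r", "tau_theta", "theta_floor")) {
    cfg[[f]] <- as.numeric(cfg[[f]])
  }
  config <- structure(cfg[c("m", "n", "t", "lambda", "alpha_s", "alpha_w",
                            "alpha_theta", "theta_0", "theta_r", "tau_theta",
                            "seed", "theta_floor")],
                      class = "crba_config")
  labeling <- NULL
  if (!is.null(obj$labeling) && length(obj$labeling) > 0) {
    classes <- as.integer(obj$labeling$classes)
    labeling <- list(
      labels = as.integer(obj$labeling$labels),
      classes = classes,
      activity = matrix(obj$labeling$activity, nrow = obj$m,
                        ncol = length(classes))
    )
  } else {
    inform(sprintf("model in %s has no labeling; label before predicting", path))
  }
  metrics <- if (is.null(obj$metrics) || length(obj$metrics) == 0) {
    tibble::tibble(presentation = numeric(), mean_theta = numeric(),
                   min_theta = numeric(), max_theta = numeric(),
                   mean_winner_spikes = numeric())
  } else {
    tibble::as_tibble(lapply(obj$metrics, as.numeric))
  }
  structure(
    list(W = matrix(as.numeric(obj$W), nrow = obj$p, ncol = obj$m),
         theta = as.numeric(obj$theta),
         config = config,
         presentations = as.integer(obj$presentations),
         win_counts = as.integer(obj$win_counts),
         metrics = metrics,
         labeling = labeling),
    class = "crba"
  )
}
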