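# Shared coercion of tabular input data to the feature matrix the learners use.
#
# Data frames carry one sample per row, feature columns numeric and
# non-negative, with an optional integer `class` column. Matrices are accepted
# directly.

as_input_matrix <- function(data, require_class = FALSE) {
  if (is.matrix(data)) {
    X <- data
    classes <- attr(data, "class_labels", exact = TRUE)
  } else if (is.data.frame(data)) {
    classes <- if ("class" %in% names(data)) data[["class"]] else NULL
    feat <- setdiff(names(data), "class")
    ok <- vapply(data[feat], is.numeric, logical(1))
    if (!all(ok)) {
      abort(sprintf("non-numeric feature column(s): %s",
                    paste(feat[!ok], collapse = ", ")))
    }
    X <- as.matrix(data[feat])
  } else {
    abort("`data` must be a data frame or a numeric matrix")
  }
  storage.mode(X) <- "double"
  dimnames(X) <- NULL
  if (nrow(X) == 0L) abort("`data` has no rows")
  if (anyNA(X) || any(!is.finite(X))) abort("input features must be finite")
  if (any(X < 0)) abort("input features must be non-negative")
  list(X = X, classes = if (is.null(classes)) NULL else as.integer(classes))
}

check_dims <- function(x, p, what = "x") {
  if (length(x) != p) {
    abort(sprintf("dimension mismatch: %s has length %d, expected %d",
                  what, length(x), p))
  }
  invisible(x)
}

cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
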