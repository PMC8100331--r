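#' Assign class labels to trained neurons
#'
#' Second half of the learning phase: with weights and thresholds frozen, each
#' neuron's response (`alpha_s * t * rate`, the predicted spike count it would
#' fire) is accumulated per class over a labeled sample set, and each neuron
#' receives the class for which it was most active. No weights or thresholds
#' are modified. Ties go to the lowest class id.
#'
#' @param model A fitted `crba` model.
#' @param data Labeled samples: data frame with feature columns and an integer
#'   `class` column.
#' @param classes Optional full class set; classes present here but absent
#'   from `data` trigger a warning and stay unassignable.
#' @return The model with a `labeling` component: per-neuron `labels`, the
#'   ordered `classes`, and the `m x K` accumulated `activity` matrix.
#' @export
crba_label <- function(model, data, classes = NULL) {
  stopifnot(inherits(model, "crba"))
  inp <- as_input_matrix(data)
  if (is.null(inp$classes)) abort("labeling data must carry a `class` column")
  seen <- sort(unique(inp$classes))
  if (is.null(classes)) {
    classes <- seen
  } else {
    classes <- sort(as.integer(unique(classes)))
    missing <- setdiff(classes, seen)
    if (length(missing) > 0) {
      warn(sprintf("class(es) with zero labeling samples stay unassignable: %s",
                   paste(missing, collapse = ", ")))
    }
  }
  R <- model$config$alpha_s * model$config$t *
    rates_matrix(inp$X, model$W, model$theta, model$config$theta_floor)
  # activity[j, c]: neuron j's summed response to class c
  activity <- matrix(0, ncol(model$W), length(classes))
  for (ci in seq_along(classes)) {
    sel <- inp$classes == classes[ci]
    if (any(sel)) activity[, ci] <- colSums(R[sel, , drop = FALSE])
  }
  labels <- classes[max.col(activity, ties.method = "first")]
  model$labeling <- list(labels = as.integer(labels),
                         classes = as.integer(classes),
                         activity = unname(activity))
  model
}

#' Predict classes by maximum voting
#'
#' For each new sample the per-neuron responses are grouped by neuron label
#' and averaged (so classes represented by more neurons are not favored); the
#' predicted class is the one with the highest average response, ties going to
#' the lowest class id. If every response is exactly zero there is no
#' evidence: the most common neuron label is returned and the row is flagged.
#'
#' @param object A labeled `crba` model (see [crba_label()]).
#' @param new_data Data frame or matrix of samples (a `class` column, if
#'   present, is ignored).
#' @param ... Unused.
#' @return A tibble with one row per sample: `.pred_class`, one `vote_<class>`
#'   column per class (the average response), and `no_evidence`.
#' @export
predict.crba <- function(object, new_data, ...) {
  lab <- object$labeling
  if (is.null(lab)) abort("model unlabeled: run crba_label() first")
  inp <- as_input_matrix(new_data)
  R <- rates_matrix(inp$X, object$W, object$theta, object$config$theta_floor)
  votes <- vote_matrix(R, lab)
  pred <- lab$classes[max.col(votes, ties.method = "first")]
  none <- rowSums(R) == 0
  if (any(none)) {
    counts <- table(factor(lab$labels, levels = lab$classes))
    pred[none] <- lab$classes[which.max(counts)]
    warn(sprintf("%d sample(s) evoked no response; assigned the most common label",
                 sum(none)))
  }
  out <- tibble::tibble(.pred_class = as.integer(pred), no_evidence = none)
  vt <- tibble::as_tibble(as.data.frame(votes), .name_repair = "minimal")
  names(vt) <- paste0("vote_", lab$classes)
  dplyr::bind_cols(out, vt)
}

vote_matrix <- function(R, labeling) {
  K <- length(labeling$classes)
  votes <- matrix(-Inf, nrow(R), K)              # unassignable classes never win
  for (ci in seq_len(K)) {
    sel <- labeling$labels == labeling$classes[ci]
    if (any(sel)) votes[, ci] <- rowMeans(R[, sel, drop = FALSE])
  }
  votes
}

#' Classification accuracy of a labeled model
#'
#' @param model A labeled `crba` model.
#' @param data Test samples with a `class` column.
#' @return A one-row tibble: `accuracy`, `n_correct`, `n`.
#' @export
crba_evaluate <- function(model, data) {
  inp <- as_input_matrix(data)
  if (is.null(inp$classes)) abort("evaluation data must carry a `class` column")
  pred <- predict(model, data)
  tibble::tibble(accuracy = mean(pred$.pred_class == inp$classes),
                 n_correct = sum(pred$.pred_class == inp$classes),
                 n = nrow(inp$X))
}

#' Confusion matrix of a labeled model
#'
#' @param model A labeled `crba` model.
#' @param data Test samples with a `class` column.
#' @return A tibble in long form: `truth`, `estimate`, `n`.
#' @export
crba_confusion <- function(model, data) {
  inp <- as_input_matrix(data)
  if (is.null(inp$classes)) abort("data must carry a `class` column")
  pred <- predict(model, data)
  tb <- table(truth = inp$classes, estimate = pred$.pred_class)
  out <- tibble::as_tibble(as.data.frame(tb, stringsAsFactors = FALSE))
  names(out) <- c("truth", "estimate", "n")
  dplyr::mutate(out, truth = as.integer(.data$truth),
                estimate = as.integer(.data$estimate))
}
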