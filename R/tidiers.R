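#' Tidy a fitted competitive model
#'
#' @param x A `crba` model.
#' @param ... Unused.
#' @return One row per neuron: `neuron`, `threshold` (mV), `wins` (times top
#'   winner), `weight_sum`, and `label` (NA until [crba_label()] is run).
#' @export
tidy.crba <- function(x, ...) {
  tibble::tibble(
    neuron = seq_len(ncol(x$W)),
    threshold = x$theta,
    wins = x$win_counts,
    weight_sum = colSums(x$W),
    label = if (is.null(x$labeling)) NA_integer_ else x$labeling$labels
  )
}

#' One-row model summary
#'
#' @param x A `crba` model.
#' @param ... Unused.
#' @return A one-row tibble: network size, presentations seen, threshold
#'   summary, last-window mean winner spikes, and whether the model is labeled.
#' @export
glance.crba <- function(x, ...) {
  last_spk <- if (nrow(x$metrics) > 0) {
    x$metrics$mean_winner_spikes[nrow(x$metrics)]
  } else {
    NA_real_
  }
  tibble::tibble(
    m = ncol(x$W), n = x$config$n, p = nrow(x$W),
    presentations = x$presentations,
    mean_theta = mean(x$theta), min_theta = min(x$theta),
    max_theta = max(x$theta),
    mean_winner_spikes = last_spk,
    labeled = !is.null(x$labeling)
  )
}

#' Plot the training dynamics of a fitted model
#'
#' Shows the windowed mean firing threshold (with its min-max band) and the
#' windowed mean predicted winner spike count against the number of
#' presentations — the two homeostatic quantities whose opposing trends
#' (thresholds up, spikes down) signal convergence of the competition.
#'
#' @param object A `crba` model with a non-empty metrics log.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crba <- function(object, ...) {
  mt <- object$metrics
  if (nrow(mt) == 0) abort("no metrics logged; fit with presentations > 0")
  long <- tidyr::pivot_longer(
    mt, c("mean_theta", "mean_winner_spikes"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, c("mean_theta", "mean_winner_spikes"),
                        c("mean firing threshold (mV)",
                          "mean winner spikes / presentation"))
  band <- dplyr::mutate(mt, metric = factor("mean firing threshold (mV)",
                                            levels = levels(long$metric)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$presentation, y = .data$value)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(y = NULL, ymin = .data$min_theta,
                                      ymax = .data$max_theta),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "presentations", y = NULL)
}

#' Spike raster of one presentation
#'
#' @param object A `csnn_record` from [csnn_present()].
#' @param ... Unused.
#' @return A ggplot raster of output spikes (time vs neuron).
#' @export
autoplot.csnn_record <- function(object, ...) {
  ggplot2::ggplot(object$spikes,
                  ggplot2::aes(x = .data$time, y = factor(.data$neuron))) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, object$T)) +
    ggplot2::labs(x = "time (ms)", y = "neuron")
}
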