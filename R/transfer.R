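#' Transfer rate-based parameters into the spiking network
#'
#' Initializes a spiking layer from a trained rate-based model ("CSNN+CRBA").
#' Weights are copied verbatim — both models use the same per-neuron
#' column-sum normalization, so no rescaling is needed. Thresholds, which the
#' rate-based model drives to much higher values than the spiking network
#' operates at, are mapped by a linear min-max rescaling onto
#' `[theta_min, theta_max]` mV (default 35-60 mV, the stable high-threshold
#' regime); the linear map preserves the learned threshold rank order exactly.
#' If all thresholds are equal the degenerate map sends them to the interval
#' midpoint.
#'
#' The rescaled value is used as the total effective threshold of the
#' spiking neuron (offset plus adaptive component), since it is the adaptive
#' component that encodes each neuron's excitability history.
#'
#' @param model A fitted `crba` model.
#' @param params A [csnn_params()] to attach to the state.
#' @param theta_min,theta_max Target threshold range (mV), `min < max`.
#' @return A `csnn_state`: `W`, `theta` (mV), and `params`.
#' @examples
#' d <- make_synthetic(k = 2, p = 16, per_class = 10, seed = 1)
#' fit <- crba_fit(d, crba_config(m = 2, seed = 1), presentations = 100)
#' transfer_parameters(fit)
#' @export
transfer_parameters <- function(model, params = csnn_params(),
                                theta_min = 35, theta_max = 60) {
  stopifnot(inherits(model, "crba"))
  if (!(theta_min < theta_max)) abort("need theta_min < theta_max")
  th <- model$theta
  rng <- range(th)
  theta_new <- if (rng[1] == rng[2]) {
    rep((theta_min + theta_max) / 2, length(th))
  } else {
    theta_min + (th - rng[1]) / (rng[2] - rng[1]) * (theta_max - theta_min)
  }
  structure(list(W = model$W, theta = theta_new, params = params),
            class = "csnn_state")
}

#' @export
print.csnn_state <- function(x, ...) {
  cat(sprintf("<csnn_state: %d neurons, %d channels, thresholds %.2f .. %.2f mV>\n",
              ncol(x$W), nrow(x$W), min(x$theta), max(x$theta)))
  invisible(x)
}
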