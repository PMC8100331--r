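#' Poisson rate encoding of an input vector
#'
#' Channel `i` emits a spike in each time step independently with probability
#' `dt * beta * x_i` — a Bernoulli thinning of a Poisson process at rate
#' `beta * x_i` spikes/ms. Deterministic given the seed.
#'
#' @param x Input vector, rescaled to `[0, 1]`.
#' @param params A [csnn_params()].
#' @param seed Optional RNG seed.
#' @return A `spike_trains` object: a `p x n_steps` integer matrix of spike
#'   counts plus timing metadata.
#' @export
poisson_encode <- function(x, params, seed = NULL) {
  stopifnot(inherits(params, "csnn_params"))
  if (any(x < 0)) abort("input intensities must be non-negative")
  pr <- params$dt * params$beta * x
  if (max(pr) >= 1) {
    abort(sprintf("rate too high for time step: dt*beta*max(x) = %.3g >= 1", max(pr)))
  }
  if (!is.null(seed)) set.seed(seed)
  p <- length(x)
  S <- matrix(rbinom(p * params$n_steps, 1L, rep(pr, params$n_steps)),
              nrow = p, ncol = params$n_steps)
  new_spike_trains(S, params)
}

#' Regular (deterministic) rate encoding
#'
#' Channel `i` fires at the constant rate `beta * x_i` spikes/ms, delivered at
#' the step boundaries where the cumulative expected count crosses an integer.
#' Rates above `1/dt` deliver multiple spikes in one step. This is the
#' constant-frequency drive under which the closed-form membrane solution is
#' derived, so it is the encoder used to validate the integrator.
#'
#' @inheritParams poisson_encode
#' @return A `spike_trains` object.
#' @export
regular_encode <- function(x, params) {
  stopifnot(inherits(params, "csnn_params"))
  if (any(x < 0)) abort("input intensities must be non-negative")
  f_dt <- params$beta * x * params$dt
  steps <- seq_len(params$n_steps)
  S <- vapply(steps, function(s) {
    as.integer(floor(f_dt * s) - floor(f_dt * (s - 1)))
  }, integer(length(x)))
  if (length(x) == 1L) S <- matrix(S, nrow = 1L)
  new_spike_trains(S, params)
}

new_spike_trains <- function(S, params) {
  structure(list(spikes = S, dt = params$dt, T = params$T,
                 n_steps = params$n_steps),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains: %d channels x %d steps (%g ms), %d spikes>\n",
              nrow(x$spikes), x$n_steps, x$T, sum(x$spikes)))
  invisible(x)
}

#' @export
tidy.spike_trains <- function(x, ...) {
  idx <- which(x$spikes > 0, arr.ind = TRUE)
  tibble::tibble(channel = as.integer(idx[, 1]),
                 time = idx[, 2] * x$dt,
                 count = as.integer(x$spikes[idx]))
}

#' Present encoded input to the spiking layer
#'
#' Integrates the layer over one presentation: exact-exponential leak per
#' step, delta-pulse excitation from the input trains, all-to-all lateral
#' inhibition triggered by output spikes, post-spike reset and refractory
#' hold, adaptive thresholds (jump per spike, exponential relaxation toward
#' the offset), and — with `learning = TRUE` — nearest-spike STDP on the
#' firing neuron's afferents followed by column renormalization at the end of
#' the presentation. Simultaneous threshold crossings resolve lowest index
#' first.
#'
#' @param trains A `spike_trains` object.
#' @param W Weight matrix, channels x neurons.
#' @param theta Total firing thresholds (mV); `Inf` entries never fire.
#' @param params A [csnn_params()].
#' @param learning Apply STDP and normalization?
#' @return A `csnn_record`: tibble of output `spikes` (`neuron`, `time`),
#'   per-neuron `counts`, final membranes `u`, the (possibly updated) `W` and
#'   `theta`, and `first_spiker` (`NA` if silent).
#' @export
csnn_present <- function(trains, W, theta, params, learning = FALSE) {
  stopifnot(inherits(trains, "spike_trains"), inherits(params, "csnn_params"))
  W <- as.matrix(W)
  if (nrow(W) != nrow(trains$spikes)) {
    abort("weight rows must match the number of input channels")
  }
  if (length(theta) == 1L) theta <- rep(theta, ncol(W))
  res <- csnn_present_cpp(trains$spikes, W, as.numeric(theta),
                          learning,
                          params$tau_u, params$u_r, params$u_reset,
                          params$t_refrac, params$dt, params$w_inh,
                          params$alpha_plus, params$alpha_minus,
                          params$tau_plus, params$tau_minus,
                          params$theta0_offset, params$alpha_theta_inc,
                          params$tau_theta0, params$lambda)
  structure(
    list(spikes = tibble::tibble(neuron = res$spike_neuron,
                                 time = res$spike_time),
         counts = as.integer(res$counts),
         u = res$u, W = res$W, theta = res$theta,
         first_spiker = res$first_spiker,
         T = params$T, dt = params$dt),
    class = "csnn_record"
  )
}

#' @export
print.csnn_record <- function(x, ...) {
  cat(sprintf("<csnn_record: %d neurons, %d spikes over %g ms>\n",
              length(x$counts), nrow(x$spikes), x$T))
  invisible(x)
}

#' @export
tidy.csnn_record <- function(x, ...) x$spikes

#' Closed-form membrane potential under a constant-rate drive
#'
#' For a leaky integrate-and-fire neuron with direct synapses driven by
#' constant-frequency trains (rates `beta * x_i`), the membrane approaches its
#' steady state exponentially:
#' `u(t) = tau_u * beta * <x, w> * (1 - exp(-t / tau_u))` (zero-rest
#' convention). The approximation is accurate once each contributing rate
#' satisfies `f * tau_u >~ 3`.
#'
#' @param x Input vector.
#' @param w Weight column.
#' @param params A [csnn_params()].
#' @param t Time since presentation onset (ms); vectorized.
#' @return Membrane potential(s) in mV.
#' @export
membrane_closed_form <- function(x, w, params, t) {
  stopifnot(length(x) == length(w), all(t >= 0))
  params$tau_u * params$beta * sum(x * w) * (1 - exp(-t / params$tau_u))
}

#' Closed-form first-spike time
#'
#' Inverts the closed-form membrane trajectory at a fixed threshold:
#' `t_f = tau_u * (log(S) - log(S - theta))` with steady state
#' `S = tau_u * beta * <x, w>`. Returns `Inf` ("never") when the threshold is
#' at or above the steady state.
#'
#' @inheritParams membrane_closed_form
#' @param theta Firing threshold (mV), `> 0`.
#' @return First-spike time in ms, or `Inf`.
#' @export
firing_time_closed_form <- function(x, w, theta, params) {
  stopifnot(theta > 0)
  S <- params$tau_u * params$beta * sum(x * w)
  if (theta >= S) return(Inf)
  params$tau_u * (log(S) - log(S - theta))
}

#' STDP weight change for one spike pair
#'
#' Two-branch exponential kernel over the pre-to-post time difference
#' `delta_t = t_post - t_pre`: potentiation `alpha_plus * exp(-delta_t /
#' tau_plus)` for `delta_t > 0`, depression `-alpha_minus * exp(delta_t /
#' tau_minus)` for `delta_t <= 0` (simultaneous spikes depress).
#'
#' @param delta_t Pre-to-post time difference(s) in ms; vectorized.
#' @param params A [csnn_params()].
#' @return Weight change(s).
#' @export
stdp_delta <- function(delta_t, params) {
  ifelse(delta_t > 0,
         params$alpha_plus * exp(-delta_t / params$tau_plus),
         -params$alpha_minus * exp(delta_t / params$tau_minus))
}

#' Relax an adaptive threshold over elapsed time
#'
#' Between spikes the threshold decays exponentially toward its offset:
#' `theta0_offset + (theta - theta0_offset) * exp(-elapsed / tau_theta0)`.
#'
#' @param theta Threshold(s) in mV.
#' @param elapsed Elapsed time in ms (`>= 0`).
#' @param params A [csnn_params()].
#' @return Relaxed threshold(s).
#' @export
threshold_relax <- function(theta, elapsed, params) {
  stopifnot(all(elapsed >= 0))
  params$theta0_offset + (theta - params$theta0_offset) * exp(-elapsed / params$tau_theta0)
}

#' Simulate a data set through the spiking layer
#'
#' Presents each row of `data` to a spiking layer in a given state, with
#' Poisson (default) or regular encoding, and reports the per-sample winner
#' (the first neuron to spike) and total output spikes. With
#' `learning = FALSE` the state is untouched; with `learning = TRUE` the
#' updated state is carried across presentations and returned.
#'
#' @param data Data frame or matrix of samples.
#' @param state A `csnn_state` (see [transfer_parameters()]) or a list with
#'   `W` and `theta`.
#' @param params A [csnn_params()]; defaults to the state's own, if present.
#' @param learning Apply STDP and normalization across presentations?
#' @param encode `"poisson"` or `"regular"`.
#' @param seed Seed for the Poisson encoder (one stream for the whole run).
#' @return A list with `results` (tibble: `sample`, `winner`, `n_spikes`),
#'   the per-sample `counts` matrix, and the final `state`.
#' @export
csnn_simulate <- function(data, state, params = NULL, learning = FALSE,
                          encode = c("poisson", "regular"), seed = 1L) {
  encode <- match.arg(encode)
  if (is.null(params)) params <- state$params
  stopifnot(inherits(params, "csnn_params"))
  inp <- as_input_matrix(data)
  W <- state$W; theta <- state$theta
  m <- ncol(W)
  n <- nrow(inp$X)
  winners <- integer(n); nspk <- integer(n)
  counts <- matrix(0L, n, m)
  if (encode == "poisson") set.seed(seed)
  for (i in seq_len(n)) {
    trains <- if (encode == "poisson") {
      poisson_encode(inp$X[i, ], params)
    } else {
      regular_encode(inp$X[i, ], params)
    }
    rec <- csnn_present(trains, W, theta, params, learning = learning)
    winners[i] <- ifelse(is.na(rec$first_spiker), NA_integer_, rec$first_spiker)
    nspk[i] <- sum(rec$counts)
    counts[i, ] <- rec$counts
    if (learning) { W <- rec$W; theta <- rec$theta }
  }
  state$W <- W; state$theta <- theta
  list(results = tibble::tibble(sample = seq_len(n), winner = winners,
                                n_spikes = nspk),
       counts = counts, state = state)
}
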