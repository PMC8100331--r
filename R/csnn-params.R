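#' Parameters of the spiking reference network
#'
#' Configures the time-stepped competitive spiking network: Poisson rate
#' encoding, leaky integrate-and-fire neurons with direct (delta-pulse)
#' synapses, lateral inhibition, adaptive firing thresholds and STDP. The
#' default presentation is 350 ms at a 0.1 ms step (3500 steps).
#'
#' Membrane convention: resting and reset potentials are zero, so the membrane
#' steady state under a constant-rate drive is `tau_u * beta * <x, w>` mV.
#' The default encoding gain `beta = 2` spikes/ms per unit intensity places
#' that steady state at O(100 mV) for unit-scaled inputs and weight columns
#' summing to `lambda = 1`, which makes firing thresholds in the tens of mV —
#' the regime of the transferred rate-based thresholds — operational. Gains
#' quoted per pixel in conductance-based implementations (e.g. 63.75 Hz at
#' full intensity) are not directly comparable because their synapses scale
#' with the driving force rather than delivering fixed mV kicks.
#'
#' @param tau_u Membrane time constant (ms).
#' @param u_r Resting potential (mV).
#' @param u_reset Post-spike reset potential (mV).
#' @param t_refrac Refractory period (ms); the membrane is held at `u_reset`.
#' @param dt Integration step (ms); `T` must be a whole number of steps.
#' @param T Presentation time (ms).
#' @param beta Encoding gain: spikes/ms per unit input intensity.
#' @param w_inh Lateral inhibition weight (mV per inhibitory spike). The
#'   default 500 is the "strong inhibition" regime in which a single spike
#'   silences the rest of the layer for most of a presentation; values of a
#'   few mV give the "soft" regime in which several neurons fire.
#' @param alpha_plus,alpha_minus STDP potentiation/depression magnitudes.
#' @param tau_plus,tau_minus STDP time constants (ms).
#' @param theta0_offset Threshold offset (mV): the value the adaptive
#'   threshold relaxes toward.
#' @param alpha_theta_inc Threshold increment per output spike (mV).
#' @param tau_theta0 Threshold decay time constant (ms).
#' @param lambda Per-neuron total connection weight (shared with the
#'   rate-based model).
#' @return An object of class `csnn_params`.
#' @export
csnn_params <- function(tau_u = 100, u_r = 0, u_reset = 0, t_refrac = 5,
                        dt = 0.1, T = 350, beta = 2, w_inh = 500,
                        alpha_plus = 1e-3, alpha_minus = 7.5e-4,
                        tau_plus = 20, tau_minus = 20,
                        theta0_offset = 20, alpha_theta_inc = 0.05,
                        tau_theta0 = 1e6, lambda = 1) {
  stopifnot(dt > 0, tau_u > 0, T > 0, beta > 0, t_refrac >= 0,
            tau_plus > 0, tau_minus > 0, tau_theta0 > 0, lambda > 0)
  n_steps <- T / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    abort(sprintf("T = %g ms is not a whole number of dt = %g ms steps", T, dt))
  }
  structure(
    list(tau_u = tau_u, u_r = u_r, u_reset = u_reset, t_refrac = t_refrac,
         dt = dt, T = T, n_steps = as.integer(round(n_steps)), beta = beta,
         w_inh = w_inh, alpha_plus = alpha_plus, alpha_minus = alpha_minus,
         tau_plus = tau_plus, tau_minus = tau_minus,
         theta0_offset = theta0_offset, alpha_theta_inc = alpha_theta_inc,
         tau_theta0 = tau_theta0, lambda = lambda),
    class = "csnn_params"
  )
}

#' @export
print.csnn_params <- function(x, ...) {
  cat("<csnn_params>\n")
  cat(sprintf("  T = %g ms at dt = %g ms (%d steps), tau_u = %g ms\n",
              x$T, x$dt, x$n_steps, x$tau_u))
  cat(sprintf("  beta = %g spikes/ms, w_inh = %g mV, refractory %g ms\n",
              x$beta, x$w_inh, x$t_refrac))
  cat(sprintf("  STDP: +%g/-%g, tau +%g/-%g ms; threshold: offset %g mV, +%g mV/spike, tau %g ms\n",
              x$alpha_plus, x$alpha_minus, x$tau_plus, x$tau_minus,
              x$theta0_offset, x$alpha_theta_inc, x$tau_theta0))
  invisible(x)
}
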