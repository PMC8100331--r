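#' Hyper-parameters for the competitive rate-based algorithm
#'
#' Bundles every tunable of the rate-based competitive learner. Defaults follow
#' the published operating point for unit-scaled inputs: a winner neuron
#' predicted to emit around 30 spikes per 350 ms presentation, weight increments
#' of a few tenths of the per-neuron weight budget, and threshold increments of
#' about 1-2 mV per win.
#'
#' @param m Number of competitive neurons (>= 1).
#' @param n Winners per presentation. Either an integer in `[1, m]` or a
#'   percentage string such as `"5%"`, resolved as `max(1, round(m * pct))`.
#' @param t Presentation time in ms. Only enters through the predicted spike
#'   count `alpha_s * t * rate`.
#' @param lambda Per-neuron total connection weight: every weight column is
#'   renormalized to this sum after each update.
#' @param alpha_s Spike-count scale applied to the rate when predicting how many
#'   spikes a winner would fire.
#' @param alpha_w Weight-update scale (per predicted spike).
#' @param alpha_theta Threshold-update scale in mV per predicted spike.
#' @param theta_0 Initial firing threshold (mV), shared by all neurons.
#' @param theta_r Threshold resting value (mV) toward which thresholds decay.
#' @param tau_theta Threshold decay constant in presentations. Defaults by
#'   network size: 1e5 up to 100 neurons, 1e6 up to 400, 1e7 beyond.
#' @param seed Integer RNG seed controlling weight initialization.
#' @param theta_floor Minimum threshold used as divisor when computing rates,
#'   guarding against thresholds that have decayed to zero or below.
#'
#' @return An object of class `crba_config` (a named list).
#' @examples
#' crba_config(m = 10)
#' crba_config(m = 100, n = "5%")
#' @export
crba_config <- function(m, n = 1, t = 350, lambda = 1, alpha_s = 10,
                        alpha_w = 5e-5, alpha_theta = 0.05,
                        theta_0 = 20, theta_r = -10,
                        tau_theta = default_tau_theta(m),
                        seed = 1L, theta_floor = 1e-3) {
  m <- as.integer(m)
  n <- resolve_winner_count(n, m)
  stopifnot(m >= 1L, t > 0, lambda > 0, tau_theta > 0)
  if (n < 1L || n > m) {
    abort(sprintf("`n` must be in [1, m]; got n = %d with m = %d", n, m))
  }
  if (!(theta_0 > theta_floor) || !(theta_floor > 0)) {
    abort("need theta_0 > theta_floor > 0")
  }
  structure(
    list(m = m, n = n, t = t, lambda = lambda, alpha_s = alpha_s,
         alpha_w = alpha_w, alpha_theta = alpha_theta, theta_0 = theta_0,
         theta_r = theta_r, tau_theta = tau_theta, seed = as.integer(seed),
         theta_floor = theta_floor),
    class = "crba_config"
  )
}

#' Default threshold decay constant for a given network size
#'
#' Larger networks pair with slower threshold decay (1e5 presentations up to
#' 100 neurons, 1e6 up to 400, 1e7 beyond), keeping the homeostatic pressure
#' per neuron roughly constant as competition is spread over more units.
#'
#' @param m Number of neurons.
#' @return A decay constant in presentations.
#' @export
default_tau_theta <- function(m) {
  if (m <= 100) 1e5 else if (m <= 400) 1e6 else 1e7
}

resolve_winner_count <- function(n, m) {
  if (is.character(n)) {
    if (!grepl("^\\s*[0-9.]+\\s*%\\s*$", n)) {
      abort(sprintf("cannot parse winner count '%s'; use an integer or e.g. \"5%%\"", n))
    }
    pct <- as.numeric(sub("%.*$", "", gsub("\\s", "", n))) / 100
    n <- max(1, round(m * pct))
  }
  as.integer(n)
}

#' @export
print.crba_config <- function(x, ...) {
  cat("<crba_config>\n")
  cat(sprintf("  m = %d neurons, n = %d winner(s), t = %g ms\n", x$m, x$n, x$t))
  cat(sprintf("  lambda = %g, alpha_s = %g, alpha_w = %g, alpha_theta = %g\n",
              x$lambda, x$alpha_s, x$alpha_w, x$alpha_theta))
  cat(sprintf("  theta_0 = %g mV, theta_r = %g mV, tau_theta = %g, seed = %d\n",
              x$theta_0, x$theta_r, x$tau_theta, x$seed))
  invisible(x)
}
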