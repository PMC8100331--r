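#' Renormalize synaptic weight columns to a fixed budget
#'
#' Each competitive neuron owns one column of `W`; after any update the column
#' is rescaled so its entries sum to `lambda`, the per-neuron total connection
#' weight. This caps the excitatory drive a neuron can receive and spreads each
#' local increment over all of its synapses.
#'
#' @param W Numeric matrix (features x neurons), all entries `>= 0`.
#' @param lambda Positive column-sum target.
#' @return The rescaled matrix.
#' @export
normalize_columns <- function(W, lambda = 1) {
  s <- colSums(W)
  if (any(s <= 0)) {
    abort(sprintf("degenerate neuron: column(s) %s sum to zero",
                  paste(which(s <= 0), collapse = ", ")))
  }
  sweep(W, 2, lambda / s, `*`)
}

#' Sample-based weight initialization
#'
#' Each neuron's weight column starts as one of the input samples: draws are
#' without replacement until the data set is exhausted, then with replacement.
#' A small constant positive jitter keeps every synapse strictly positive (so
#' no column can normalize to a degenerate state), and columns are then
#' renormalized to sum `lambda`. Starting from actual samples places every
#' neuron inside the data cloud, which cuts the number of presentations needed
#' before neurons specialize.
#'
#' @param data Samples (data frame with numeric feature columns, or matrix),
#'   one per row.
#' @param m Number of neurons.
#' @param lambda Column-sum budget.
#' @param seed RNG seed; the draw sequence is fully determined by it.
#' @param jitter Constant added to every entry before normalization.
#' @return A features x `m` weight matrix with all column sums equal `lambda`.
#' @export
init_weights <- function(data, m, lambda = 1, seed = 1L, jitter = 1e-3) {
  inp <- tryCatch(as_input_matrix(data), error = function(e) {
    abort(paste0("no initialization samples: ", conditionMessage(e)))
  })
  X <- inp$X
  N <- nrow(X)
  set.seed(seed)
  idx <- sample.int(N, min(N, m), replace = FALSE)
  if (m > N) idx <- c(idx, sample.int(N, m - N, replace = TRUE))
  W <- t(X[idx, , drop = FALSE]) + jitter
  normalize_columns(W, lambda)
}

#' Predicted firing rates of all neurons for one input
#'
#' The rate proxy of the competitive model: the dot product between the input
#' and each neuron's weight column, divided by that neuron's current firing
#' threshold. The divisor is clamped below at `theta_floor` so that neurons
#' whose threshold has decayed to zero or below re-enter the competition with a
#' very high rate instead of producing an undefined ratio.
#'
#' @param x Non-negative input vector of length `p`.
#' @param model A fitted or initialized [crba_fit()] model.
#' @return Numeric vector of length `m` of non-negative rates (spikes/ms scale).
#' @export
firing_rates <- function(x, model) {
  stopifnot(inherits(model, "crba"))
  check_dims(x, nrow(model$W))
  rates_for(x, model$W, model$theta, model$config$theta_floor)
}

rates_for <- function(x, W, theta, theta_floor) {
  drop(x %*% W) / pmax(theta, theta_floor)
}

rates_matrix <- function(X, W, theta, theta_floor) {
  R <- X %*% W
  sweep(R, 2, pmax(theta, theta_floor), `/`)
}

#' Select the winner neurons of a presentation
#'
#' Returns the indices of the `n` largest rates in descending rate order. Ties
#' are broken deterministically by lowest index (stable ordering), so repeated
#' runs are exactly reproducible.
#'
#' @param rates Numeric rate vector.
#' @param n Number of winners, `1 <= n <= length(rates)`.
#' @return Integer index vector of length `n`.
#' @export
select_winners <- function(rates, n) {
  if (n > length(rates)) {
    abort(sprintf("n = %d winners requested from %d neurons", n, length(rates)))
  }
  o <- order(-rates, seq_along(rates), method = "radix")
  o[seq_len(n)]
}

#' Rank-dependent winner coefficients
#'
#' Winners beyond the first receive exponentially smaller spike-count
#' coefficients, `c_i = exp(-5 i / n)` for ranks `i = 0, ..., n - 1`, emulating
#' the firing distribution observed in the spiking network under soft lateral
#' inhibition: the first neuron to fire partially suppresses the rest. Rank 0
#' (the top winner) always has coefficient 1, so single-winner runs reduce to
#' plain rate scaling.
#'
#' @param n Number of winners (>= 1).
#' @return Strictly decreasing positive vector of length `n`, starting at 1.
#' @export
winner_coefficients <- function(n) {
  if (n < 1) abort("need at least one winner")
  exp(-5 * (seq_len(n) - 1) / n)
}

#' Predicted spike counts for the winner neurons
#'
#' The number of spikes winner `k` would fire during a presentation of length
#' `t`: `alpha_s * t * rate * c_k`. Counts are kept real-valued; they only ever
#' act as multiplicative scales on the weight and threshold updates.
#'
#' @param rates Full rate vector.
#' @param winners Winner indices (from [select_winners()]).
#' @param config A [crba_config()].
#' @return Non-negative numeric vector aligned with `winners`.
#' @export
predicted_spikes <- function(rates, winners, config) {
  stopifnot(all(winners >= 1), all(winners <= length(rates)))
  config$alpha_s * config$t * rates[winners] * winner_coefficients(length(winners))
}

#' Apply the discrete-EM weight update to the winner columns
#'
#' Each winner column moves toward the presented input, `W_j <- W_j +
#' alpha_w * spikes_j * x`, and is immediately renormalized to sum `lambda`.
#' The renormalization supplies the contraction that makes the sequence of
#' updates track the mean of the samples a neuron wins, so each neuron's
#' column converges to (a scaled copy of) its cluster centroid. Non-winner
#' columns are untouched.
#'
#' @param model A `crba` model.
#' @param x Input vector.
#' @param winners Winner indices.
#' @param spikes Predicted spike counts aligned with `winners`.
#' @param config A [crba_config()]; defaults to the model's own.
#' @return The model with updated weights.
#' @export
update_winner_weights <- function(model, x, winners, spikes,
                                  config = model$config) {
  stopifnot(length(winners) == length(spikes))
  W <- model$W
  for (k in seq_along(winners)) {
    j <- winners[k]
    col <- W[, j] + config$alpha_w * spikes[k] * x
    s <- sum(col)
    if (s <= 0) abort(sprintf("degenerate neuron: column %d sums to zero", j))
    W[, j] <- col * (config$lambda / s)
  }
  model$W <- W
  model
}

#' Homeostatic threshold update
#'
#' Winner thresholds jump by `alpha_theta` per predicted spike, then all
#' thresholds take one discrete decay step toward the resting value:
#' `theta <- theta + (theta_r - theta) / tau_theta`. The jump penalizes neurons
#' that keep winning; the slow decay lets neurons that never win drift down
#' until their rate is high enough to compete again.
#'
#' @param theta Current threshold vector (mV).
#' @param winners Winner indices.
#' @param spikes Predicted spike counts aligned with `winners`.
#' @param config A [crba_config()].
#' @return Updated threshold vector.
#' @export
update_thresholds <- function(theta, winners, spikes, config) {
  stopifnot(length(winners) == length(spikes))
  theta[winners] <- theta[winners] + config$alpha_theta * spikes
  theta + (config$theta_r - theta) / config$tau_theta
}

#' Fit the competitive rate-based model
#'
#' Runs the one-pass competitive loop: for each presented sample, compute
#' rates, select winners, predict their spike counts, move the winner columns
#' toward the sample (with renormalization) and update the thresholds. Samples
#' are presented strictly sequentially in data order; if `presentations`
#' exceeds the number of rows the data set is cycled. The whole run is
#' deterministic given the configuration seed and the sample order.
#'
#' @param data Training samples: data frame (numeric feature columns; a
#'   `class` column, if present, is ignored during fitting) or matrix. May be
#'   omitted only when `W0` is given and `presentations = 0`.
#' @param config A [crba_config()].
#' @param W0 Optional initial weight matrix (features x `m`, column sums
#'   `lambda`); defaults to sample-based initialization.
#' @param presentations Number of sample presentations; defaults to one pass
#'   over `data`.
#' @param metrics_every Window length (in presentations) for the logged
#'   progress metrics.
#' @param verbose Print a line per metrics window.
#' @return An object of class `crba`: weights `W`, thresholds `theta`, the
#'   configuration, per-neuron win counts and a tibble of windowed metrics
#'   (mean/min/max threshold, mean top-winner predicted spikes).
#' @examples
#' d <- make_synthetic(k = 2, p = 16, per_class = 20, seed = 1)
#' fit <- crba_fit(d, crba_config(m = 2, seed = 1), presentations = 200)
#' fit
#' @export
crba_fit <- function(data = NULL, config, W0 = NULL, presentations = NULL,
                     metrics_every = 10000L, verbose = FALSE) {
  stopifnot(inherits(config, "crba_config"))
  have_data <- !is.null(data)
  if (!have_data && is.null(W0)) abort("no training data and no initial weights W0")
  X <- if (have_data) as_input_matrix(data)$X else NULL
  if (is.null(presentations)) presentations <- if (have_data) nrow(X) else 0L
  presentations <- as.integer(presentations)
  if (presentations > 0 && !have_data) {
    abort("presentations > 0 requires training data")
  }

  if (is.null(W0)) {
    W <- init_weights(X, config$m, config$lambda, seed = config$seed)
  } else {
    W <- as.matrix(W0)
    if (ncol(W) != config$m) abort("W0 must have one column per neuron")
    W <- normalize_columns(W, config$lambda)
  }
  theta <- rep(config$theta_0, config$m)
  Cn <- winner_coefficients(config$n)
  a_st <- config$alpha_s * config$t
  wins <- integer(config$m)

  n_win <- if (presentations > 0) ceiling(presentations / metrics_every) else 0L
  mlog <- vector("list", n_win)
  acc_theta <- 0; acc_spk <- 0; acc_n <- 0L; widx <- 0L
  N <- if (have_data) nrow(X) else 0L

  for (i in seq_len(presentations)) {
    x <- X[((i - 1L) %% N) + 1L, ]
    r <- drop(x %*% W) / pmax(theta, config$theta_floor)
    winners <- select_winners(r, config$n)
    spikes <- a_st * r[winners] * Cn
    for (k in seq_along(winners)) {
      j <- winners[k]
      col <- W[, j] + config$alpha_w * spikes[k] * x
      s <- sum(col)
      if (s <= 0) abort(sprintf("degenerate neuron: column %d sums to zero", j))
      W[, j] <- col * (config$lambda / s)
    }
    theta[winners] <- theta[winners] + config$alpha_theta * spikes
    theta <- theta + (config$theta_r - theta) / config$tau_theta
    wins[winners[1L]] <- wins[winners[1L]] + 1L

    acc_theta <- acc_theta + mean(theta)
    acc_spk <- acc_spk + spikes[1L]
    acc_n <- acc_n + 1L
    if (acc_n == metrics_every || i == presentations) {
      widx <- widx + 1L
      mlog[[widx]] <- c(presentation = i,
                        mean_theta = acc_theta / acc_n,
                        min_theta = min(theta), max_theta = max(theta),
                        mean_winner_spikes = acc_spk / acc_n)
      if (verbose) {
        inform(sprintf("presentation %d: mean theta %.2f mV, mean winner spikes %.2f",
                       i, acc_theta / acc_n, acc_spk / acc_n))
      }
      acc_theta <- 0; acc_spk <- 0; acc_n <- 0L
    }
  }

  metrics <- if (widx > 0) {
    tibble::as_tibble(do.call(rbind, mlog[seq_len(widx)]))
  } else {
    tibble::tibble(presentation = numeric(), mean_theta = numeric(),
                   min_theta = numeric(), max_theta = numeric(),
                   mean_winner_spikes = numeric())
  }

  structure(
    list(W = W, theta = theta, config = config, presentations = presentations,
         win_counts = wins, metrics = metrics, labeling = NULL),
    class = "crba"
  )
}

#' @export
print.crba <- function(x, ...) {
  cat(sprintf("<crba model: %d neurons, %d features, %d presentation(s)>\n",
              ncol(x$W), nrow(x$W), x$presentations))
  cat(sprintf("  thresholds: %.3g .. %.3g mV (mean %.3g)\n",
              min(x$theta), max(x$theta), mean(x$theta)))
  cat(if (is.null(x$labeling)) "  unlabeled\n"
      else sprintf("  labeled over %d classes\n", length(x$labeling$classes)))
  invisible(x)
}

#' Batch discrete-EM update
#'
#' With unit variance and 0/1 posteriors, the EM mean update for one neuron
#' reduces to the arithmetic mean of the samples assigned to it — the K-means
#' centroid step.
#'
#' @param samples Assigned samples: data frame or matrix, one sample per row.
#' @return The mean vector.
#' @export
batch_em_update <- function(samples) {
  X <- as_input_matrix(samples)$X
  colMeans(X)
}

#' Sequential (stochastic-approximation) EM update
#'
#' One online step of the discrete EM mean update: `mu + step * (x - mu)`.
#' With the harmonic step sequence `step_k = 1/k` the iterates telescope into
#' the exact running mean, so a full pass reproduces [batch_em_update()] to
#' machine precision.
#'
#' @param mu Current mean estimate.
#' @param x New sample.
#' @param step Step size in `(0, 1]`.
#' @return Updated mean estimate.
#' @seealso [sequential_em()] for a full pass with harmonic steps.
#' @export
sequential_em_update <- function(mu, x, step) {
  stopifnot(length(mu) == length(x), step > 0)
  mu + step * (x - mu)
}

#' Full sequential EM pass with harmonic steps
#'
#' @param samples Data frame or matrix of assigned samples.
#' @return The resulting mean vector (equal to the batch mean).
#' @export
sequential_em <- function(samples) {
  X <- as_input_matrix(samples)$X
  mu <- X[1L, ]
  for (k in seq_len(nrow(X))[-1L]) {
    mu <- sequential_em_update(mu, X[k, ], 1 / k)
  }
  mu
}
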