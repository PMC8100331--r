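# Shared fixtures, all built in code at test time.

# Minimal model wrapper around explicit weights/thresholds.
toy_model <- function(W, theta, config = crba_config(m = ncol(W))) {
  structure(list(W = W, theta = theta, config = config,
                 presentations = 0L, win_counts = integer(ncol(W)),
                 metrics = tibble::tibble(), labeling = NULL),
            class = "crba")
}

# Two well-separated clusters with orthogonal prototype supports.
two_cluster_data <- function(n_per = 100, p = 16, noise = 0.05, seed = 1) {
  set.seed(seed)
  pa <- c(rep(0.8, p / 2), rep(0, p / 2))
  pb <- c(rep(0, p / 2), rep(0.8, p / 2))
  X <- rbind(matrix(pa, n_per, p, byrow = TRUE),
             matrix(pb, n_per, p, byrow = TRUE)) +
    matrix(abs(rnorm(2 * n_per * p, 0, noise)), 2 * n_per, p)
  X <- pmin(X, 1)
  cls <- rep(0:1, each = n_per)
  ord <- sample(2 * n_per)
  d <- tibble::as_tibble(as.data.frame(X[ord, ]), .name_repair = "minimal")
  names(d) <- paste0("x", seq_len(p))
  d$class <- cls[ord]
  list(data = d, proto = rbind(pa, pb))
}

# Write a tiny valid IDX image/label pair with known bytes; returns paths and
# the expected feature matrix.
write_idx_fixture <- function(dir, n = 2, rows = 2, cols = 2,
                              pixels = c(0L, 128L, 255L, 64L,
                                         10L, 20L, 30L, 40L),
                              labels = c(7L, 3L)) {
  img <- file.path(dir, "images.idx")
  lab <- file.path(dir, "labels.idx")
  con <- file(img, "wb")
  writeBin(as.integer(c(2051L, n, rows, cols)), con, size = 4, endian = "big")
  writeBin(as.raw(pixels), con)
  close(con)
  con <- file(lab, "wb")
  writeBin(as.integer(c(2049L, length(labels))), con, size = 4, endian = "big")
  writeBin(as.raw(labels), con)
  close(con)
  list(images = img, labels = lab,
       X = matrix(pixels / 255, nrow = n, byrow = TRUE), labels_expected = labels)
}

# Parameters used by the closed-form validation instances: dense regular
# drive (every channel delivers at least one spike per step) so the
# constant-rate closed forms apply at sub-step resolution.
closed_form_params <- function() {
  csnn_params(tau_u = 100, beta = 20, dt = 0.1, T = 350,
              alpha_theta_inc = 0, tau_theta0 = Inf, w_inh = 0)
}

rel_err <- function(a, b) abs(a - b) / abs(b)

# All distinct arrangements of a small vector, for exhaustive tie-rule checks.
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Rate matrix for a sample block against a fitted model.
rates_for_test <- function(X, model) {
  sweep(X %*% model$W, 2, pmax(model$theta, model$config$theta_floor), "/")
}
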