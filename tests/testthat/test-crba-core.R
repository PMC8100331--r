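test_that("sample-based initialization normalizes, is deterministic, and recycles samples", {
  # single sample, single neuron: normalization forces the equal split
  W <- init_weights(matrix(c(2, 2), 1, 2), m = 1, lambda = 1, seed = 1)
  expect_equal(as.vector(W), c(0.5, 0.5))

  set.seed(99)
  X <- matrix(runif(10 * 6), 10, 6)
  W3 <- init_weights(X, m = 3, lambda = 1, seed = 7)
  expect_equal(colSums(W3), rep(1, 3))
  expect_equal(nrow(unique(t(W3))), 3)  # three distinct columns
  expect_identical(W3, init_weights(X, m = 3, lambda = 1, seed = 7))

  # m > N: the draw order is without replacement first, then with replacement
  W20 <- init_weights(X, m = 20, lambda = 2, seed = 5, jitter = 1e-3)
  expect_equal(colSums(W20), rep(2, 20), tolerance = 1e-12)
  set.seed(5)
  idx <- c(sample.int(10, 10, replace = FALSE), sample.int(10, 10, replace = TRUE))
  expected <- normalize_columns(t(X[idx, ]) + 1e-3, 2)
  expect_identical(W20, expected)

  expect_error(init_weights(data.frame(), 2), "no initialization samples")
})

test_that("firing rates are threshold-scaled dot products with a clamped divisor", {
  cfg <- crba_config(m = 2)
  model <- toy_model(diag(2), c(20, 20), cfg)
  expect_equal(firing_rates(c(0, 0), model), c(0, 0))
  expect_equal(firing_rates(c(0.8, 0.2), model), c(0.04, 0.01))
  expect_error(firing_rates(c(1, 2, 3), model), "dimension mismatch")

  # uniform thresholds: ranking identical to ranking by raw dot product
  set.seed(1)
  for (i in 1:20) {
    p <- sample(2:5, 1); m <- sample(2:6, 1)
    W <- matrix(runif(p * m), p, m)
    x <- runif(p)
    mdl <- toy_model(W, rep(17, m), crba_config(m = m))
    expect_identical(order(-firing_rates(x, mdl)), order(-drop(x %*% W)))
  }

  # non-positive thresholds fall back to the floor instead of flipping sign
  mdl <- toy_model(diag(2), c(-5, 20), crba_config(m = 2, theta_floor = 1e-3))
  r <- firing_rates(c(1, 1), mdl)
  expect_true(all(is.finite(r)) && all(r >= 0))
  expect_equal(r[1], 1 / 1e-3)
})

test_that("winner selection is stable with exhaustive tie-breaking by lowest index", {
  expect_identical(select_winners(c(0.1, 0.5, 0.2), 1), 2L)
  expect_error(select_winners(c(1, 2), 3), "3 winners")

  # every arrangement of a tied multiset against a brute-force oracle
  vals <- c(0.3, 0.3, 0.1)
  perms <- unique(combinat_perms(vals))
  for (r in perms) {
    oracle <- order(-r, seq_along(r))[1:2]
    expect_identical(select_winners(r, 2), as.integer(oracle))
  }
  expect_identical(select_winners(c(0.3, 0.3, 0.1), 2), c(1L, 2L))

  # n = m returns a permutation sorting rates descending
  set.seed(2)
  r <- runif(6)
  w <- select_winners(r, 6)
  expect_identical(sort(w), 1:6)
  expect_true(all(diff(r[w]) <= 0))
})

test_that("winner coefficients decay from 1 with rank", {
  expect_equal(winner_coefficients(1), 1.0)
  expect_equal(winner_coefficients(3), c(1, exp(-5 / 3), exp(-10 / 3)))
  expect_equal(winner_coefficients(3)[2:3], c(0.1889, 0.0357), tolerance = 1e-3)
  for (n in c(1, 2, 5, 12)) {
    cc <- winner_coefficients(n)
    expect_equal(cc[1], 1.0)     # top winner keeps its full rate
    expect_true(all(cc > 0) && all(diff(cc) < 0 | n == 1))
  }
  expect_error(winner_coefficients(0), "at least one")
})

test_that("predicted spike counts scale rate by time and rank coefficient", {
  cfg <- crba_config(m = 3, n = 1)
  expect_equal(predicted_spikes(c(0, 0, 0), 1L, cfg), 0)
  expect_equal(predicted_spikes(c(0.01, 0, 0), 1L, cfg), 35)  # 10 * 350 * 0.01

  # at the published operating point (winner dot product giving ~30 spikes at
  # theta_0 = 20 mV) the count lands in the designed 10-60 band
  dot <- 0.171
  rate <- dot / cfg$theta_0
  spk <- predicted_spikes(c(rate, 0, 0), 1L, cfg)
  expect_gt(spk, 10); expect_lt(spk, 60)
  expect_equal(spk, 29.925, tolerance = 1e-9)
})

test_that("weight update pulls the winner toward the input under renormalization", {
  cfg <- crba_config(m = 2, alpha_w = 0)
  model <- toy_model(matrix(0.5, 2, 2), c(20, 20), cfg)
  out <- update_winner_weights(model, c(1, 0), 1L, 10, cfg)
  expect_identical(out$W, model$W)  # alpha_w = 0: normalization is idempotent

  cfg1 <- crba_config(m = 2, alpha_w = 1)
  m1 <- toy_model(matrix(0.5, 2, 2), c(20, 20), cfg1)
  out1 <- update_winner_weights(m1, c(1, 0), 1L, 1, cfg1)
  expect_equal(out1$W[, 1], c(0.75, 0.25))   # (1.5, 0.5) renormalized
  expect_equal(out1$W[, 2], c(0.5, 0.5))     # non-winner untouched

  # repeated presentation drives the winner column toward x monotonically
  x <- c(0.9, 0.05, 0.4, 0)
  cfg2 <- crba_config(m = 1, alpha_w = 5e-3)
  mdl <- toy_model(matrix(0.25, 4, 1), 20, cfg2)
  cosines <- numeric(30)
  for (i in 1:30) {
    mdl <- update_winner_weights(mdl, x, 1L, 30, cfg2)
    cosines[i] <- sum(mdl$W[, 1] * x) / sqrt(sum(mdl$W[, 1]^2) * sum(x^2))
  }
  expect_true(all(diff(cosines) > -1e-12))
  expect_gt(cosines[30], 0.999)

  bad <- toy_model(matrix(c(0, 0, 1, 1), 2, 2), c(20, 20), cfg1)
  expect_error(update_winner_weights(bad, c(0, 0), 1L, 1, cfg1), "degenerate neuron")
})

test_that("threshold update: winner jump, then one global decay step", {
  cfg <- crba_config(m = 3, alpha_theta = 0.05, theta_r = -10, tau_theta = 1e5)
  th <- update_thresholds(c(20, 20, 20), 1L, 35, cfg)
  expect_equal(th[1], 21.75 + (-10 - 21.75) / 1e5)  # 21.7496825
  expect_equal(th[1], 21.7496825)
  expect_equal(th[2], 20 + (-10 - 20) / 1e5)

  # infinite decay constant and zero spikes leave thresholds untouched
  cfg_inf <- crba_config(m = 2, tau_theta = Inf)
  expect_identical(update_thresholds(c(20, 30), 1L, 0, cfg_inf), c(20, 30))

  # a neuron that never wins relaxes monotonically toward theta_r
  cfg2 <- crba_config(m = 2, tau_theta = 50)
  th <- c(20, 20)
  prev <- th[2]
  for (i in 1:200) {
    th <- update_thresholds(th, 1L, 1, cfg2)
    expect_lt(th[2], prev)
    prev <- th[2]
  }
  expect_equal(prev, -10, tolerance = 0.6)
})

test_that("discrete EM: batch mean and telescoping sequential pass agree", {
  expect_equal(batch_em_update(matrix(c(0.3, 0.7), 1, 2)), c(0.3, 0.7))
  expect_equal(batch_em_update(rbind(c(0, 1), c(1, 0))), c(0.5, 0.5))
  expect_error(batch_em_update(data.frame()), "no rows")

  set.seed(3)
  for (i in 1:10) {
    X <- matrix(runif(sample(2:40, 1) * 5), ncol = 5)
    expect_equal(sequential_em(X), batch_em_update(X), tolerance = 1e-14)
  }
})

test_that("fit runs the sequential loop deterministically and conserves column sums", {
  tc <- two_cluster_data(n_per = 50, seed = 11)
  cfg <- crba_config(m = 2, seed = 4)

  f0 <- crba_fit(NULL, cfg, W0 = matrix(c(1, 3, 2, 2), 2, 2), presentations = 0)
  expect_equal(f0$W, matrix(c(0.25, 0.75, 0.5, 0.5), 2, 2))
  expect_equal(f0$theta, c(20, 20))
  expect_error(crba_fit(NULL, cfg), "no training data")

  f1 <- crba_fit(tc$data, cfg, presentations = 4000, metrics_every = 1000)
  f2 <- crba_fit(tc$data, cfg, presentations = 4000, metrics_every = 1000)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$theta, f2$theta)
  expect_equal(colSums(f1$W), rep(1, 2), tolerance = 1e-9)
  expect_equal(nrow(f1$metrics), 4)

  # two orthogonal prototypes, one winner: bijective assignment, high cosine
  cosm <- sapply(1:2, function(k) apply(f1$W, 2, function(w)
    sum(w * tc$proto[k, ]) / sqrt(sum(w^2) * sum(tc$proto[k, ]^2))))
  best <- apply(cosm, 1, which.max)
  expect_setequal(best, 1:2)
  expect_true(all(apply(cosm, 1, max) > 0.95))
})

test_that("single-winner locality: one presentation touches one column and one jump", {
  set.seed(8)
  W <- normalize_columns(matrix(runif(8 * 4), 8, 4), 1)
  cfg <- crba_config(m = 4, n = 1, tau_theta = Inf)
  x <- runif(8)
  model <- toy_model(W, rep(20, 4), cfg)
  r <- firing_rates(x, model)
  win <- select_winners(r, 1)
  spk <- predicted_spikes(r, win, cfg)
  after <- update_winner_weights(model, x, win, spk, cfg)
  changed <- which(colSums(abs(after$W - W)) > 0)
  expect_identical(changed, win)
  th <- update_thresholds(model$theta, win, spk, cfg)
  expect_identical(which(th != 20), win)
})

test_that("homeostasis: a winning streak on a fixed input has strictly decreasing rate", {
  x <- c(0.8, 0.6, 0.1, 0)
  cfg <- crba_config(m = 2, n = 1)
  mdl <- toy_model(normalize_columns(cbind(x + 0.01, rev(x) + 0.01), 1),
                   c(20, 20), cfg)
  rates <- numeric(60)
  for (i in 1:60) {
    r <- firing_rates(x, mdl)
    win <- select_winners(r, 1)
    expect_identical(win, 1L)   # same neuron keeps winning
    rates[i] <- r[win]
    spk <- predicted_spikes(r, win, cfg)
    mdl <- update_winner_weights(mdl, x, win, spk, cfg)
    mdl$theta <- update_thresholds(mdl$theta, win, spk, cfg)
  }
  expect_true(all(diff(rates) < 0))
})

test_that("winner-count shorthand resolves percentages against m", {
  expect_identical(crba_config(m = 100, n = "5%")$n, 5L)
  expect_identical(crba_config(m = 100, n = "1%")$n, 1L)
  expect_identical(crba_config(m = 10, n = "1%")$n, 1L)   # floor at one winner
  expect_error(crba_config(m = 10, n = 11), "must be in")
  expect_error(crba_config(m = 10, n = "x%"), "cannot parse")
})
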