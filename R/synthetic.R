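#' Generate a synthetic clustered data set
#'
#' Emulates the statistical structure the competitive learner assumes: each
#' class is a cluster of non-negative intensity vectors around a sparse
#' prototype, with bounded within-class noise — an idealized stand-in for
#' image data where each class concentrates around a template. Prototypes are
#' drawn by rejection sampling until every pair is at least `separation` apart
#' in cosine distance; samples add truncated Gaussian noise and are clipped to
#' `[0, 1]`.
#'
#' @param k Number of clusters/classes (>= 2).
#' @param p Feature dimension.
#' @param per_class Samples per cluster.
#' @param prototype_sparsity Fraction of active (non-zero) prototype entries.
#' @param noise_sd Within-cluster noise standard deviation before clipping.
#' @param separation Minimum pairwise prototype cosine distance
#'   (`1 - cosine similarity`) required of the drawn prototypes.
#' @param seed RNG seed; identical spec + seed gives an identical data set.
#' @return A tibble with feature columns `x1..xp` in `[0, 1]` and an integer
#'   `class` column with values `0..k-1`, rows in shuffled order. The drawn
#'   prototypes (a `k x p` matrix) are attached as attribute `"prototypes"`,
#'   and `"source" = "synthetic"`.
#' @examples
#' d <- make_synthetic(k = 3, p = 20, per_class = 5, seed = 42)
#' dplyr::count(d, class)
#' @export
make_synthetic <- function(k = 10, p = 196, per_class = 500,
                           prototype_sparsity = 0.15, noise_sd = 0.05,
                           separation = 0.5, seed = 1L) {
  stopifnot(k >= 2, per_class >= 1, p >= 2,
            prototype_sparsity > 0, prototype_sparsity <= 1,
            noise_sd >= 0, separation >= 0, separation < 2)
  set.seed(seed)
  n_active <- max(1L, round(prototype_sparsity * p))

  draw_proto <- function() {
    proto <- numeric(p)
    proto[sample.int(p, n_active)] <- runif(n_active, 0.3, 1)
    proto
  }
  min_cos_dist <- function(P) {
    S <- tcrossprod(P / sqrt(rowSums(P^2)))
    1 - max(S[upper.tri(S)])
  }
  P <- NULL
  for (round in seq_len(1000L)) {
    cand <- do.call(rbind, replicate(k, draw_proto(), simplify = FALSE))
    if (min_cos_dist(cand) >= separation) { P <- cand; break }
  }
  if (is.null(P)) {
    abort(sprintf("infeasible separation: %g not reached in 1000 rejection rounds",
                  separation))
  }

  n <- k * per_class
  cls <- rep(0:(k - 1), each = per_class)
  X <- P[cls + 1L, , drop = FALSE] +
    matrix(rnorm(n * p, sd = noise_sd), n, p)
  X <- pmin(pmax(X, 0), 1)
  ord <- sample.int(n)

  out <- tibble::as_tibble(as.data.frame(X[ord, , drop = FALSE]),
                           .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(p))
  out$class <- as.integer(cls[ord])
  attr(out, "prototypes") <- P
  attr(out, "source") <- "synthetic"
  attr(out, "scale_max") <- 1
  out
}
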