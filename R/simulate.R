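# Gaussian-cluster benchmark simulator. Cluster centers sit on a ring of
# radius alpha in a random 2-plane of P-dimensional space: center j is
# alpha * (cos(2*pi*j/k), sin(2*pi*j/k)) mapped through a seeded random
# orthonormal P x 2 embedding, so adjacent centers are exactly
# 2 * alpha * sin(pi/k) apart regardless of P. Each sample is its center
# plus isotropic Gaussian noise with standard deviation sigma per feature.

#' Simulate Gaussian clusters with controlled spacing, size and variance
#'
#' @param k Number of clusters (`>= 1`).
#' @param n Samples per cluster (`>= 1`).
#' @param P Feature dimension (`>= 2`).
#' @param alpha Inter-cluster spacing: radius of the ring the cluster
#'   centers are placed on (unitless; `alpha = 0` collapses all centers to
#'   the origin, a single Gaussian blob).
#' @param sigma Per-feature Gaussian noise standard deviation (`> 0`,
#'   default 0.025).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A list of class `resoclust_simulation`: `X` (`k*n x P` matrix,
#'   rows named `S1..`), `labels` (tibble `id`, `label` with ground-truth
#'   cluster ids `G1..Gk`), `centers` (`k x P`), and `params`.
#' @export
simulate_clusters <- function(k, n, P, alpha, sigma = 0.025, seed = 42) {
  if (!(is.numeric(k) && length(k) == 1 && k >= 1)) stop("invalid k", call. = FALSE)
  if (!(is.numeric(n) && length(n) == 1 && n >= 1)) stop("invalid n", call. = FALSE)
  if (!(is.numeric(P) && length(P) == 1 && P >= 2)) stop("invalid P", call. = FALSE)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0)) stop("invalid alpha", call. = FALSE)
  if (!(is.numeric(sigma) && length(sigma) == 1 && sigma > 0)) stop("invalid sigma", call. = FALSE)
  k <- as.integer(k); n <- as.integer(n); P <- as.integer(P)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  # seeded random orthonormal 2-plane in P dimensions
  Q <- qr.Q(qr(matrix(stats::rnorm(P * 2L), P, 2L)))          # P x 2
  theta <- 2 * pi * (seq_len(k) - 1L) / k
  centers2 <- alpha * cbind(cos(theta), sin(theta))           # k x 2
  centers <- centers2 %*% t(Q)                                # k x P

  lab <- rep(seq_len(k), each = n)
  X <- centers[lab, , drop = FALSE] +
    matrix(stats::rnorm(k * n * P, sd = sigma), k * n, P)
  rownames(X) <- paste0("S", seq_len(k * n))
  colnames(X) <- paste0("F", seq_len(P))

  structure(list(
    X = X,
    labels = tibble::tibble(id = rownames(X), label = paste0("G", lab)),
    centers = centers,
    params = list(k = k, n = n, P = P, alpha = alpha, sigma = sigma,
                  seed = as.integer(seed))
  ), class = "resoclust_simulation")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The full synthetic benchmark parameter grid
#'
#' Cartesian grid of cluster count `k` in {4, 6, 8}, per-cluster sample size
#' `n` in {10, 20, 40}, feature dimension `P` in {500, 1000, 1500} and
#' spacing `alpha` in {0.05, 0.1, 0.25, 0.5, 1} — 135 configurations. Grid
#' entry `i` gets seed `base_seed + i`.
#'
#' @param sigma Noise standard deviation shared by all configurations
#'   (default 0.025).
#' @param base_seed Base of the per-configuration seeds (default 42).
#' @return A tibble with 135 rows: `config`, `k`, `n`, `P`, `alpha`,
#'   `sigma`, `seed`.
#' @export
benchmark_grid <- function(sigma = 0.025, base_seed = 42) {
  g <- tidyr::expand_grid(k = c(4L, 6L, 8L), n = c(10L, 20L, 40L),
                          P = c(500L, 1000L, 1500L),
                          alpha = c(0.05, 0.1, 0.25, 0.5, 1))
  g$sigma <- sigma
  g$seed <- base_seed + seq_len(nrow(g))
  dplyr::bind_cols(tibble::tibble(config = seq_len(nrow(g))), g)
}

#' Pairwise Euclidean distances of a data matrix
#'
#' Bridges a simulated (or any) sample-by-feature matrix to the detector.
#'
#' @param X Numeric matrix with at least 2 rows; row names become ids
#'   (defaults to `S1..Sn`).
#' @return A validated distance matrix.
#' @export
euclidean_distances <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("data matrix has non-finite entries", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 rows", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  validate_distance_matrix(as.matrix(dist(X, method = "euclidean")))
}
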