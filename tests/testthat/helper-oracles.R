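# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately use the most naive formulation available (explicit
# loops over pairs, direct entropy sums) so they stay independent of the
# package's implementation paths.

# Two well-separated triplets: within-triplet distance 0.1, across 1.0.
toy_two_triplets <- function() {
  m <- matrix(1.0, 6, 6)
  m[1:3, 1:3] <- 0.1
  m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("p", 1:6)
  m
}

# A random valid distance matrix: either a Euclidean cloud or an arbitrary
# symmetric nonnegative matrix with zero diagonal.
random_distance_matrix <- function(n, euclidean = TRUE) {
  if (euclidean) {
    X <- matrix(rnorm(n * 3), n, 3)
    m <- as.matrix(dist(X))
  } else {
    m <- matrix(runif(n * n, 0.05, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
  }
  rownames(m) <- colnames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# Exhaustive pair-enumeration oracle for the co-membership counts.
brute_pair_counts <- function(predicted, truth) {
  n <- length(predicted)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- predicted[i] == predicted[j]
    t <- truth[i] == truth[j]
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Index values straight from the enumerated counts.
brute_indices <- function(predicted, truth) {
  pc <- brute_pair_counts(predicted, truth)
  jac <- if (pc$TP + pc$FP + pc$FN == 0) 0 else pc$TP / (pc$TP + pc$FP + pc$FN)
  fm <- if ((pc$TP + pc$FP) * (pc$TP + pc$FN) == 0) 0 else
    pc$TP / sqrt((pc$TP + pc$FP) * (pc$TP + pc$FN))
  f1 <- if (2 * pc$TP + pc$FP + pc$FN == 0) 0 else
    2 * pc$TP / (2 * pc$TP + pc$FP + pc$FN)
  list(jaccard = jac, fm = fm, f1 = f1)
}

# Plug-in NMI oracle by direct summation over the observed joint table.
brute_nmi <- function(x, y) {
  n <- length(x)
  h <- function(v) {
    p <- table(v) / length(v)
    p <- as.numeric(p[p > 0])
    -sum(p * log(p))
  }
  hx <- h(x); hy <- h(y)
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  mi <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  mi / sqrt(hx * hy)
}

# Naive double-loop Euclidean distances.
brute_euclidean <- function(X) {
  n <- nrow(X)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  m
}

# Recursively check that every internal node's leaf set is the disjoint
# union of its children's leaf sets.
check_leafset_partition <- function(H) {
  for (v in seq_along(H$height)) {
    l <- H$left[v]
    if (l == 0L) next
    r <- H$right[v]
    a <- H$members[[l]]; b <- H$members[[r]]
    if (length(intersect(a, b)) != 0) return(FALSE)
    if (!setequal(c(a, b), H$members[[v]])) return(FALSE)
  }
  TRUE
}
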