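test_that("branch_score follows the binary-silhouette formula", {
  m <- matrix(1.0, 4, 4); m[1:2, 1:2] <- 0.1; m[3:4, 3:4] <- 0.1; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("q", 1:4)
  # each member: a = 0.1, b = 1.0, s = (1.0 - 0.1)/1.0 = 0.9
  expect_equal(branch_score(1:2, 3:4, m), 0.9)
  expect_equal(branch_score(1L, 2:4, m), 0)        # singleton convention
  eq <- matrix(0.5, 4, 4); diag(eq) <- 0
  expect_equal(branch_score(1:2, 3:4, eq), 0)      # a = b everywhere
  expect_error(branch_score(1:2, 2:3, m), "overlap")
})

test_that("node scores on the toy match the hand trace; root and leaves are 0", {
  m <- toy_two_triplets()
  H <- build_hierarchy(m)
  sc <- node_scores(H, m)
  expect_true(all(sc >= -1 & sc <= 1))
  expect_equal(sc[H$root], 0)
  expect_equal(sc[1:6], rep(0, 6))                 # leaves
  triplet_nodes <- which(lengths(H$members) == 3)
  expect_equal(sc[triplet_nodes], c(0.9, 0.9))
})

test_that("toy detection emits exactly the two triplets", {
  m <- toy_two_triplets()
  fit <- detect_communities(build_hierarchy(m), m)
  expect_equal(nrow(fit$communities), 2L)
  expect_setequal(fit$communities$members,
                  list(c("p1", "p2", "p3"), c("p4", "p5", "p6")))
  expect_identical(sort(unique(fit$assignment$community)), c("C1", "C2"))
})

test_that("structureless and limit inputs degenerate to singletons", {
  eq <- matrix(0.3, 8, 8); diag(eq) <- 0
  rownames(eq) <- colnames(eq) <- paste0("s", 1:8)
  fit <- detect_communities(build_hierarchy(eq), eq)
  expect_equal(nrow(fit$communities), 8L)
  expect_true(all(fit$communities$size == 1L))

  m <- toy_two_triplets()
  hi <- detect_communities(build_hierarchy(m), m, resolution = "high", delta = 2)
  expect_equal(nrow(hi$communities), 6L)           # delta > max score
})

test_that("detected communities always partition the ids and scores stay bounded", {
  set.seed(7)
  linkages <- c("single", "average", "complete", "weighted", "ward")
  for (rep in 1:12) {
    n <- sample(5:30, 1)
    m <- random_distance_matrix(n, euclidean = rep %% 2 == 0)
    fit <- detect_communities(build_hierarchy(m, linkages[1 + rep %% 5]), m)
    ids <- sort(unlist(fit$communities$members))
    expect_identical(ids, sort(rownames(m)))
    expect_equal(sum(fit$communities$size), n)
    expect_true(all(fit$scores >= -1 & fit$scores <= 1))
    expect_false(any(fit$assignment$community == ""))
  }
})

test_that("high resolution never yields fewer communities than low", {
  set.seed(19)
  for (rep in 1:8) {
    m <- random_distance_matrix(sample(8:25, 1), euclidean = TRUE)
    H <- build_hierarchy(m)
    lo <- detect_communities(H, m, resolution = "low")
    hi <- detect_communities(H, m, resolution = "high", delta = 0.05)
    expect_gte(nrow(hi$communities), nrow(lo$communities))
  }
})

test_that("well-separated simulated clusters are recovered regardless of linkage", {
  sim <- simulate_clusters(k = 4, n = 10, P = 200, alpha = 1,
                           sigma = 0.05, seed = 3)
  D <- euclidean_distances(sim$X)
  for (method in c("complete", "average", "ward")) {
    fit <- detect_communities(build_hierarchy(D, method), D)
    expect_equal(adjusted_rand(fit$assignment$community, sim$labels$label), 1,
                 label = method)
  }
})
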