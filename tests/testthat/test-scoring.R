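make_communities <- function(member_list, ids) {
  # minimal resoclust_communities for scoring tests
  labels <- paste0("C", seq_along(member_list))
  assignment <- character(length(ids)); names(assignment) <- ids
  for (k in seq_along(member_list)) assignment[member_list[[k]]] <- labels[k]
  structure(list(
    communities = tibble::tibble(
      community = labels, node = seq_along(member_list),
      size = lengths(member_list), members = member_list),
    assignment = tibble::tibble(id = ids, community = unname(assignment)),
    scores = numeric(0), resolution = "low", delta = 0, linkage = "complete"
  ), class = "resoclust_communities")
}

test_that("resolution score is the harmonic mean of size fraction and cohesion", {
  m <- toy_two_triplets()
  cs <- make_communities(list(c("p1", "p2", "p3"), c("p4", "p5", "p6")),
                         rownames(m))
  sc <- resolution_scores(cs, m)
  # a = 3/6, b = 1 - 0.1/1.0 = 0.9, HM = 2(.5)(.9)/1.4
  expect_equal(sc$resolution, rep(2 * 0.5 * 0.9 / 1.4, 2), tolerance = 1e-12)
  expect_true(all(sc$is_major))
  expect_true(all(sc$resolution >= 0 & sc$resolution <= 1))
  # HM(a, b) <= min(2a, 2b)
  expect_true(all(sc$resolution <= pmin(2 * sc$size_fraction, 2 * sc$cohesion)))
})

test_that("degenerate communities score as the conventions dictate", {
  # all N points in one community, all distances 0: a = b = 1, HM = 1
  z <- matrix(0, 4, 4); rownames(z) <- colnames(z) <- paste0("s", 1:4)
  cs <- make_communities(list(paste0("s", 1:4)), paste0("s", 1:4))
  expect_warning(sc <- resolution_scores(cs, z), "zero")
  expect_equal(sc$resolution, 1)

  # singleton at N = 100: a = 0.01, b = 1 -> HM = 0.02/1.01, not major
  ids <- sprintf("s%03d", 1:100)
  m <- matrix(1, 100, 100); diag(m) <- 0; rownames(m) <- colnames(m) <- ids
  cs <- make_communities(c(list(ids[1]), list(ids[-1])), ids)
  sc <- resolution_scores(cs, m)
  single <- sc[sc$size == 1, ]
  expect_equal(single$resolution, 0.02 / 1.01, tolerance = 1e-12)
  expect_false(single$is_major)
})

test_that("freq enrichment counts the modal category among non-missing members", {
  expect_equal(freq_enrichment(c("oral", "oral", "oral", "gut")), 0.75)
  expect_equal(freq_enrichment(c("a", "a", "a")), 1)
  expect_equal(freq_enrichment(c("a", "a", "b", "b")), 0.5)   # modal tie
  expect_equal(freq_enrichment(c("a", NA, "a", "b")), 2 / 3)  # NA excluded
  expect_warning(out <- freq_enrichment(c(NA_character_, NA)), "all-missing")
  expect_equal(out, 0)
  # never below 1 / (number of observed categories)
  set.seed(5)
  for (i in 1:20) {
    v <- sample(letters[1:4], 12, replace = TRUE)
    expect_gte(freq_enrichment(v), 1 / length(unique(v)))
  }
})

test_that("NMI conventions, value, symmetry and renaming invariance", {
  x <- c("a", "a", "b", "b", "c")
  expect_equal(nmi_enrichment(x, x), 1)
  expect_equal(nmi_enrichment(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)  # independent
  # hand-derived plug-in value, cross-checked against the entropy oracle
  x2 <- c(0, 0, 1, 1); y2 <- c(0, 0, 0, 1)
  expect_equal(nmi_enrichment(x2, y2), 0.34559202, tolerance = 1e-7)
  expect_equal(nmi_enrichment(x2, y2), brute_nmi(x2, y2), tolerance = 1e-12)

  expect_equal(nmi_enrichment(rep("k", 4), x2), 0)  # one zero entropy
  expect_equal(nmi_enrichment(rep("k", 4), rep(3, 4)), 1)  # both constant

  set.seed(8)
  for (i in 1:15) {
    a <- sample(letters[1:3], 20, replace = TRUE)
    b <- sample(letters[1:4], 20, replace = TRUE)
    expect_equal(nmi_enrichment(a, b), nmi_enrichment(b, a), tolerance = 1e-12)
    expect_equal(nmi_enrichment(a, b), brute_nmi(a, b), tolerance = 1e-10)
    ren <- c(a = "z", b = "y", c = "x")[a]         # permute category names
    expect_equal(nmi_enrichment(ren, b), nmi_enrichment(a, b), tolerance = 1e-12)
  }
  expect_error(nmi_enrichment(c(1, NA), c(NA, 2)), "fewer than 2")
})

test_that("discretize performs capped equal-frequency binning", {
  expect_identical(discretize(1:8, bins = 4),
                   paste0("Q", rep(1:4, each = 2)))
  expect_identical(discretize(c(2, 2, 2)), rep("Q1", 3))      # constant
  expect_identical(sort(unique(discretize(rep(c(1, 9), 5), bins = 4))),
                   c("Q1", "Q2"))                             # capped at 2
  expect_identical(discretize(c(1, NA, 8), bins = 2), c("Q1", NA, "Q2"))
})

test_that("metadata ranking orders variables by enrichment", {
  m <- toy_two_triplets()
  cs <- make_communities(list(c("p1", "p2", "p3"), c("p4", "p5", "p6")),
                         rownames(m))
  sc <- resolution_scores(cs, m)
  meta <- tibble::tibble(
    id = rownames(m),
    group = c("x", "x", "x", "y", "y", "y"),   # identical to the labels
    const = rep("k", 6),
    uniq = paste0("u", 1:6))

  rk <- rank_metadata(cs, sc, meta, method = "nmi")
  expect_identical(rk$metadata[1], "group")
  expect_equal(rk$rank_statistic[rk$metadata == "group"], 1)
  expect_equal(rk$rank_statistic[rk$metadata == "const"], 0)
  expect_true(rk$highlighted[1])

  rkf <- rank_metadata(cs, sc, meta, method = "freq")
  expect_equal(rkf$rank_statistic[rkf$metadata == "group"], 1)
  # all-distinct id-like column: per-community score 1/n_c, ranked last
  expect_equal(rkf$rank_statistic[rkf$metadata == "uniq"], 1 / 3)
  expect_identical(rkf$metadata[nrow(rkf)], "uniq")
  expect_equal(unname(rkf$per_community[[which(rkf$metadata == "uniq")]]),
               c(1 / 3, 1 / 3))

  empty <- rank_metadata(cs, sc, tibble::tibble(id = rownames(m)))
  expect_equal(nrow(empty), 0L)
})
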