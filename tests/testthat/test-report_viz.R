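test_that("PCoA recovers exactly Euclidean geometries", {
  # three collinear points at 0, 1, 2: first axis reproduces the line
  line <- as.matrix(dist(matrix(c(0, 1, 2), 3, 1)))
  rownames(line) <- colnames(line) <- c("a", "b", "c")
  ord <- pcoa(line, axes = 2)
  co <- as.matrix(ord$coordinates[, -1])
  expect_equal(unname(as.matrix(dist(co[, 1]))), unname(line), tolerance = 1e-10)
  expect_lt(ord$eigenvalues[2], 1e-10)
  expect_lt(max(abs(colMeans(co))), 1e-6)

  # three equidistant points: two equal positive eigenvalues
  eq <- matrix(1, 3, 3); diag(eq) <- 0
  rownames(eq) <- colnames(eq) <- c("a", "b", "c")
  orde <- pcoa(eq, axes = 2)
  expect_equal(orde$eigenvalues[1], orde$eigenvalues[2], tolerance = 1e-10)
  expect_gt(orde$eigenvalues[2], 0)

  # random planar cloud: 2-axis PCoA reproduces all pairwise distances
  set.seed(77)
  X <- matrix(rnorm(2 * 15), 15, 2)
  D <- euclidean_distances(X)
  co2 <- as.matrix(pcoa(D, axes = 2)$coordinates[, -1])
  expect_lt(max(abs(as.matrix(dist(co2)) - D)), 1e-8)

  expect_error(pcoa(line[1:2, 1:2]), "at least 3")
})

test_that("non-Euclidean input warns about clipped negative eigenvalues", {
  m <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 2.8,
                1, 1, 2.8, 0), 4, 4)  # violates triangle inequality badly
  rownames(m) <- colnames(m) <- paste0("s", 1:4)
  expect_warning(ord <- pcoa(m), "negative eigenvalues")
  expect_true(all(ord$variance_explained >= 0 & ord$variance_explained <= 1))
})

test_that("ordinate dispatches pcoa and mds, refuses tsne", {
  m <- toy_two_triplets()
  expect_equal(ordinate(m, "mds")$coordinates, pcoa(m)$coordinates)
  expect_error(ordinate(m, "tsne"), "not bundled")
})

test_that("report files have the documented schema and are deterministic", {
  m <- toy_two_triplets()
  meta <- tibble::tibble(id = rownames(m),
                         group = c("x", "x", "x", "y", "y", "y"),
                         noise = c("u", "v", "u", "v", "u", "v"))
  fit <- resoclust(m, metadata = meta, enrichment = "nmi")
  d1 <- withr::local_tempdir()
  write_fit_report(fit, d1)
  clusters <- read.delim(file.path(d1, "clusters.txt"))
  expect_equal(nrow(clusters), 2L)
  expect_setequal(clusters$members, c("p1;p2;p3", "p4;p5;p6"))
  # ranked metadata ordering: the label-aligned column comes first
  expect_equal(names(clusters)[6], "enrichment_group")
  ranking <- read.delim(file.path(d1, "metadata_ranking.txt"))
  expect_identical(ranking$metadata, c("group", "noise"))

  # byte-identical re-run
  d2 <- withr::local_tempdir()
  write_fit_report(fit, d2)
  expect_identical(readLines(file.path(d1, "clusters.txt")),
                   readLines(file.path(d2, "clusters.txt")))

  # round trip: the partition is recovered exactly
  part <- read_report_partition(file.path(d1, "clusters.txt"))
  merged <- dplyr::left_join(fit$assignment, part, by = "id")
  expect_identical(merged$community.x, merged$community.y)
})

test_that("ordination plots build and save with community colors and shapes", {
  m <- toy_two_triplets()
  meta <- tibble::tibble(id = rownames(m),
                         group = c("x", "x", "x", "y", "y", "y"))
  fit <- resoclust(m, metadata = meta)
  p <- autoplot(fit, metadata = meta)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(length(unique(built$data[[1]]$colour)), 2L)
  expect_equal(length(unique(built$data[[1]]$shape)), 2L)

  p2 <- autoplot(fit)                       # no metadata: one shape
  built2 <- ggplot2::ggplot_build(p2)
  expect_equal(length(unique(built2$data[[1]]$shape)), 1L)

  f <- withr::local_tempfile(fileext = ".png")
  save_plot(p, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
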