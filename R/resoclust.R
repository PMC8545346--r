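#' Multi-resolution community detection from a distance matrix
#'
#' The full pipeline: builds a hierarchy over the distances with the chosen
#' linkage, descends it adaptively using binary-silhouette scores to emit
#' communities, computes per-community resolution scores and, when metadata
#' are supplied, ranks each variable by its enrichment in the detected
#' structure.
#'
#' @param D Square labeled distance matrix (or `dist`); see
#'   [read_distance_matrix()] for the file format.
#' @param metadata Optional metadata tibble/data frame with an `id` column
#'   (see [read_metadata()]), or `NULL`.
#' @param linkage Linkage method passed to [build_hierarchy()] (default
#'   `"complete"`).
#' @param resolution `"low"` (default) or `"high"`; see
#'   [detect_communities()].
#' @param delta High-resolution acceptance margin (default 0.05).
#' @param enrichment `"nmi"` (default) or `"freq"`; see [rank_metadata()].
#' @param major_threshold Resolution score above which a community is major
#'   (default 0.05).
#' @param bins Quantile bins used to discretize numeric metadata
#'   (default 4).
#' @return An object of class `resoclust`: list with `communities`
#'   (community tibble joined with resolution scores), `assignment`,
#'   `enrichment` (ranked metadata tibble), `hierarchy`, `detection`
#'   (the raw `resoclust_communities`), `D`, and `params`.
#' @examples
#' sim <- simulate_clusters(k = 3, n = 8, P = 40, alpha = 1,
#'                          sigma = 0.05, seed = 7)
#' fit <- resoclust(euclidean_distances(sim$X))
#' tidy(fit)
#' glance(fit)
#' @export
resoclust <- function(D, metadata = NULL, linkage = "complete",
                      resolution = c("low", "high"), delta = 0.05,
                      enrichment = c("nmi", "freq"),
                      major_threshold = 0.05, bins = 4) {
  resolution <- match.arg(resolution)
  enrichment <- match.arg(enrichment)
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- validate_distance_matrix(D)

  H <- build_hierarchy(D, method = linkage)
  det <- detect_communities(H, D, resolution = resolution, delta = delta)
  scores <- resolution_scores(det, D, major_threshold = major_threshold)

  enr <- if (!is.null(metadata) && ncol(metadata) > 1) {
    if (!"id" %in% names(metadata)) {
      stop("metadata must have an 'id' column", call. = FALSE)
    }
    rank_metadata(det, scores, tibble::as_tibble(metadata),
                  method = enrichment, bins = bins)
  } else {
    rank_metadata(det, scores, tibble::tibble(id = H$ids),
                  method = enrichment, bins = bins)
  }

  communities <- dplyr::left_join(det$communities, scores,
                                  by = c("community", "size"))

  structure(list(
    communities = communities,
    assignment = det$assignment,
    enrichment = enr,
    hierarchy = H,
    detection = det,
    D = D,
    params = list(linkage = linkage, resolution = resolution, delta = delta,
                  enrichment = enrichment, major_threshold = major_threshold,
                  bins = bins)
  ), class = "resoclust")
}

#' @export
print.resoclust <- function(x, ...) {
  cat("<resoclust fit> ", nrow(x$communities), " communities (",
      sum(x$communities$is_major), " major) over ", nrow(x$assignment),
      " points; ", x$params$linkage, " linkage, ", x$params$resolution,
      " resolution\n", sep = "")
  print(x$communities[, c("community", "size", "resolution", "is_major")],
        n = 10)
  if (nrow(x$enrichment) > 0) {
    cat("top metadata: ", x$enrichment$metadata[1], " (",
        x$enrichment$method[1], " = ",
        sprintf("%.3f", x$enrichment$rank_statistic[1]), ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy a resoclust fit into one row per community
#'
#' @param x A `resoclust` object.
#' @param ... Unused.
#' @return Tibble: `community`, `size`, `size_fraction`, `cohesion`,
#'   `resolution`, `is_major`, `members` (list-column).
#' @method tidy resoclust
#' @export
tidy.resoclust <- function(x, ...) {
  x$communities[, c("community", "size", "size_fraction", "cohesion",
                    "resolution", "is_major", "members")]
}

#' One-row summary of a resoclust fit
#'
#' @param x A `resoclust` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_communities`, `n_major`, `linkage`,
#'   `resolution`, `top_metadata`, `top_enrichment`.
#' @method glance resoclust
#' @export
glance.resoclust <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$assignment),
    n_communities = nrow(x$communities),
    n_major = sum(x$communities$is_major),
    linkage = x$params$linkage,
    resolution = x$params$resolution,
    top_metadata = if (nrow(x$enrichment) > 0) x$enrichment$metadata[1]
                   else NA_character_,
    top_enrichment = if (nrow(x$enrichment) > 0) x$enrichment$rank_statistic[1]
                     else NA_real_
  )
}

#' Ordination autoplot of a resoclust fit
#'
#' PCoA of the input distances, points colored by detected community and,
#' when metadata were supplied, shaped by the top-ranked variable.
#'
#' @param object A `resoclust` object.
#' @param metadata Optional metadata tibble (with `id`) to derive the shape
#'   variable from; defaults to none.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot resoclust
#' @export
autoplot.resoclust <- function(object, metadata = NULL, ...) {
  ord <- pcoa(object$D, axes = 2)
  shp <- NULL
  nm <- "metadata"
  if (!is.null(metadata) && nrow(object$enrichment) > 0) {
    nm <- object$enrichment$metadata[1]
    md <- dplyr::left_join(object$assignment,
                           tibble::as_tibble(metadata), by = "id")
    v <- md[[nm]]
    if (is.numeric(v)) v <- discretize(v, bins = object$params$bins)
    shp <- as.character(v)
  }
  plot_ordination(ord, object$detection, top_metadata = shp,
                  metadata_name = nm)
}

#' Write the standard report files for a fit
#'
#' Convenience wrapper over [write_report()].
#'
#' @param x A `resoclust` object.
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_fit_report <- function(x, out_dir) {
  stopifnot(inherits(x, "resoclust"))
  scores <- x$communities[, c("community", "size", "size_fraction",
                              "cohesion", "resolution", "is_major")]
  write_report(x$detection, scores, x$enrichment, out_dir)
}
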