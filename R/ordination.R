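# Ordination of the distance matrix for visual inspection. Principal
# coordinates analysis (classical scaling: Gower double-centering of the
# squared distances followed by an eigendecomposition) is the deterministic
# core; metric MDS is a thin alias for it and is flagged as such.

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling via [stats::cmdscale()]: coordinates are eigenvectors
#' of the double-centered squared-distance matrix scaled by the square roots
#' of their (nonnegative) eigenvalues, so column means are zero and, for an
#' exactly Euclidean input, pairwise coordinate distances reproduce the
#' input distances. Negative eigenvalues (non-Euclidean input) are reported
#' but clipped to zero for the variance decomposition, with a warning.
#'
#' @param D Validated distance matrix (or `dist`), `n >= 3`.
#' @param axes Number of axes to return (default 2).
#' @return An object of class `resoclust_ordination`: `coordinates` (tibble
#'   `id`, `Axis1..Axisk`), `eigenvalues` (all `n` values, descending,
#'   before clipping), `variance_explained` (per returned axis, in `[0, 1]`)
#'   and `method = "pcoa"`.
#' @export
pcoa <- function(D, axes = 2) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 points", call. = FALSE)
  axes <- as.integer(axes)
  stopifnot(axes >= 1)
  cs <- suppressWarnings(cmdscale(as.dist(D), k = min(axes, n - 1), eig = TRUE))
  eig <- sort(cs$eig, decreasing = TRUE)
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warning("negative eigenvalues (non-Euclidean distances) clipped to 0",
            call. = FALSE)
  }
  pos <- pmax(eig, 0)
  coords <- cs$points
  if (ncol(coords) < axes) {
    # degenerate geometry: pad with zero axes so the contract holds
    coords <- cbind(coords, matrix(0, n, axes - ncol(coords)))
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    coordinates = dplyr::bind_cols(tibble::tibble(id = rownames(D)),
                                   tibble::as_tibble(coords)),
    eigenvalues = eig,
    variance_explained = if (sum(pos) > 0) pos[seq_len(axes)] / sum(pos)
                         else rep(0, axes),
    method = "pcoa"
  ), class = "resoclust_ordination")
}

#' Ordination dispatcher
#'
#' `method = "pcoa"` and `"mds"` both run metric classical scaling
#' ([pcoa()]); `"tsne"` is not bundled and errors with a pointer to
#' dedicated packages. Kept so callers can request ordination by name.
#'
#' @param D Distance matrix.
#' @param method One of `"pcoa"`, `"mds"`, `"tsne"`.
#' @param axes Number of axes.
#' @return A `resoclust_ordination`.
#' @export
ordinate <- function(D, method = c("pcoa", "mds", "tsne"), axes = 2) {
  method <- match.arg(method)
  if (method == "tsne") {
    stop("t-SNE is not bundled; use a dedicated t-SNE package on the ",
         "coordinates or distances directly", call. = FALSE)
  }
  out <- pcoa(D, axes = axes)
  out$method <- method
  out
}

#' @export
print.resoclust_ordination <- function(x, ...) {
  cat("<resoclust ordination> method ", x$method, ", ",
      nrow(x$coordinates), " points, variance explained ",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " / "),
      "\n", sep = "")
  invisible(x)
}
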