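# The method core: binary-silhouette branch scoring and the adaptive
# top-down descent of the hierarchy that emits communities.
#
# The binary silhouette differs from the classical silhouette in that each
# member of a branch is scored against exactly one other cluster — the
# sibling branch at the same node — rather than against all clusters:
#   a_i = mean distance from i to the other members of its own branch
#   b_i = mean distance from i to the members of the sibling branch
#   s_i = (b_i - a_i) / max(a_i, b_i)
# with s_i = 0 for a singleton branch (Rousseeuw's convention) and when
# max(a_i, b_i) = 0 (duplicate points).

#' Binary-silhouette score of a branch against its sibling
#'
#' @param C Integer indices (into the ids of `D`) of the branch being scored.
#' @param S Integer indices of the sibling branch.
#' @param D Validated distance matrix.
#' @return Mean silhouette over the members of `C`, in `[-1, 1]`; 0 when `C`
#'   is a singleton.
#' @export
branch_score <- function(C, S, D) {
  if (length(intersect(C, S)) > 0) {
    stop("branches overlap: corrupt tree", call. = FALSE)
  }
  if (length(C) < 2L) return(0)
  DC <- D[C, C, drop = FALSE]
  a <- rowSums(DC) / (length(C) - 1L)
  b <- rowMeans(D[C, S, drop = FALSE])
  mx <- pmax(a, b)
  s <- ifelse(mx > 0, (b - a) / mx, 0)
  mean(s)
}

#' Binary-silhouette score of every node in a hierarchy
#'
#' Each node is scored against its sibling with [branch_score()]. Leaves are
#' singleton branches and score 0; the root has no sibling and scores 0 by
#' convention, so a dataset whose first split is uninformative is returned
#' as a single community.
#'
#' @param H A `resoclust_hierarchy`.
#' @param D The distance matrix `H` was built from. Scores always use the
#'   original point distances, never cophenetic distances.
#' @return Numeric vector of length `2n - 1`, scores indexed by node.
#' @export
node_scores <- function(H, D) {
  stopifnot(inherits(H, "resoclust_hierarchy"))
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.null(rownames(D)) && !identical(rownames(D), H$ids)) {
    D <- D[H$ids, H$ids, drop = FALSE]
  }
  scores <- numeric(2L * H$n - 1L)
  # every non-root node is scored against its sibling; visiting each
  # internal node once covers all of them. Root (no sibling) and leaves
  # (singleton branches) keep 0.
  for (v in seq_along(scores)) {
    if (H$left[v] == 0L) next
    scores[H$left[v]] <- branch_score(H$members[[H$left[v]]],
                                      H$members[[H$right[v]]], D)
    scores[H$right[v]] <- branch_score(H$members[[H$right[v]]],
                                       H$members[[H$left[v]]], D)
  }
  scores[H$root] <- 0
  scores
}

#' Detect communities by adaptive descent of a hierarchy
#'
#' Starting at the root: a leaf is emitted as a singleton; an internal node
#' whose binary-silhouette score strictly exceeds the larger of its two
#' children's scores (by at least `delta`) is emitted as a community
#' (all tips under it); otherwise the descent recurses into both children.
#' With structureless input (all scores equal) the strict comparison never
#' holds and the output degenerates to `n` singletons.
#'
#' @param H A `resoclust_hierarchy`.
#' @param D The distance matrix `H` was built from.
#' @param resolution `"low"` (default): a node only needs to beat its
#'   children (`delta = 0`). `"high"`: the node must beat them by `delta`,
#'   forcing deeper descent and finer communities.
#' @param delta Acceptance margin used in high-resolution mode (default
#'   0.05). Ignored when `resolution = "low"`.
#' @return An object of class `resoclust_communities`: list with
#'   `communities` (tibble: `community`, `node`, `size`, `members`
#'   list-column, sorted by size descending, labeled `"C1"`, `"C2"`, ...),
#'   `assignment` (tibble `id`, `community` in input id order), `scores`
#'   (per-node binary-silhouette scores) and the call parameters.
#' @export
detect_communities <- function(H, D, resolution = c("low", "high"),
                               delta = 0.05) {
  stopifnot(inherits(H, "resoclust_hierarchy"))
  resolution <- match.arg(resolution)
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!identical(rownames(D), H$ids)) {
    D <- D[H$ids, H$ids, drop = FALSE]
  }
  margin <- if (resolution == "high") delta else 0
  stopifnot(margin >= 0)
  scores <- node_scores(H, D)

  founders <- integer(0)
  stack <- H$root
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    l <- H$left[v]; r <- H$right[v]
    if (l == 0L) {                      # leaf
      founders <- c(founders, v)
    } else if (scores[v] > max(scores[l], scores[r]) + margin) {
      founders <- c(founders, v)
    } else {
      stack <- c(l, r, stack)
    }
  }

  sizes <- lengths(H$members[founders])
  ord <- order(-sizes, founders)
  founders <- founders[ord]
  sizes <- sizes[ord]
  labels <- paste0("C", seq_along(founders))
  member_ids <- lapply(H$members[founders], function(ix) H$ids[sort(ix)])

  assignment <- character(H$n)
  for (k in seq_along(founders)) {
    assignment[H$members[[founders[k]]]] <- labels[k]
  }

  structure(list(
    communities = tibble::tibble(
      community = labels, node = founders, size = sizes,
      members = member_ids),
    assignment = tibble::tibble(id = H$ids, community = assignment),
    scores = scores,
    resolution = resolution,
    delta = margin,
    linkage = H$method
  ), class = "resoclust_communities")
}

#' @export
print.resoclust_communities <- function(x, ...) {
  cat("<resoclust communities> ", nrow(x$communities), " communities over ",
      nrow(x$assignment), " points (", x$resolution, " resolution, ",
      x$linkage, " linkage)\n", sep = "")
  print(x$communities, ...)
  invisible(x)
}
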