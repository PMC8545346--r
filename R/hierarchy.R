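# Hierarchy construction: agglomerative clustering over the distance matrix,
# plus an explicit binary-tree view of the merge structure used by the
# community detector.

.linkage_methods <- c("single", "average", "complete", "weighted",
                      "centroid", "median", "ward")

# hclust's name for each supported linkage. Ward on raw dissimilarities is
# "ward.D2"; "weighted" is McQuitty's WPGMA. Centroid and median require the
# agglomeration to run on squared dissimilarities, with merge heights mapped
# back by a square root afterwards.
.hclust_method <- c(single = "single", average = "average",
                    complete = "complete", weighted = "mcquitty",
                    centroid = "centroid", median = "median",
                    ward = "ward.D2")

#' Build a hierarchy over a distance matrix
#'
#' Runs standard agglomerative clustering ([stats::hclust()]) and unfolds the
#' merge table into an explicit binary tree: `2n - 1` nodes, each internal
#' node carrying its merge height and its two children, each leaf at height
#' zero. Child orientation is fixed so the left child contains the
#' lexicographically smallest member id; community scores are symmetric in
#' siblings so this only stabilizes output order.
#'
#' @param D Validated distance matrix (see [validate_distance_matrix()]) or a
#'   `dist` object with labels.
#' @param method Linkage: one of `"single"`, `"average"`, `"complete"`
#'   (default), `"weighted"`, `"centroid"`, `"median"`, `"ward"`. Centroid and
#'   median agglomerate on squared dissimilarities (heights are mapped back by
#'   a square root) and may produce inversions, which are kept and logged.
#' @return An object of class `resoclust_hierarchy`: a list with `ids`,
#'   `method`, `n`, the underlying `hclust` object, and per-node vectors
#'   `height`, `left`, `right`, `members` (leaf indices under each node).
#'   Nodes `1..n` are leaves; node `n + k` is the k-th merge; node `2n - 1`
#'   is the root.
#' @export
build_hierarchy <- function(D, method = "complete") {
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- validate_distance_matrix(D)
  if (!is.character(method) || length(method) != 1 ||
      !(method %in% .linkage_methods)) {
    stop("unknown linkage method; valid options: ",
         paste(.linkage_methods, collapse = ", "), call. = FALSE)
  }
  n <- nrow(D)
  if (n < 2) stop("need at least 2 points to build a hierarchy", call. = FALSE)
  ids <- rownames(D)

  squared <- method %in% c("centroid", "median")
  d <- as.dist(if (squared) D^2 else D)
  hc <- hclust(d, method = .hclust_method[[method]])
  if (squared) hc$height <- sqrt(pmax(hc$height, 0))
  if (is.unsorted(hc$height)) {
    message("inversions present in ", method, "-linkage hierarchy (kept as is)")
  }

  n_nodes <- 2L * n - 1L
  height <- numeric(n_nodes)
  left <- integer(n_nodes)    # 0 for leaves
  right <- integer(n_nodes)
  members <- vector("list", n_nodes)
  members[seq_len(n)] <- as.list(seq_len(n))
  node_of <- function(x) if (x < 0) -x else n + x  # hclust merge coding
  for (k in seq_len(n - 1L)) {
    v <- n + k
    a <- node_of(hc$merge[k, 1]); b <- node_of(hc$merge[k, 2])
    # orient: left child holds the lexicographically smallest id
    min_a <- min(ids[members[[a]]]); min_b <- min(ids[members[[b]]])
    if (min_b < min_a) { tmp <- a; a <- b; b <- tmp }
    left[v] <- a; right[v] <- b
    height[v] <- hc$height[k]
    members[[v]] <- c(members[[a]], members[[b]])
  }

  structure(list(ids = ids, method = method, n = n, hclust = hc,
                 height = height, left = left, right = right,
                 members = members, root = n_nodes),
            class = "resoclust_hierarchy")
}

#' @export
print.resoclust_hierarchy <- function(x, ...) {
  cat("<resoclust hierarchy> ", x$n, " leaves, ", x$method, " linkage, ",
      2L * x$n - 1L, " nodes\n", sep = "")
  invisible(x)
}

#' Deterministic pre-order traversal of a hierarchy
#'
#' Visits node, then left child, then right child, starting at the root.
#'
#' @param H A `resoclust_hierarchy`.
#' @return A tibble with one row per node in visit order: `node`, `height`,
#'   `is_leaf`, `n_members`, and `members` (list-column of member ids).
#' @export
traverse_nodes <- function(H) {
  stopifnot(inherits(H, "resoclust_hierarchy"))
  order <- integer(2L * H$n - 1L)
  i <- 0L
  stack <- H$root
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    i <- i + 1L
    order[i] <- v
    if (H$left[v] > 0L) stack <- c(H$left[v], H$right[v], stack)
  }
  tibble::tibble(
    node = order,
    height = H$height[order],
    is_leaf = H$left[order] == 0L,
    n_members = lengths(H$members[order]),
    members = lapply(H$members[order], function(ix) H$ids[ix])
  )
}

#' Export a hierarchy as a Newick string (debug aid)
#'
#' Leaf names are the ids; branch lengths are height differences between a
#' node and its parent.
#'
#' @param H A `resoclust_hierarchy`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
hierarchy_newick <- function(H, path = NULL) {
  stopifnot(inherits(H, "resoclust_hierarchy"))
  phy <- ape::as.phylo(H$hclust)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
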