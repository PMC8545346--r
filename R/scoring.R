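# Community prioritization and metadata enrichment.
#
# Resolution score of a community = harmonic mean of
#   a = size fraction n_c / N            (normalized member count)
#   b = cohesion = 1 - mean within-community distance / max(D)
# so both arguments live in (0, 1]. Communities with resolution above the
# major threshold (default 0.05) are "major". Enrichment of a metadata
# variable is either the modal-category fraction per community (freq) or the
# normalized mutual information with the community labels (nmi).

#' Resolution scores for a set of communities
#'
#' @param communities A `resoclust_communities` object.
#' @param D The distance matrix the communities were detected on.
#' @param major_threshold Resolution score above which a community is
#'   flagged major (default 0.05).
#' @return A tibble with one row per community: `community`, `size`,
#'   `size_fraction`, `cohesion`, `resolution`, `is_major`. Singletons have
#'   cohesion 1 by convention.
#' @export
resolution_scores <- function(communities, D, major_threshold = 0.05) {
  stopifnot(inherits(communities, "resoclust_communities"))
  if (inherits(D, "dist")) D <- as.matrix(D)
  N <- nrow(communities$assignment)
  dmax <- max(D)
  if (dmax == 0) {
    warning("all distances are zero; cohesion set to 1 for every community",
            call. = FALSE)
  }
  res <- purrr::map_dfr(seq_len(nrow(communities$communities)), function(k) {
    mem <- communities$communities$members[[k]]
    n_c <- length(mem)
    if (n_c < 2L || dmax == 0) {
      b <- 1
    } else {
      sub <- D[mem, mem, drop = FALSE]
      b <- 1 - mean(sub[upper.tri(sub)]) / dmax
    }
    a <- n_c / N
    resolution <- if (a == 0 || b == 0) 0 else 2 * a * b / (a + b)
    tibble::tibble(
      community = communities$communities$community[k],
      size = n_c, size_fraction = a, cohesion = b, resolution = resolution)
  })
  res$is_major <- res$resolution > major_threshold
  res
}

#' Frequency-based enrichment of a categorical variable in one community
#'
#' The count of the modal category among the community's members, divided by
#' the number of members with a non-missing value. A community whose members
#' are all missing for the variable scores 0 (with a warning).
#'
#' @param values Character (categorical) values of the variable for the
#'   community's members; may contain `NA`.
#' @return A number in `[0, 1]`.
#' @export
freq_enrichment <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) {
    warning("variable is all-missing within a community; enrichment 0",
            call. = FALSE)
    return(0)
  }
  max(table(v)) / length(v)
}

#' Normalized mutual information between two label vectors
#'
#' Plug-in (empirical) NMI with natural logarithms, normalized by the
#' geometric mean of the marginal entropies: `I(X;Y) / sqrt(H(X) H(Y))`.
#' Identical (non-constant) vectors score 1 and independent vectors score 0.
#' When both entropies are 0 the vectors are both constant and the score is
#' 1; when exactly one is 0 the score is 0. Pairs with a missing value in
#' either vector are dropped first.
#'
#' @param x,y Vectors of equal length (coerced to character); at least 2
#'   complete pairs required.
#' @return A number in `[0, 1]`.
#' @export
nmi_enrichment <- function(x, y) {
  if (length(x) != length(y)) stop("label vectors differ in length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- as.character(x[ok]); y <- as.character(y[ok])
  n <- length(x)
  if (n < 2) stop("fewer than 2 complete pairs for NMI", call. = FALSE)
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  px <- table(x) / n
  py <- table(y) / n
  hx <- entropy(as.numeric(px))
  hy <- entropy(as.numeric(py))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  joint <- table(x, y) / n
  mi <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log(p / (as.numeric(px[i]) * as.numeric(py[j])))
  }
  min(1, max(0, mi / sqrt(hx * hy)))
}

#' Discretize a numeric variable into equal-frequency bins
#'
#' Quantile binning into at most `bins` categories labeled `"Q1".."Qk"`; the
#' effective number of bins is capped by the number of distinct non-missing
#' values (duplicate quantile boundaries are collapsed). Missing stays
#' missing.
#'
#' @param x Numeric vector with at least one non-missing value.
#' @param bins Target number of bins, `>= 2` (default 4).
#' @return Character vector of the same length with categories `"Q1".."Qk"`.
#' @export
discretize <- function(x, bins = 4) {
  stopifnot(is.numeric(x), bins >= 2)
  obs <- x[!is.na(x)]
  if (length(obs) == 0) stop("no non-missing values to discretize", call. = FALSE)
  k <- min(bins, length(unique(obs)))
  if (k < 2) {
    out <- ifelse(is.na(x), NA_character_, "Q1")
    return(out)
  }
  breaks <- unique(quantile(obs, probs = seq(0, 1, length.out = k + 1),
                            names = FALSE, type = 7))
  if (length(breaks) < 3) {
    # heavy ties collapsed everything: fall back to distinct values
    breaks <- unique(sort(obs))
    breaks <- c(breaks[1] - 1, breaks)
  }
  cut_codes <- cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  ifelse(is.na(cut_codes), NA_character_, paste0("Q", cut_codes))
}

#' Rank metadata variables by their enrichment in the detected communities
#'
#' Numeric variables are first discretized with [discretize()]. For
#' `method = "freq"` the rank statistic of a variable is the mean
#' modal-category fraction over the *major* communities (all communities if
#' none is major); for `method = "nmi"` it is the normalized mutual
#' information between the variable and the community labels over all
#' assigned samples. Variables are sorted by rank statistic descending, ties
#' broken by name; those above `highlight_threshold` are flagged.
#'
#' @param communities A `resoclust_communities` object.
#' @param scores Output of [resolution_scores()] for the same communities.
#' @param meta Metadata tibble with an `id` column matching the assignment
#'   ids (see [read_metadata()]); may have zero variable columns.
#' @param method `"nmi"` (default) or `"freq"`.
#' @param bins Bin count for discretizing numeric variables (default 4).
#' @param highlight_threshold Enrichment above which a variable is
#'   highlighted (default 0.05).
#' @return A tibble sorted by `rank_statistic` descending: `metadata`,
#'   `method`, `rank_statistic`, `highlighted`, and `per_community`
#'   (list-column of per-community freq scores; `NULL` rows for nmi).
#' @export
rank_metadata <- function(communities, scores, meta,
                          method = c("nmi", "freq"), bins = 4,
                          highlight_threshold = 0.05) {
  stopifnot(inherits(communities, "resoclust_communities"))
  method <- match.arg(method)
  vars <- setdiff(names(meta), "id")
  if (length(vars) == 0) {
    return(tibble::tibble(metadata = character(), method = character(),
                          rank_statistic = numeric(), highlighted = logical(),
                          per_community = list()))
  }
  meta <- dplyr::left_join(communities$assignment, meta, by = "id")
  major <- scores$community[scores$is_major]
  if (length(major) == 0) major <- scores$community

  rows <- purrr::map_dfr(vars, function(nm) {
    v <- meta[[nm]]
    if (is.numeric(v)) v <- discretize(v, bins = bins)
    v <- as.character(v)
    if (method == "nmi") {
      stat <- nmi_enrichment(meta$community, v)
      tibble::tibble(metadata = nm, method = method, rank_statistic = stat,
                     per_community = list(NULL))
    } else {
      per <- vapply(communities$communities$community, function(cc) {
        freq_enrichment(v[meta$community == cc])
      }, numeric(1))
      names(per) <- communities$communities$community
      tibble::tibble(metadata = nm, method = method,
                     rank_statistic = mean(per[major]),
                     per_community = list(per))
    }
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$rank_statistic), .data$metadata)
  rows$highlighted <- rows$rank_statistic > highlight_threshold
  rows[, c("metadata", "method", "rank_statistic", "highlighted", "per_community")]
}
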