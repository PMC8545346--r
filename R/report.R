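# Tab-delimited reports: clusters.txt (one row per community with members,
# resolution score, major flag and one enrichment column per metadatum,
# ordered by metadata rank) and metadata_ranking.txt.

#' Write the tab-delimited community report
#'
#' `clusters.txt` has one row per community: `community`, `size`, `members`
#' (semicolon-joined, input id order), `resolution`, `is_major`, then one
#' enrichment column per metadata variable ordered by rank statistic
#' descending (freq: per-community score; nmi: the global score repeated).
#' `metadata_ranking.txt` lists each variable with its rank statistic and
#' highlight flag. Output is byte-identical across re-runs on the same
#' input.
#'
#' @param communities A `resoclust_communities` object.
#' @param scores Output of [resolution_scores()].
#' @param enrichment Output of [rank_metadata()] (may have zero rows).
#' @param out_dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(communities, scores, enrichment, out_dir) {
  stopifnot(inherits(communities, "resoclust_communities"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir,
                                 call. = FALSE)

  input_order <- communities$assignment$id
  members_joined <- vapply(communities$communities$members, function(m) {
    paste(m[order(match(m, input_order))], collapse = ";")
  }, character(1))

  tab <- data.frame(
    community = communities$communities$community,
    size = communities$communities$size,
    members = members_joined,
    resolution = sprintf("%.6f", scores$resolution[
      match(communities$communities$community, scores$community)]),
    is_major = scores$is_major[
      match(communities$communities$community, scores$community)],
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (nrow(enrichment) > 0) {
    for (i in seq_len(nrow(enrichment))) {
      nm <- enrichment$metadata[i]
      per <- enrichment$per_community[[i]]
      col <- if (is.null(per)) {
        rep(enrichment$rank_statistic[i], nrow(tab))  # global nmi score
      } else {
        as.numeric(per[tab$community])
      }
      tab[[paste0("enrichment_", nm)]] <- sprintf("%.6f", col)
    }
  }
  clusters_path <- file.path(out_dir, "clusters.txt")
  write.table(tab, clusters_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  ranking_path <- file.path(out_dir, "metadata_ranking.txt")
  rk <- if (nrow(enrichment) > 0) {
    data.frame(metadata = enrichment$metadata, method = enrichment$method,
               rank_statistic = sprintf("%.6f", enrichment$rank_statistic),
               highlighted = enrichment$highlighted,
               stringsAsFactors = FALSE)
  } else {
    data.frame(metadata = character(), method = character(),
               rank_statistic = character(), highlighted = logical())
  }
  write.table(rk, ranking_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(clusters_path, ranking_path))
}

#' Read a clusters.txt report back into a partition
#'
#' @param path Path to a `clusters.txt` written by [write_report()].
#' @return A tibble `id`, `community` recovering the exact partition.
#' @export
read_report_partition <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    tibble::tibble(id = strsplit(tab$members[i], ";", fixed = TRUE)[[1]],
                   community = tab$community[i])
  })
}
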