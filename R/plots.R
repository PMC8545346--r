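# Ordination scatter plots: color = community, shape = top-ranked metadata
# category (at most 8 shapes; rarer categories pooled as "other").

#' Ordination plot colored by community
#'
#' @param ord A `resoclust_ordination`.
#' @param communities A `resoclust_communities` for the same ids.
#' @param top_metadata Optional character vector (one value per assigned id,
#'   in assignment order) of the top-ranked metadata variable; mapped to
#'   marker shape. More than 8 categories are pooled into `"other"` by
#'   frequency.
#' @param metadata_name Legend title for the shape scale.
#' @return A ggplot object.
#' @export
plot_ordination <- function(ord, communities, top_metadata = NULL,
                            metadata_name = "metadata") {
  stopifnot(inherits(ord, "resoclust_ordination"),
            inherits(communities, "resoclust_communities"))
  df <- dplyr::left_join(ord$coordinates, communities$assignment, by = "id")
  ve <- ord$variance_explained
  labs_xy <- ggplot2::labs(
    x = sprintf("Axis 1 (%.1f%%)", 100 * ve[1]),
    y = sprintf("Axis 2 (%.1f%%)", 100 * ifelse(length(ve) > 1, ve[2], 0)),
    colour = "community", shape = metadata_name)
  if (!is.null(top_metadata)) {
    shp <- as.character(top_metadata)
    cats <- names(sort(table(shp), decreasing = TRUE))
    if (length(cats) > 8) {
      shp[!shp %in% cats[1:8]] <- "other"
    }
    shp[is.na(shp)] <- "missing"
    df$shape_var <- factor(shp)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2,
                                          colour = .data$community,
                                          shape = .data$shape_var)) +
      ggplot2::scale_shape_manual(
        values = c(16, 17, 15, 3, 7, 8, 5, 6, 4)[seq_len(nlevels(df$shape_var))],
        drop = TRUE)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2,
                                          colour = .data$community))
  }
  p + ggplot2::geom_point(size = 2) +
    labs_xy +
    ggplot2::theme_bw()
}

#' Save an ordination plot to file
#'
#' @param p A ggplot object.
#' @param path Output path; format follows the extension (png, pdf, ...).
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
save_plot <- function(p, path, width = 6, height = 4.5) {
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 150)
  invisible(path)
}
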