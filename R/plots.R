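# ggplot2 figures for the main result types.

#' Plot growth curves (mean +/- sd per day)
#'
#' @param series A [growth_series()] tibble.
#' @return A ggplot: day vs RFU, colored by culture, faceted by species.
#' @export
plot_growth_curves <- function(series) {
  df <- as_tibble(series) |>
    dplyr::group_by(.data$species, .data$culture, .data$day) |>
    dplyr::summarise(mean_rfu = mean(.data$rfu), sd_rfu = sd(.data$rfu),
                     .groups = "drop")
  ggplot(df, aes(x = .data$day, y = .data$mean_rfu, color = .data$culture)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean_rfu - .data$sd_rfu,
                      ymax = .data$mean_rfu + .data$sd_rfu), width = 0.3) +
    facet_wrap(~species) +
    labs(x = "day", y = "chlorophyll-a fluorescence (RFU)", color = "culture") +
    theme_bw()
}

#' Score plot of a PCA result
#'
#' @param object A `pca_result` from [pca()] or [pca_feature_table()].
#' @param colour Scores column used for point color (default `"group"` when
#'   present, else none).
#' @param ... Unused.
#' @return A ggplot of the first two components with explained-variance
#'   percentages in the axis labels.
#' @export
autoplot.pca_result <- function(object, colour = NULL, ...) {
  sc <- object$scores
  if (is.null(colour) && "group" %in% names(sc)) colour <- "group"
  expl <- round(100 * object$explained_fraction, 1)
  p <- ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) +
    labs(x = paste0("PC1 (", expl[1], "%)"),
         y = paste0("PC2 (", if (length(expl) >= 2) expl[2] else NA, "%)")) +
    theme_bw()
  if (!is.null(colour)) {
    p + geom_point(aes(color = .data[[colour]]), size = 2)
  } else {
    p + geom_point(size = 2)
  }
}

#' VIP score plot of a selection result
#'
#' @param selection A `selection_result` from [select_features()].
#' @param top Number of top-VIP features to label (default 20).
#' @return A ggplot of ranked VIP scores with the selection threshold.
#' @export
plot_vip <- function(selection, top = 20) {
  df <- as_tibble(selection) |>
    dplyr::filter(!is.na(.data$vip)) |>
    dplyr::arrange(dplyr::desc(.data$vip)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot(df, aes(x = .data$rank, y = .data$vip)) +
    geom_point(aes(color = .data$selected), size = 1) +
    geom_hline(yintercept = attr(selection, "threshold"), linetype = "dashed") +
    geom_text(
      data = df[df$rank <= top & df$selected, ],
      aes(label = .data$feature_id), hjust = -0.1, size = 2.5
    ) +
    labs(x = "VIP rank", y = "VIP", color = "selected") +
    theme_bw()
}

#' Bar chart of exchange-category counts
#'
#' @param counts The `counts` tibble from [summarize_exchange()].
#' @return A ggplot, categories on the x axis, faceted by focal species.
#' @export
plot_exchange <- function(counts) {
  ggplot(counts, aes(x = .data$category, y = .data$n, fill = .data$category)) +
    geom_col() +
    facet_wrap(~focal_species) +
    labs(x = NULL, y = "differential features") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1), legend.position = "none")
}
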