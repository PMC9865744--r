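# ggplot2 graphics for the result types, plus the bundled artifact writer.

#' @importFrom ggplot2 ggplot aes geom_col geom_histogram geom_boxplot
#'   geom_tile geom_text labs facet_wrap theme_minimal scale_fill_gradient2
#'   scale_fill_viridis_d stat_summary autoplot theme element_text
NULL

join_regions <- function(map, annotations) {
  ann <- validate_annotations(annotations)
  left_join(map, ann, by = c(res_index = "index")) |>
    mutate(region = factor(.data$region, levels = unique(ann$region)))
}

#' Relevance map plot
#'
#' Average residue relevance along the chain, colored by receptor region;
#' faceted per explained class when a `class` column is present.
#'
#' @param map Tibble `res_index,relevance` (optionally `class`), e.g. from
#'   [relevance_maps()].
#' @param annotations Residue annotation tibble.
#' @return A ggplot object.
#' @export
plot_relevance_map <- function(map, annotations) {
  p <- ggplot(join_regions(map, annotations),
              aes(x = .data$res_index, y = .data$relevance,
                  fill = .data$region)) +
    geom_col(width = 1) +
    scale_fill_viridis_d(drop = FALSE) +
    labs(x = "residue index", y = "average relevance", fill = "region") +
    theme_minimal()
  if ("class" %in% names(map)) p <- p + facet_wrap(~class, ncol = 1)
  p
}

#' Histogram of residue relevance values
#'
#' @param map As in [plot_relevance_map()].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_relevance_histogram <- function(map, bins = 50) {
  p <- ggplot(map, aes(x = .data$relevance)) +
    geom_histogram(bins = bins, fill = "grey30") +
    labs(x = "residue relevance", y = "count") +
    theme_minimal()
  if ("class" %in% names(map)) p <- p + facet_wrap(~class, ncol = 1)
  p
}

#' Per-region relevance distribution box plots
#'
#' Box plots of per-residue-per-frame relevance by region, with the mean
#' marked by a triangle; outliers beyond the whiskers are the candidate
#' key residues.
#'
#' @param frame_maps Tibble `res_index,relevance` of per-frame residue
#'   relevances for one class (e.g. the `frame_maps` attribute of
#'   [relevance_maps()] filtered to a class).
#' @param annotations Residue annotation tibble.
#' @return A ggplot object.
#' @export
plot_region_boxplot <- function(frame_maps, annotations) {
  ggplot(join_regions(frame_maps, annotations),
         aes(x = .data$region, y = .data$relevance)) +
    geom_boxplot(outlier.size = 0.6) +
    stat_summary(fun = mean, geom = "point", shape = 17, size = 2) +
    labs(x = NULL, y = "relevance") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Confusion-matrix heatmap
#'
#' @param object A `conformo_eval`.
#' @param ... Unused.
#' @return A ggplot object (row-normalized confusion matrix).
#' @export
autoplot.conformo_eval <- function(object, ...) {
  cm <- as_tibble(object$confusion_normalized, rownames = "truth") |>
    tidyr::pivot_longer(-"truth", names_to = "predicted",
                        values_to = "fraction") |>
    mutate(truth = factor(.data$truth, levels = rev(rownames(
             object$confusion_normalized))),
           predicted = factor(.data$predicted,
                              levels = colnames(object$confusion_normalized)))
  ggplot(cm, aes(x = .data$predicted, y = .data$truth,
                 fill = .data$fraction)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$fraction)), size = 3) +
    scale_fill_gradient2(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = "predicted", y = "true") +
    theme_minimal()
}

#' Write figures and CSV twins for a completed analysis
#'
#' One relevance-map plot and one histogram per class, per-region box
#' plots, the confusion heatmap, and CSV copies of every table.
#'
#' @param maps [relevance_maps()] result (with `frame_maps` attribute).
#' @param motifs Named list of [iqr_motifs()] tables (one per class).
#' @param summaries Named list of [region_summary()] tables (one per
#'   class).
#' @param eval_report A `conformo_eval`, or `NULL` to skip.
#' @param annotations Residue annotation tibble.
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
render_outputs <- function(maps, motifs, summaries, eval_report, annotations,
                           dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  save_plot <- function(p, name) {
    path <- file.path(dir, name)
    ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 150)
    written[[length(written) + 1]] <<- path
  }
  save_csv <- function(d, name) {
    path <- file.path(dir, name)
    readr::write_csv(d, path, progress = FALSE)
    written[[length(written) + 1]] <<- path
  }
  frame_maps <- attr(maps, "frame_maps")
  for (cl in unique(maps$class)) {
    mcl <- filter(maps, .data$class == cl)
    save_plot(plot_relevance_map(mcl, annotations),
              paste0("relevance_map_", cl, ".png"))
    save_plot(plot_relevance_histogram(mcl),
              paste0("relevance_hist_", cl, ".png"))
    if (!is.null(frame_maps)) {
      save_plot(plot_region_boxplot(filter(frame_maps, .data$class == cl),
                                    annotations),
                paste0("region_boxplot_", cl, ".png"))
    }
    save_csv(mcl, paste0("relevance_map_", cl, ".csv"))
    save_csv(motifs[[cl]], paste0("motifs_", cl, ".csv"))
    save_csv(summaries[[cl]], paste0("regions_", cl, ".csv"))
  }
  if (!is.null(eval_report)) {
    save_plot(autoplot(eval_report), "confusion_matrix.png")
    cm <- as_tibble(eval_report$confusion_normalized, rownames = "truth")
    save_csv(cm, "confusion_matrix.csv")
    save_csv(eval_report$metrics, "classification_metrics.csv")
  }
  invisible(unlist(written))
}
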