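# Plotting: axial-slice rasters for maps and a scatter for symptom
# correlations. All plots are ggplot2 objects the caller can restyle.

#' Plot one axial slice of a per-voxel map
#'
#' @param values Numeric per-voxel vector (or a `metric_map` / `zmap`).
#' @param voxel_index,grid_shape Voxel geometry (taken from the object when
#'   one is supplied).
#' @param slice_z Axial slice to show (default: middle slice).
#' @return A ggplot object.
#' @export
plot_map_slice <- function(values, voxel_index = NULL, grid_shape = NULL,
                           slice_z = NULL) {
  if (inherits(values, c("metric_map", "zmap"))) {
    obj <- values
    voxel_index <- obj$voxel_index
    grid_shape <- obj$grid_shape
    values <- obj$values %||% obj$z
  }
  slice_z <- slice_z %||% ceiling(grid_shape[3L] / 2)
  keep <- voxel_index[, 3L] == slice_z
  df <- tibble::tibble(x = voxel_index[keep, 1L], y = voxel_index[keep, 2L],
                       value = values[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("axial slice z = %d", slice_z),
                  fill = "value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.metric_map <- function(object, slice_z = NULL, ...) {
  plot_map_slice(object, slice_z = slice_z)
}

#' @export
autoplot.zmap <- function(object, slice_z = NULL, ...) {
  plot_map_slice(object, slice_z = slice_z)
}

#' Scatter plot of cluster-mean connectivity against a symptom score
#'
#' @param mean_table Cluster-mean tibble from [cluster_means()].
#' @param subjects Subject tibble.
#' @param cluster_id Cluster to plot.
#' @param symptom Symptom column name (e.g. `"phq15"`).
#' @return A ggplot object.
#' @export
plot_symptom_scatter <- function(mean_table, subjects, cluster_id,
                                 symptom = "phq15") {
  sub <- mean_table[mean_table$cluster_id == cluster_id, ]
  df <- tibble::tibble(
    value = sub$mean_value,
    score = subjects[[symptom]][match(sub$id, subjects$id)],
    group = subjects$group[match(sub$id, subjects$id)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$value,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "grey30") +
    ggplot2::labs(x = toupper(symptom), y = "cluster mean (normalized)") +
    ggplot2::theme_minimal()
}
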