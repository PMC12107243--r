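# The three per-voxel graph metrics. All are raw edge-weight sums over the
# nonnegative connectivity matrix: weighted degree sums every edge of a
# voxel; integration only edges whose endpoints lie in different networks;
# segregation only edges within the voxel's own network. Integration and
# segregation therefore partition the isocortical weighted degree exactly.

new_metric_map <- function(metric, values, voxel_index, scope, grid_shape,
                           normalized = FALSE, subject = NA_character_) {
  structure(
    list(metric = metric, values = as.numeric(values),
         voxel_index = voxel_index, scope = scope,
         grid_shape = as.integer(grid_shape),
         normalized = normalized, subject = subject),
    class = "metric_map"
  )
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("<metric_map> %s (%s%s), %d voxels\n", x$metric, x$scope,
              if (x$normalized) ", normalized" else "", length(x$values)))
  invisible(x)
}

#' Weighted-degree map
#'
#' The weighted degree of voxel i is the sum of its edge weights to all
#' other voxels (the diagonal is zero by construction, so self-connections
#' never contribute).
#'
#' @param cm A nonnegative `conn_matrix`.
#' @param subject Optional subject id stored on the map.
#' @return A `metric_map`.
#' @export
weighted_degree <- function(cm, subject = NA_character_) {
  stopifnot(inherits(cm, "conn_matrix"))
  new_metric_map("weighted_degree", rowSums(cm$weights), cm$voxel_index,
                 cm$scope, cm$grid_shape, subject = subject)
}

# Shared worker: per-voxel sum of edges to same-network voxels.
within_network_sums <- function(weights, labels) {
  v <- length(labels)
  seg <- numeric(v)
  for (lab in unique(labels)) {
    members <- labels == lab
    seg[members] <- rowSums(weights[members, members, drop = FALSE])
  }
  seg
}

resolve_labels <- function(cm, assignment) {
  labels <- if (is.null(assignment)) cm$labels else as.integer(assignment)
  if (is.null(labels) || length(labels) != ncol(cm$weights))
    stop("network assignment must cover every voxel in the matrix")
  if (any(is.na(labels)) || any(labels < 1L))
    stop("all voxels must carry a network label >= 1 (restrict to isocortex first)")
  labels
}

#' Between-network integration map
#'
#' Integration of voxel i is the sum of its edge weights to voxels assigned
#' to a *different* network, indexing between-network communication.
#'
#' @param cm An isocortical `conn_matrix`.
#' @param assignment Integer network labels (1..K) aligned with the matrix
#'   voxels; defaults to the labels carried by `cm`.
#' @inheritParams weighted_degree
#' @return A `metric_map`.
#' @export
integration <- function(cm, assignment = NULL, subject = NA_character_) {
  stopifnot(inherits(cm, "conn_matrix"))
  labels <- resolve_labels(cm, assignment)
  vals <- rowSums(cm$weights) - within_network_sums(cm$weights, labels)
  new_metric_map("integration", vals, cm$voxel_index, cm$scope,
                 cm$grid_shape, subject = subject)
}

#' Within-network segregation map
#'
#' Segregation of voxel i is the sum of its edge weights to voxels in the
#' *same* network, indexing within-network communication.
#'
#' @inheritParams integration
#' @return A `metric_map`.
#' @export
segregation <- function(cm, assignment = NULL, subject = NA_character_) {
  stopifnot(inherits(cm, "conn_matrix"))
  labels <- resolve_labels(cm, assignment)
  new_metric_map("segregation", within_network_sums(cm$weights, labels),
                 cm$voxel_index, cm$scope, cm$grid_shape, subject = subject)
}

#' Canonical seven-network names
#'
#' Label-to-name map for the standard seven-network isocortical
#' parcellation.
#' @return A named character vector indexed by label 1..7.
#' @export
network_names <- function() {
  c(`1` = "visual", `2` = "somatomotor", `3` = "dorsal attention",
    `4` = "ventral attention (salience)", `5` = "limbic",
    `6` = "frontoparietal", `7` = "default mode")
}
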