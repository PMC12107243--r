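# Per-subject voxel-wise connectivity: Pearson correlation of every voxel
# pair, negative-edge removal, and restriction to the isocortex.

new_conn_matrix <- function(weights, voxel_index, scope, grid_shape,
                            labels = NULL, zero_variance = integer()) {
  structure(
    list(weights = weights, voxel_index = voxel_index, scope = scope,
         grid_shape = as.integer(grid_shape), labels = labels,
         zero_variance = zero_variance),
    class = "conn_matrix"
  )
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d voxels, scope = %s, %d zero-variance voxel(s)\n",
              ncol(x$weights), x$scope, length(x$zero_variance)))
  invisible(x)
}

#' Voxel-by-voxel Pearson correlation matrix
#'
#' Entry (i, j) is the Pearson correlation of voxel series i and j; the
#' diagonal is forced to zero so self-connections never enter metric sums.
#' Zero-variance voxels get zero rows/columns and are reported in the
#' `zero_variance` field. Setting `block_size` computes the matrix in column
#' blocks, bounding the working-set size for large masks; the result is
#' identical to the dense path.
#'
#' @param ts A `voxel_ts` with at least 3 time points.
#' @param block_size Optional number of voxels per block.
#' @return A `conn_matrix` with scope `"whole_brain"`.
#' @export
pearson_matrix <- function(ts, block_size = NULL) {
  stopifnot(inherits(ts, "voxel_ts"))
  x <- ts$data
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 time points for correlation")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  ss <- sqrt(colSums(xc^2))
  zero_var <- which(ss <= 0)
  ss[zero_var] <- 1  # avoid 0/0; rows zeroed below
  xs <- sweep(xc, 2L, ss, "/")
  v <- ncol(xs)
  if (is.null(block_size) || block_size >= v) {
    w <- crossprod(xs)
  } else {
    w <- matrix(0, v, v)
    starts <- seq(1L, v, by = block_size)
    for (s in starts) {
      cols <- s:min(s + block_size - 1L, v)
      w[, cols] <- crossprod(xs, xs[, cols, drop = FALSE])
    }
  }
  if (length(zero_var)) {
    w[zero_var, ] <- 0
    w[, zero_var] <- 0
  }
  diag(w) <- 0
  new_conn_matrix(w, ts$voxel_index, "whole_brain", ts$grid_shape,
                  zero_variance = zero_var)
}

#' Zero out negative connectivity weights
#'
#' Negative correlations are replaced by 0 (edge absent); nonnegative
#' entries are untouched, keeping the matrix rectangular so that the graph
#' metric sums remain well defined.
#'
#' @param cm A `conn_matrix`.
#' @return A `conn_matrix` with all weights `>= 0`.
#' @export
remove_negatives <- function(cm) {
  stopifnot(inherits(cm, "conn_matrix"))
  cm$weights[cm$weights < 0] <- 0
  cm
}

#' Restrict a connectivity matrix to isocortical voxels
#'
#' Keeps the submatrix over voxels with parcellation label >= 1, preserving
#' voxel order. Voxels absent from the parcellation count as label 0 and are
#' dropped (tallied in `dropped_voxels`).
#'
#' @param cm A `conn_matrix`.
#' @param parcellation 3-D integer array of network labels (0 = not
#'   isocortical), or a label vector aligned with `cm$voxel_index` rows.
#' @return A `conn_matrix` with scope `"isocortical"` and a `labels` field.
#' @export
restrict_isocortex <- function(cm, parcellation) {
  stopifnot(inherits(cm, "conn_matrix"))
  if (is.array(parcellation) && length(dim(parcellation)) == 3L) {
    labels <- parcellation[coords_to_linear(cm$voxel_index, cm$grid_shape)]
  } else {
    labels <- as.integer(parcellation)
    if (length(labels) != nrow(cm$voxel_index))
      stop("label vector must cover every voxel in the matrix")
  }
  labels[is.na(labels)] <- 0L
  keep <- which(labels >= 1L)
  out <- new_conn_matrix(cm$weights[keep, keep, drop = FALSE],
                         cm$voxel_index[keep, , drop = FALSE],
                         "isocortical", cm$grid_shape,
                         labels = labels[keep],
                         zero_variance = intersect(cm$zero_variance, keep))
  out$dropped_voxels <- length(labels) - length(keep)
  out
}
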