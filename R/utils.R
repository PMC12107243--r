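# Grid geometry helpers shared across modules. Voxels are addressed by
# 1-based (x, y, z) grid coordinates; the canonical voxel ordering is
# column-major (x fastest), matching how R linearizes arrays.

#' Enumerate grid coordinates of the in-mask voxels
#'
#' @param mask A logical or 0/1 3-D array; `TRUE`/nonzero marks in-mask
#'   voxels. A 3-vector of dimensions is accepted as shorthand for a full
#'   (all-`TRUE`) mask.
#' @return An integer matrix with one row per in-mask voxel and columns
#'   `x`, `y`, `z`, ordered column-major.
#' @export
mask_coords <- function(mask) {
  if (is.numeric(mask) && is.null(dim(mask)) && length(mask) == 3L) {
    mask <- array(TRUE, dim = as.integer(mask))
  }
  stopifnot(length(dim(mask)) == 3L)
  idx <- which(mask != 0)
  coords <- arrayInd(idx, dim(mask))
  colnames(coords) <- c("x", "y", "z")
  coords
}

coords_to_linear <- function(coords, grid_shape) {
  coords[, 1L] +
    grid_shape[1L] * (coords[, 2L] - 1L) +
    grid_shape[1L] * grid_shape[2L] * (coords[, 3L] - 1L)
}

#' Scatter per-voxel values back onto a 3-D grid
#'
#' @param values Numeric vector, one value per voxel row.
#' @param coords Integer matrix of voxel coordinates (rows match `values`).
#' @param grid_shape Integer 3-vector of grid dimensions.
#' @param fill Value for voxels not covered (default `NA`).
#' @return A 3-D numeric array.
#' @export
values_to_grid <- function(values, coords, grid_shape, fill = NA_real_) {
  arr <- array(fill, dim = grid_shape)
  arr[coords_to_linear(coords, grid_shape)] <- values
  arr
}

# Hemisphere of each voxel: the grid is treated as template space with the
# midline at x = (nx + 1) / 2; voxels strictly left of the midline are
# "left". Midline voxels (odd nx) are assigned to neither hemisphere.
hemisphere_of <- function(coords, grid_shape) {
  mid <- (grid_shape[1L] + 1) / 2
  ifelse(coords[, 1L] < mid, "left", ifelse(coords[, 1L] > mid, "right", NA))
}

#' Tukey fences at 1.5 times the interquartile range
#'
#' Quartiles use the linear-interpolation convention (`quantile()` type 7).
#' Values strictly outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged.
#'
#' @param x Numeric vector.
#' @return A list with `lower`, `upper`, `q1`, `q3` and `outlier`, a logical
#'   vector aligned with `x` (`NA` values are never flagged).
#' @export
iqr_fences <- function(x) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  lower <- q[1L] - 1.5 * iqr
  upper <- q[2L] + 1.5 * iqr
  out <- !is.na(x) & (x < lower | x > upper)
  list(lower = lower, upper = upper, q1 = q[1L], q3 = q[2L], outlier = out)
}

# Column standard deviations with the n - 1 denominator.
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows to compute a standard deviation")
  mu <- colMeans(m)
  sqrt(colSums(sweep(m, 2L, mu)^2) / (n - 1))
}

# Stable t -> z quantile transform: z has the same two-sided tail probability
# under N(0,1) as t under t_df. Log-scale tails keep extreme statistics
# finite and monotone.
t_to_z <- function(t, df) {
  log_upper <- pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE)
  z <- qnorm(log_upper, lower.tail = FALSE, log.p = TRUE)
  sign(t) * z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
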