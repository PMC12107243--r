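# Cross-subject map handling: the map_set container (subjects x voxels),
# subject-level QC on mean weighted degree, age/sex residualization and
# z-scoring against the healthy-control per-voxel distribution.

#' Collect per-subject metric maps into a subjects-by-voxels matrix
#'
#' @param maps Named list of [metric_map] objects (names = subject ids), or
#'   a numeric matrix with subject-id rownames.
#' @param metric,scope,voxel_index,grid_shape Metadata when `maps` is a bare
#'   matrix; inferred from the maps otherwise.
#' @return A `map_set`: `values` (subjects x voxels), `metric`,
#'   `voxel_index`, `scope`, `grid_shape`, `normalized`.
#' @export
map_set <- function(maps, metric = NULL, scope = NULL, voxel_index = NULL,
                    grid_shape = NULL) {
  if (is.matrix(maps)) {
    stopifnot(!is.null(rownames(maps)), !is.null(voxel_index),
              !is.null(grid_shape))
    values <- maps
    metric <- metric %||% "unknown"
    scope <- scope %||% "whole_brain"
    normalized <- FALSE
  } else {
    stopifnot(length(maps) >= 1L, !is.null(names(maps)))
    first <- maps[[1L]]
    values <- do.call(rbind, lapply(maps, function(m) m$values))
    rownames(values) <- names(maps)
    metric <- metric %||% first$metric
    scope <- scope %||% first$scope
    voxel_index <- voxel_index %||% first$voxel_index
    grid_shape <- grid_shape %||% first$grid_shape
    normalized <- first$normalized
  }
  structure(list(values = values, metric = metric, scope = scope,
                 voxel_index = voxel_index,
                 grid_shape = as.integer(grid_shape),
                 normalized = normalized),
            class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat(sprintf("<map_set> %s (%s%s): %d subjects x %d voxels\n", x$metric,
              x$scope, if (x$normalized) ", normalized" else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subject-level weighted-degree outlier QC
#'
#' The subject statistic is the mean of the whole-brain weighted-degree map.
#' Fences are Tukey's at 1.5 IQR (type-7 quartiles) over all pooled
#' subjects; subjects strictly outside the fences are marked
#' `excluded` with reason `wd_outlier`. With fewer than 4 statistics the
#' quartiles are unstable and QC is skipped with a warning.
#'
#' @param subjects Subject tibble with `id`, `qc_status`, `qc_reason`.
#' @param wd_maps A `map_set` of whole-brain weighted degree (or a named
#'   numeric vector of precomputed subject means).
#' @return The subjects tibble with updated QC columns; the per-subject
#'   report is attached as attribute `"qc_report"`.
#' @export
wd_outlier_qc <- function(subjects, wd_maps) {
  stats_vec <- if (inherits(wd_maps, "map_set")) {
    rowMeans(wd_maps$values)
  } else {
    wd_maps
  }
  included <- subjects$qc_status == "included"
  ids <- subjects$id[included]
  stats_vec <- stats_vec[ids]
  if (length(stats_vec) < 4L) {
    warning("fewer than 4 subjects; weighted-degree outlier QC skipped")
    return(subjects)
  }
  f <- iqr_fences(stats_vec)
  report <- tibble::tibble(
    id = ids, statistic = unname(stats_vec),
    lower = f$lower, upper = f$upper,
    decision = ifelse(f$outlier, "excluded", "included"))
  out_ids <- ids[f$outlier]
  subjects$qc_status[subjects$id %in% out_ids] <- "excluded"
  subjects$qc_reason[subjects$id %in% out_ids] <- "wd_outlier"
  attr(subjects, "qc_report") <- report
  subjects
}

# Covariate design for residualization: intercept + requested covariates,
# with sex encoded 0 (F) / 1 (M) and constant columns dropped with warning.
covariate_design <- function(subjects, covariates) {
  n <- nrow(subjects)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  for (cv in covariates) {
    col <- subjects[[cv]]
    if (is.null(col)) stop(sprintf("covariate '%s' missing from subjects", cv))
    if (cv == "sex" || is.character(col) || is.factor(col)) {
      col <- as.numeric(factor(col)) - 1
    }
    col <- as.numeric(col)
    if (anyNA(col))
      stop(sprintf("covariate '%s' incomplete for included subjects", cv))
    if (length(unique(col)) < 2L) {
      warning(sprintf("covariate '%s' is constant; dropped", cv))
      next
    }
    X <- cbind(X, setNames(data.frame(col), cv)[[1L]])
    colnames(X)[ncol(X)] <- cv
  }
  X
}

#' Remove covariate effects from metric maps
#'
#' Per voxel, an OLS of map value on `[1, covariates]` is fitted over the
#' QC-included subjects of the map set (all groups pooled), and residuals
#' replace the values. Pooled fitting keeps the subsequent healthy-control
#' mean/SD interpretable; set `fit_on` to `"HC"` to fit the model on healthy
#' controls only and apply it to everyone.
#'
#' @param maps A `map_set`.
#' @param subjects Subject tibble (`id`, `qc_status`, covariate columns).
#' @param covariates Character vector (default `c("age", "sex")`).
#' @param fit_on `"pooled"` (default) or `"HC"`.
#' @return The `map_set` with residualized values (included subjects only).
#' @export
residualize_covariates <- function(maps, subjects,
                                   covariates = c("age", "sex"),
                                   fit_on = c("pooled", "HC")) {
  stopifnot(inherits(maps, "map_set"))
  fit_on <- match.arg(fit_on)
  keep <- subjects$id[subjects$qc_status == "included"]
  keep <- intersect(rownames(maps$values), keep)
  sub <- subjects[match(keep, subjects$id), ]
  Y <- maps$values[keep, , drop = FALSE]
  X <- covariate_design(sub, covariates)
  fit_rows <- if (fit_on == "HC") which(sub$group == "HC") else seq_len(nrow(X))
  if (length(fit_rows) <= ncol(X))
    stop("not enough subjects to fit the covariate model")
  Xf <- X[fit_rows, , drop = FALSE]
  beta <- solve(crossprod(Xf), crossprod(Xf, Y[fit_rows, , drop = FALSE]))
  maps$values <- Y - X %*% beta
  maps
}

#' Normalize subject maps to the healthy-control distribution
#'
#' Every subject's value at voxel i becomes
#' `(value - mean over HC at i) / SD over HC at i` (sample SD, n - 1
#' denominator). By construction the HC subjects' normalized values have
#' per-voxel mean 0 and SD 1. Voxels with zero HC SD are flagged and set to
#' 0 for all subjects.
#'
#' @param maps A `map_set` (typically residualized first).
#' @param subjects Subject tibble with `group` and `qc_status`.
#' @return The `map_set` with `normalized = TRUE` and attribute
#'   `"zero_sd_voxels"`.
#' @export
normalize_to_hc <- function(maps, subjects) {
  stopifnot(inherits(maps, "map_set"))
  keep <- subjects$id[subjects$qc_status == "included"]
  keep <- intersect(rownames(maps$values), keep)
  sub <- subjects[match(keep, subjects$id), ]
  hc_ids <- sub$id[sub$group == "HC"]
  if (length(hc_ids) < 2L)
    stop("need at least 2 included HC subjects for normalization")
  Y <- maps$values[keep, , drop = FALSE]
  hc <- Y[hc_ids, , drop = FALSE]
  mu <- colMeans(hc)
  sdv <- col_sds(hc)
  bad <- which(sdv <= 0)
  sdv[bad] <- 1
  Z <- sweep(sweep(Y, 2L, mu), 2L, sdv, "/")
  if (length(bad)) {
    warning(sprintf("%d voxel(s) with zero HC SD set to 0", length(bad)))
    Z[, bad] <- 0
  }
  maps$values <- Z
  maps$normalized <- TRUE
  attr(maps, "zero_sd_voxels") <- bad
  maps
}
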