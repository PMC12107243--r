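# Group inference: voxel-wise GLM contrasts on normalized maps, cluster
# extraction at a z threshold, a Monte Carlo (group-label permutation) null
# for the maximum cluster extent, and clusterwise correction.

build_contrast_design <- function(maps, subjects, groups, covariates) {
  stopifnot(inherits(maps, "map_set"), length(groups) == 2L)
  keep <- subjects$id[subjects$qc_status == "included" &
                        subjects$group %in% groups]
  keep <- intersect(rownames(maps$values), keep)
  sub <- subjects[match(keep, subjects$id), ]
  n_a <- sum(sub$group == groups[1L])
  n_b <- sum(sub$group == groups[2L])
  if (n_a < 3L || n_b < 3L)
    stop("need at least 3 included subjects per group")
  Y <- maps$values[keep, , drop = FALSE]
  g <- as.numeric(sub$group == groups[1L])
  Z <- covariate_design(sub, covariates)
  list(Y = Y, g = g, Z = Z, subjects = sub,
       n_per_group = c(n_a, n_b))
}

# Exact OLS t-statistics for the group coefficient in Y ~ [Z, g], via the
# Frisch-Waugh-Lovell identity (Z includes the intercept).
glm_group_t <- function(Y, Z, g) {
  n <- nrow(Y)
  df <- n - ncol(Z) - 1L
  if (df < 1L) stop("singular or over-saturated design")
  P <- Z %*% solve(crossprod(Z))
  Yres <- Y - P %*% crossprod(Z, Y)
  gres <- g - P %*% crossprod(Z, g)
  gg <- sum(gres^2)
  if (gg < 1e-12) stop("group indicator collinear with covariates")
  b <- drop(crossprod(gres, Yres)) / gg
  rss <- pmax(colSums(Yres^2) - b^2 * gg, 1e-300)
  t <- b * sqrt(gg * df / rss)
  list(t = t, df = df, beta = b)
}

#' Voxel-wise GLM group contrast
#'
#' Per voxel, an OLS of the normalized map value on
#' `[1, group indicator, covariates]` is fitted over the included subjects
#' of the two contrasted groups; the group t-statistic is mapped to a
#' z-statistic through the t -> z quantile transform at the residual
#' degrees of freedom. Healthy controls define normalization only and never
#' enter contrasts.
#'
#' @param maps A normalized `map_set`.
#' @param subjects Subject tibble.
#' @param groups Length-2 character vector `(A, B)`; positive z means
#'   A > B.
#' @param covariates Covariate names adjusted in the GLM (default `ssri`;
#'   age and sex are removed upstream).
#' @return A `zmap` object: `z`, `t`, `df`, `voxel_index`, `grid_shape`,
#'   `groups`, `covariates`, `n_per_group`, `metric`.
#' @export
glm_contrast <- function(maps, subjects, groups = c("FND", "PC"),
                         covariates = "ssri") {
  d <- build_contrast_design(maps, subjects, groups, covariates)
  fit <- glm_group_t(d$Y, d$Z, d$g)
  structure(list(z = t_to_z(fit$t, fit$df), t = fit$t, df = fit$df,
                 voxel_index = maps$voxel_index,
                 grid_shape = maps$grid_shape, groups = groups,
                 covariates = covariates, n_per_group = d$n_per_group,
                 metric = maps$metric),
            class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat(sprintf("<zmap> %s: %s vs %s (n=%d/%d), %d voxels, df=%d\n",
              x$metric, x$groups[1L], x$groups[2L], x$n_per_group[1L],
              x$n_per_group[2L], length(x$z), x$df))
  invisible(x)
}

#' Extract suprathreshold clusters from a z-map
#'
#' Voxels with `z > threshold` (and, when two-sided, `z < -threshold` as a
#' separate sign group) are partitioned into connected components under the
#' requested connectivity rule (26 by default; 6 = faces only).
#'
#' @param zmap A `zmap`.
#' @param threshold Cluster-forming z threshold (default 1.96).
#' @param two_sided Also form negative clusters (default TRUE).
#' @param connectivity 26 or 6.
#' @return A `cluster_set`: tibble `clusters` (id, sign, extent, peak_z,
#'   peak coordinates, `voxels` list-column of voxel rows) sorted by extent,
#'   plus the extraction parameters.
#' @export
cluster_extract <- function(zmap, threshold = 1.96, two_sided = TRUE,
                            connectivity = 26L) {
  stopifnot(inherits(zmap, "zmap"), connectivity %in% c(6L, 26L))
  sgn <- integer(length(zmap$z))
  sgn[zmap$z > threshold] <- 1L
  if (two_sided) sgn[zmap$z < -threshold] <- -1L
  labels <- cpp_label_components(zmap$voxel_index, zmap$grid_shape, sgn,
                                 as.integer(connectivity))
  rows <- split(which(labels > 0L), labels[labels > 0L])
  clusters <- lapply(rows, function(vx) {
    zi <- zmap$z[vx]
    pk <- vx[which.max(abs(zi))]
    tibble::tibble(sign = sgn[vx[1L]], extent = length(vx),
                   peak_z = zmap$z[pk],
                   peak_x = zmap$voxel_index[pk, 1L],
                   peak_y = zmap$voxel_index[pk, 2L],
                   peak_z_coord = zmap$voxel_index[pk, 3L],
                   voxels = list(vx))
  })
  tab <- if (length(clusters)) dplyr::bind_rows(clusters) else
    tibble::tibble(sign = integer(), extent = integer(), peak_z = numeric(),
                   peak_x = integer(), peak_y = integer(),
                   peak_z_coord = integer(), voxels = list())
  tab <- tab[order(-tab$extent), , drop = FALSE]
  tab$cluster_id <- seq_len(nrow(tab))
  tab <- tab[, c("cluster_id", setdiff(names(tab), "cluster_id"))]
  structure(list(clusters = tab,
                 params = list(threshold = threshold, two_sided = two_sided,
                               connectivity = as.integer(connectivity))),
            class = "cluster_set")
}

#' Monte Carlo null distribution of the maximum cluster extent
#'
#' Each iteration permutes the group labels across the contrasted subjects
#' (covariates stay attached to their subjects), refits the voxel-wise GLM
#' exactly, and records the largest suprathreshold cluster extent. The
#' resulting distribution is the reference for corrected cluster p-values
#' `p = (1 + #\{null max >= extent\}) / (1 + n_iter)`.
#'
#' @inheritParams glm_contrast
#' @inheritParams cluster_extract
#' @param n_iter Number of permutations (default 10000, as used for the
#'   published maps; tests use fewer).
#' @param seed Optional integer seed for reproducibility.
#' @return A `cluster_null`: `max_extents` plus all identifying parameters.
#' @export
monte_carlo_null <- function(maps, subjects, groups = c("FND", "PC"),
                             covariates = "ssri", threshold = 1.96,
                             two_sided = TRUE, connectivity = 26L,
                             n_iter = 10000L, seed = NULL) {
  if (n_iter < 100L)
    warning("fewer than 100 iterations gives an unstable null tail")
  d <- build_contrast_design(maps, subjects, groups, covariates)
  df <- nrow(d$Y) - ncol(d$Z) - 1L
  t_thresh <- qt(pnorm(threshold), df)
  if (!is.null(seed)) set.seed(seed)
  ext <- cpp_perm_null(d$Y, d$Z, d$g, maps$voxel_index, maps$grid_shape,
                       t_thresh, two_sided, as.integer(connectivity),
                       as.integer(n_iter))
  structure(list(max_extents = as.integer(ext),
                 params = list(threshold = threshold, two_sided = two_sided,
                               connectivity = as.integer(connectivity),
                               n_iter = as.integer(n_iter), df = df,
                               groups = groups, covariates = covariates,
                               seed = seed)),
            class = "cluster_null")
}

#' Clusterwise correction against a Monte Carlo null
#'
#' Every observed cluster receives a corrected p-value from the null
#' distribution of maximum extents (the +1 convention keeps p > 0);
#' clusters with `p < alpha` form the corrected mask. The null must have
#' been built with the same threshold, sidedness and connectivity.
#'
#' @param zmap The observed `zmap`.
#' @param clusters A `cluster_set` from [cluster_extract()].
#' @param null A `cluster_null` from [monte_carlo_null()].
#' @param alpha Familywise alpha (default 0.05).
#' @return A `group_inference` object: `zmap`, `clusters` tibble with
#'   `p_corrected` and `significant`, `corrected_mask` (logical per voxel),
#'   `null`, `params`.
#' @export
correct_clusters <- function(zmap, clusters, null, alpha = 0.05) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(null, "cluster_null"))
  for (p in c("threshold", "two_sided", "connectivity")) {
    if (!identical(clusters$params[[p]], null$params[[p]]))
      stop(sprintf("cluster and null '%s' parameters differ; refusing", p))
  }
  tab <- clusters$clusters
  n_iter <- null$params$n_iter
  tab$p_corrected <- vapply(tab$extent, function(e) {
    (1 + sum(null$max_extents >= e)) / (1 + n_iter)
  }, numeric(1L))
  tab$significant <- tab$p_corrected < alpha
  mask <- logical(length(zmap$z))
  for (vx in tab$voxels[tab$significant]) mask[vx] <- TRUE
  structure(list(zmap = zmap, clusters = tab, corrected_mask = mask,
                 null = null,
                 params = c(clusters$params,
                            list(alpha = alpha, n_iter = n_iter))),
            class = "group_inference")
}

#' @export
print.group_inference <- function(x, ...) {
  n_sig <- sum(x$clusters$significant)
  cat(sprintf(
    "<group_inference> %s: %s vs %s; %d cluster(s), %d significant at alpha=%g\n",
    x$zmap$metric, x$zmap$groups[1L], x$zmap$groups[2L],
    nrow(x$clusters), n_sig, x$params$alpha))
  invisible(x)
}

#' Run a full contrast: GLM, clusters, Monte Carlo null, correction
#'
#' @inheritParams glm_contrast
#' @inheritParams monte_carlo_null
#' @param alpha Familywise alpha.
#' @return A `group_inference` object.
#' @export
run_contrast <- function(maps, subjects, groups = c("FND", "PC"),
                         covariates = "ssri", threshold = 1.96,
                         two_sided = TRUE, connectivity = 26L,
                         n_iter = 10000L, alpha = 0.05, seed = NULL) {
  zm <- glm_contrast(maps, subjects, groups, covariates)
  cl <- cluster_extract(zm, threshold, two_sided, connectivity)
  nl <- monte_carlo_null(maps, subjects, groups, covariates, threshold,
                         two_sided, connectivity, n_iter, seed)
  correct_clusters(zm, cl, nl, alpha)
}

#' Voxel-wise intersection of corrected masks
#'
#' Logical AND across corrected masks from several analyses or covariate
#' adjustments, identifying voxels that hold across all of them.
#'
#' @param masks List of logical vectors (or `group_inference` objects) on
#'   the same voxel set.
#' @return A logical vector.
#' @export
intersection_map <- function(masks) {
  masks <- lapply(masks, function(m) {
    if (inherits(m, "group_inference")) m$corrected_mask else as.logical(m)
  })
  len <- unique(vapply(masks, length, integer(1L)))
  if (length(len) != 1L) stop("masks are on different voxel grids")
  Reduce(`&`, masks)
}

#' @export
tidy.group_inference <- function(x, ...) {
  dplyr::select(x$clusters, -"voxels")
}

#' @export
glance.group_inference <- function(x, ...) {
  tibble::tibble(metric = x$zmap$metric, group_a = x$zmap$groups[1L],
                 group_b = x$zmap$groups[2L],
                 n_a = x$zmap$n_per_group[1L], n_b = x$zmap$n_per_group[2L],
                 df = x$zmap$df, n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$significant),
                 threshold = x$params$threshold,
                 connectivity = x$params$connectivity,
                 n_iter = x$params$n_iter, alpha = x$params$alpha)
}
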