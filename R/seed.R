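# Integration-peak seed-to-voxel connectivity: peak selection inside the
# corrected and intersection masks, 27-voxel cube ROIs, Fisher r-to-z seed
# maps, group contrast and seven-network composition of significant voxels.

#' Find one peak voxel per hemisphere
#'
#' Within each hemisphere, the voxel of maximal z among voxels inside
#' `corrected_mask` (and `intersection_mask`, when given). Ties break to the
#' lowest voxel index (lexicographic grid coordinate). Hemispheres are
#' split at the grid midline; a hemisphere with no eligible voxel is
#' skipped with a warning.
#'
#' @param zmap A `zmap`.
#' @param corrected_mask Logical per-voxel mask (or `group_inference`).
#' @param intersection_mask Optional additional logical mask.
#' @return Named list (`left`, `right`) of voxel row indices (entries
#'   absent for skipped hemispheres).
#' @export
find_peaks <- function(zmap, corrected_mask, intersection_mask = NULL) {
  stopifnot(inherits(zmap, "zmap"))
  if (inherits(corrected_mask, "group_inference"))
    corrected_mask <- corrected_mask$corrected_mask
  eligible <- corrected_mask
  if (!is.null(intersection_mask)) eligible <- eligible & intersection_mask
  hemi <- hemisphere_of(zmap$voxel_index, zmap$grid_shape)
  out <- list()
  for (h in c("left", "right")) {
    cand <- which(eligible & !is.na(hemi) & hemi == h)
    if (!length(cand)) {
      warning(sprintf("no eligible voxel in %s hemisphere; skipped", h))
      next
    }
    out[[h]] <- cand[which.max(zmap$z[cand])]
  }
  out
}

#' Build a seed region of interest around a peak voxel
#'
#' The member set is the 3x3x3 voxel neighbourhood of the peak (Chebyshev
#' radius 1) intersected with the available voxels: 27 members for an
#' interior peak, fewer at mask edges (kept, not recentred).
#'
#' @param peak Voxel row index of the peak.
#' @param voxel_index Voxel coordinate matrix the row refers to.
#' @param grid_shape Grid dimensions.
#' @return A `seed_roi`: `centre` (row), `centre_coord`, `member_voxels`
#'   (rows), `hemisphere`.
#' @export
build_seed <- function(peak, voxel_index, grid_shape) {
  centre <- voxel_index[peak, ]
  cheb <- apply(abs(sweep(voxel_index, 2L, centre)), 1L, max)
  members <- which(cheb <= 1L)
  structure(list(centre = peak, centre_coord = centre,
                 member_voxels = members,
                 hemisphere = hemisphere_of(rbind(centre), grid_shape)),
            class = "seed_roi")
}

#' @export
print.seed_roi <- function(x, ...) {
  cat(sprintf("<seed_roi> centre (%s), %d member voxel(s), %s hemisphere\n",
              paste(x$centre_coord, collapse = ", "),
              length(x$member_voxels), x$hemisphere %||% "?"))
  invisible(x)
}

#' Seed-to-voxel Fisher-z connectivity map
#'
#' Pearson correlation between the mean series over the seed members and
#' every other voxel series, passed through the Fisher r-to-z transform
#' `atanh(r)`. Correlations at +-1 are clipped to +-(1 - 1e-7) first. Seed
#' member voxels are excluded from the map.
#'
#' @param ts A cleaned `voxel_ts`.
#' @param seed A `seed_roi`.
#' @param voxel_rows Optional voxel rows to map over (e.g. isocortical
#'   voxels); defaults to all voxels. Seed members are always removed.
#' @return List: `values` (Fisher z), `voxel_rows` (rows of `ts$voxel_index`
#'   the values refer to), `seed`.
#' @export
seed_to_voxel <- function(ts, seed, voxel_rows = NULL) {
  stopifnot(inherits(ts, "voxel_ts"), inherits(seed, "seed_roi"))
  if (is.null(voxel_rows)) voxel_rows <- seq_len(ncol(ts$data))
  voxel_rows <- setdiff(voxel_rows, seed$member_voxels)
  seed_series <- rowMeans(ts$data[, seed$member_voxels, drop = FALSE])
  r <- drop(cor(seed_series, ts$data[, voxel_rows, drop = FALSE]))
  clip <- 1 - 1e-7
  r <- pmin(clip, pmax(-clip, r))
  list(values = atanh(r), voxel_rows = voxel_rows, seed = seed)
}

#' Group contrast on seed maps with seven-network composition
#'
#' Runs the standard GLM + Monte Carlo clusterwise machinery on per-subject
#' seed connectivity maps, then labels each significant positive-contrast
#' voxel by its network and reports the percentage falling in each of the
#' six networks other than the seed's own (the seed network's connections
#' are not integration-relevant). The seed's network is the parcellation
#' label of its peak voxel.
#'
#' @param seed_maps A `map_set` of per-subject Fisher-z seed maps.
#' @param subjects Subject tibble.
#' @param labels Integer network labels aligned with the map voxels.
#' @param seed_label Network label of the seed's peak voxel.
#' @inheritParams run_contrast
#' @return List: `result` (`group_inference`) and `composition` tibble
#'   (network label, name, n_voxels, percent).
#' @export
seed_glm_and_compose <- function(seed_maps, subjects, labels, seed_label,
                                 groups = c("FND", "PC"),
                                 covariates = "ssri", threshold = 1.96,
                                 connectivity = 26L, n_iter = 10000L,
                                 alpha = 0.05, seed = NULL) {
  res <- run_contrast(seed_maps, subjects, groups, covariates, threshold,
                      two_sided = TRUE, connectivity = connectivity,
                      n_iter = n_iter, alpha = alpha, seed = seed)
  sig_pos <- res$corrected_mask & res$zmap$z > 0
  composition <- network_composition(labels[sig_pos], labels, seed_label)
  list(result = res, composition = composition,
       excluded_network = seed_label)
}

#' Seven-network composition of a set of significant voxels
#'
#' Percentage of significant voxels falling in each network other than the
#' seed's own; seed-network voxels are excluded from both numerator and
#' denominator. Percentages sum to 100 whenever any eligible voxel exists.
#'
#' @param sig_labels Network labels of the significant voxels.
#' @param all_labels Network labels of every voxel in the analysis (defines
#'   which networks exist).
#' @param seed_label The excluded (seed) network label.
#' @return Tibble: `network`, `name`, `n_voxels`, `percent`.
#' @export
network_composition <- function(sig_labels, all_labels, seed_label) {
  sig_labels <- sig_labels[sig_labels != seed_label & sig_labels >= 1L]
  others <- setdiff(sort(unique(all_labels[all_labels >= 1L])), seed_label)
  counts <- vapply(others, function(l) sum(sig_labels == l), integer(1L))
  total <- sum(counts)
  nm <- network_names()
  tibble::tibble(
    network = others,
    name = unname(nm[as.character(others)]),
    n_voxels = counts,
    percent = if (total > 0) 100 * counts / total else rep(0, length(counts)))
}
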