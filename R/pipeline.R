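# End-to-end orchestration: denoise every subject, build connectivity
# matrices and the three metric maps, apply QC, residualize and normalize,
# then contrast groups with clusterwise correction.

#' Analysis parameters
#'
#' Defaults follow the published analysis: FD scrubbing at 0.5 mm, 120
#' retained volumes, 0.01-0.08 Hz pass band, cluster-forming z = 1.96,
#' 10 000 Monte Carlo iterations at alpha 0.05 with 26-connectivity.
#'
#' @param fd_threshold_mm,n_volumes,band,cluster_forming,n_iter,alpha,connectivity,seed
#'   See description.
#' @param covariates Covariates adjusted in group GLMs (default `ssri`).
#' @param residual_covariates Covariates removed before normalization.
#' @return A named list of parameters.
#' @export
analysis_params <- function(fd_threshold_mm = 0.5, n_volumes = 120L,
                            band = c(0.01, 0.08), cluster_forming = 1.96,
                            n_iter = 10000L, alpha = 0.05,
                            connectivity = 26L, seed = 1L,
                            covariates = "ssri",
                            residual_covariates = c("age", "sex")) {
  stopifnot(fd_threshold_mm > 0, n_volumes >= 3L, length(band) == 2L,
            band[1L] > 0, band[1L] < band[2L], cluster_forming > 0,
            n_iter >= 1L, alpha > 0, alpha < 1,
            connectivity %in% c(6L, 26L))
  list(fd_threshold_mm = fd_threshold_mm, n_volumes = as.integer(n_volumes),
       band = band, cluster_forming = cluster_forming,
       n_iter = as.integer(n_iter), alpha = alpha,
       connectivity = as.integer(connectivity), seed = as.integer(seed),
       covariates = covariates, residual_covariates = residual_covariates)
}

#' Denoise every subject of a cohort
#'
#' Runs [prep_subject()] per subject; subjects with fewer than
#' `params$n_volumes` usable volumes are marked excluded with reason
#' `"motion"`. When the parcellation has label-0 voxels, two disjoint
#' halves of them serve as the noise-tissue sets for the compcor-style
#' confounds.
#'
#' @param cohort A `synth_cohort` (or compatible list).
#' @param params [analysis_params()].
#' @return List: `ts` (named list of cleaned `voxel_ts`), `subjects`
#'   (updated QC).
#' @export
prep_cohort <- function(cohort, params = analysis_params()) {
  subjects <- cohort$subjects
  labels0 <- which(cohort$parcellation == 0L & cohort$mask != 0)
  compcor_sets <- NULL
  if (length(labels0) >= 4L) {
    half <- seq_along(labels0) <= length(labels0) / 2
    m1 <- array(FALSE, dim = dim(cohort$mask)); m1[labels0[half]] <- TRUE
    m2 <- array(FALSE, dim = dim(cohort$mask)); m2[labels0[!half]] <- TRUE
    compcor_sets <- list(lv = m1, wm = m2)
  }
  ts <- list()
  for (id in subjects$id) {
    res <- prep_subject(cohort$images[[id]], cohort$motion_tables[[id]],
                        cohort$mask, cohort$config$tr_seconds,
                        fd_threshold_mm = params$fd_threshold_mm,
                        n_keep = params$n_volumes, band = params$band,
                        compcor_sets = compcor_sets)
    if (inherits(res, "subject_exclusion")) {
      subjects$qc_status[subjects$id == id] <- "excluded"
      subjects$qc_reason[subjects$id == id] <- res$reason
    } else {
      ts[[id]] <- res
    }
  }
  list(ts = ts, subjects = subjects)
}

#' Compute the three metric map sets for a cohort
#'
#' Per subject: Pearson matrix, negative removal, whole-brain weighted
#' degree; isocortical restriction, integration and segregation.
#'
#' @param ts Named list of cleaned `voxel_ts`.
#' @param parcellation 3-D label array.
#' @return List of `map_set`: `weighted_degree`, `integration`,
#'   `segregation`.
#' @export
cohort_metric_maps <- function(ts, parcellation) {
  wd <- list(); integ <- list(); seg <- list()
  for (id in names(ts)) {
    cm <- remove_negatives(pearson_matrix(ts[[id]]))
    wd[[id]] <- weighted_degree(cm, subject = id)
    iso <- restrict_isocortex(cm, parcellation)
    integ[[id]] <- integration(iso, subject = id)
    seg[[id]] <- segregation(iso, subject = id)
  }
  list(weighted_degree = map_set(wd), integration = map_set(integ),
       segregation = map_set(seg))
}

#' Run the full group analysis on a cohort
#'
#' Denoising, connectivity, metric maps, two-stage QC (motion then
#' weighted-degree outliers), age/sex residualization, HC normalization and
#' the group contrast with Monte Carlo clusterwise correction for each of
#' the three metrics.
#'
#' @param cohort A `synth_cohort` or a directory written by
#'   [write_cohort()].
#' @param params [analysis_params()].
#' @param groups Contrast groups (default FND vs PC).
#' @return A `pipeline_result`: `subjects`, `maps` (normalized map sets),
#'   `results` (per-metric `group_inference`), `ts`, `params`.
#' @export
run_pipeline <- function(cohort, params = analysis_params(),
                         groups = c("FND", "PC")) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  prep <- prep_cohort(cohort, params)
  maps <- cohort_metric_maps(prep$ts, cohort$parcellation)
  subjects <- wd_outlier_qc(prep$subjects, maps$weighted_degree)
  norm_maps <- lapply(maps, function(m) {
    normalize_to_hc(
      residualize_covariates(m, subjects, params$residual_covariates),
      subjects)
  })
  results <- list()
  for (metric in names(norm_maps)) {
    results[[metric]] <- run_contrast(
      norm_maps[[metric]], subjects, groups,
      covariates = params$covariates,
      threshold = params$cluster_forming, two_sided = TRUE,
      connectivity = params$connectivity, n_iter = params$n_iter,
      alpha = params$alpha, seed = params$seed)
  }
  structure(list(subjects = subjects, maps = norm_maps, results = results,
                 ts = prep$ts, parcellation = cohort$parcellation,
                 params = params, groups = groups),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s vs %s; %d included subject(s)\n",
              x$groups[1L], x$groups[2L],
              sum(x$subjects$qc_status == "included")))
  for (m in names(x$results)) {
    cl <- x$results[[m]]$clusters
    cat(sprintf("  %-16s %d cluster(s), %d significant\n", m, nrow(cl),
                sum(cl$significant)))
  }
  invisible(x)
}
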