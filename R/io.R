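# On-disk formats: NIfTI-1 volumes via RNifti, tab-separated tables with a
# header row, and JSON for configuration and effect truth.

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' @param x Numeric/integer array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param tr_seconds Optional TR recorded in the header for 4-D images.
#' @return The path, invisibly.
#' @export
write_nifti <- function(x, path, tr_seconds = NULL) {
  img <- RNifti::asNifti(x)
  if (!is.null(tr_seconds) && length(dim(x)) == 4L) {
    RNifti::pixdim(img) <- c(1, 1, 1, tr_seconds)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path Input path.
#' @return An array (header dropped).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("input not found: %s", path))
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("input not found: %s", path))
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to a directory
#'
#' Lays out one 4-D NIfTI and one motion TSV per subject, the mask and
#' parcellation NIfTI volumes, the subjects TSV, the configuration and the
#' effect-truth JSON.
#'
#' @param cohort A `synth_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest of written files.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory: %s", out_dir))
  files <- list()
  add <- function(kind, path) {
    files[[length(files) + 1L]] <<- tibble::tibble(kind = kind, path = path)
  }
  for (id in names(cohort$images)) {
    p <- file.path(out_dir, paste0(id, "_bold.nii.gz"))
    write_nifti(cohort$images[[id]], p,
                tr_seconds = cohort$config$tr_seconds)
    add("image", p)
    m <- file.path(out_dir, paste0(id, "_motion.tsv"))
    write_tsv(cohort$motion_tables[[id]], m)
    add("motion", m)
  }
  p <- file.path(out_dir, "mask.nii.gz")
  write_nifti(cohort$mask, p); add("mask", p)
  p <- file.path(out_dir, "parcellation.nii.gz")
  write_nifti(cohort$parcellation, p); add("parcellation", p)
  p <- file.path(out_dir, "subjects.tsv")
  write_tsv(cohort$subjects[, c("id", "group", "age", "sex", "ssri",
                                "sdq20", "phq15", "sim_id")], p)
  add("subjects", p)
  p <- file.path(out_dir, "truth.json")
  jsonlite::write_json(lapply(cohort$truth, unclass), p, auto_unbox = TRUE,
                       digits = NA, null = "null")
  add("truth", p)
  p <- file.path(out_dir, "config.json")
  cfg <- unclass(cohort$config)
  cfg$effects <- lapply(cfg$effects, unclass)
  cfg$group_sizes <- as.list(cfg$group_sizes)
  jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA)
  add("config", p)
  dplyr::bind_rows(files)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A `synth_cohort` (images/motion reloaded from disk).
#' @export
read_cohort <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  effects <- read_truth(file.path(dir, "truth.json"))
  config <- synth_config(
    grid_shape = cfg$grid_shape, n_timepoints = cfg$n_timepoints,
    tr_seconds = cfg$tr_seconds, n_networks = cfg$n_networks,
    group_sizes = unlist(cfg$group_sizes), effects = effects,
    noise_sd = cfg$noise_sd, base_within_corr = cfg$base_within_corr,
    base_between_corr = cfg$base_between_corr,
    label0_frac = cfg$label0_frac, n_motion_spikes = cfg$n_motion_spikes,
    seed = cfg$seed)
  subjects <- tibble::as_tibble(read_tsv_file(file.path(dir, "subjects.tsv")))
  subjects$qc_status <- "included"
  subjects$qc_reason <- NA_character_
  images <- list(); motions <- list()
  for (id in subjects$id) {
    images[[id]] <- read_nifti(file.path(dir, paste0(id, "_bold.nii.gz")))
    motions[[id]] <- read_tsv_file(file.path(dir, paste0(id, "_motion.tsv")))
  }
  structure(list(images = images, motion_tables = motions,
                 mask = read_nifti(file.path(dir, "mask.nii.gz")),
                 parcellation = read_nifti(file.path(dir,
                                                     "parcellation.nii.gz")),
                 subjects = subjects, truth = effects, config = config),
            class = "synth_cohort")
}

#' Read an effect-truth JSON back into effect specs
#'
#' @param path Path to `truth.json`.
#' @return List of `effect_spec` objects.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(e) {
    link <- e$covariate_link
    if (length(link) == 0L) link <- NULL
    effect_spec(e$target_group, unlist(e$region), e$mode, e$delta_corr,
                if (is.null(link)) NULL else list(link$covariate, link$slope))
  })
}
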