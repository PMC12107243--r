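# Synthetic-cohort generator. Voxel time series are drawn from a
# multivariate normal whose correlation matrix carries the seven-network
# block structure the analysis assumes (within-network pairs more correlated
# than between-network pairs), optionally perturbed by group- or
# covariate-linked effects on chosen edges. Motion tables carry mostly
# sub-threshold jitter plus configurable translation steps that exceed the
# scrubbing threshold. The generator defines the statistical conditions the
# test-suite exercises; it makes no attempt at haemodynamics, spatial noise
# autocorrelation or physiological confounds.

#' Specify an injected connectivity effect
#'
#' An effect adds `delta_corr` to the target correlation of a set of edges
#' incident to `region`, for subjects of `target_group`:
#' `between_network_gain` affects edges from region voxels to voxels in a
#' different network, `within_network_gain` edges to same-network voxels,
#' and `global_gain` all edges incident to the region. An optional
#' `covariate_link` `(name, slope)` makes the added correlation vary with a
#' subject covariate: `delta + slope * (covariate - cohort mean)`.
#'
#' @param target_group Group label the effect applies to.
#' @param region Integer vector of voxel rows (mask ordering).
#' @param mode One of `"between_network_gain"`, `"within_network_gain"`,
#'   `"global_gain"`.
#' @param delta_corr Correlation added to affected edges.
#' @param covariate_link Optional list/vector `(covariate, slope)`.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(target_group, region, mode, delta_corr,
                        covariate_link = NULL) {
  mode <- match.arg(mode, c("between_network_gain", "within_network_gain",
                            "global_gain"))
  if (!is.null(covariate_link)) {
    covariate_link <- list(covariate = as.character(covariate_link[[1L]]),
                           slope = as.numeric(covariate_link[[2L]]))
  }
  structure(list(target_group = target_group,
                 region = as.integer(region), mode = mode,
                 delta_corr = as.numeric(delta_corr),
                 covariate_link = covariate_link),
            class = "effect_spec")
}

#' Synthetic-cohort configuration
#'
#' Defaults describe a desk-scale cohort with detectable network block
#' structure: a 12x12x12 grid, 160 acquired volumes at TR 2 s (enough to
#' survive scrubbing and still retain 120), within-network correlation 0.3
#' versus 0.1 between networks, and observation noise SD 0.2.
#'
#' @param grid_shape Voxel counts per axis.
#' @param n_timepoints Acquired volumes per subject (>= 120).
#' @param tr_seconds Repetition time.
#' @param n_networks Number of networks in the parcellation (default 7).
#' @param group_sizes Named vector of subjects per group.
#' @param effects List of [effect_spec()] objects.
#' @param noise_sd Observation-noise SD added on top of the unit-variance
#'   network signal.
#' @param base_within_corr,base_between_corr Baseline correlations for
#'   within- and between-network voxel pairs; must satisfy
#'   `0 <= between < within < 1`.
#' @param label0_frac Fraction of the mask labelled 0 ("non-isocortical").
#' @param n_motion_spikes Translation steps per subject exceeding the 0.5 mm
#'   scrubbing threshold.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(grid_shape = c(12L, 12L, 12L), n_timepoints = 160L,
                         tr_seconds = 2, n_networks = 7L,
                         group_sizes = c(FND = 30L, PC = 30L, HC = 30L),
                         effects = list(), noise_sd = 0.2,
                         base_within_corr = 0.3, base_between_corr = 0.1,
                         label0_frac = 0.1, n_motion_spikes = 2L, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            n_timepoints >= 120L, tr_seconds > 0, n_networks >= 1L,
            all(group_sizes > 0L), !is.null(names(group_sizes)),
            noise_sd > 0, base_within_corr > 0, base_within_corr < 1,
            base_between_corr >= 0,
            base_between_corr < base_within_corr,
            label0_frac >= 0, label0_frac < 1)
  if (prod(grid_shape) < n_networks)
    stop("grid too small: fewer voxels than networks")
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  structure(list(grid_shape = as.integer(grid_shape),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, n_networks = as.integer(n_networks),
                 group_sizes = group_sizes, effects = effects,
                 noise_sd = noise_sd, base_within_corr = base_within_corr,
                 base_between_corr = base_between_corr,
                 label0_frac = label0_frac,
                 n_motion_spikes = as.integer(n_motion_spikes),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Recursively bisect a box into n axis-aligned sub-boxes with voxel counts
# as equal as possible. Returns a list of boxes (each a 2x3 range matrix).
split_box <- function(box, n) {
  if (n == 1L) return(list(box))
  extents <- box[2L, ] - box[1L, ] + 1L
  if (all(extents == 1L))
    stop("grid too small to partition into contiguous networks")
  n1 <- n %/% 2L
  axis <- which.max(extents)
  cut <- round(extents[axis] * n1 / n)
  cut <- max(1L, min(extents[axis] - 1L, cut))
  b1 <- box; b1[2L, axis] <- box[1L, axis] + cut - 1L
  b2 <- box; b2[1L, axis] <- box[1L, axis] + cut
  c(split_box(b1, n1), split_box(b2, n - n1))
}

#' Build a contiguous-block network parcellation
#'
#' Partitions the grid into `n_networks` spatially contiguous axis-aligned
#' blocks (labels 1..n) by recursive bisection, after optionally carving a
#' contiguous slab of about `label0_frac` of the voxels as label 0
#' ("non-isocortical" tissue inside the whole-brain mask). `seed` shuffles
#' which block receives which label.
#'
#' @inheritParams synth_config
#' @param label0_frac Fraction of voxels labelled 0.
#' @return A 3-D integer array of labels.
#' @export
make_parcellation <- function(grid_shape, n_networks = 7L, seed = 1L,
                              label0_frac = 0.1) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, n_networks >= 1L)
  if (prod(grid_shape) < n_networks + (label0_frac > 0))
    stop("grid too small: fewer voxels than requested labels")
  box <- rbind(rep(1L, 3L), grid_shape)
  if (label0_frac > 0) {
    axis <- which.max(grid_shape)
    n0 <- max(1L, round(grid_shape[axis] * label0_frac))
    if (n0 >= grid_shape[axis])
      stop("label0_frac leaves no room for the networks")
    zero_box <- box; zero_box[1L, axis] <- grid_shape[axis] - n0 + 1L
    box[2L, axis] <- grid_shape[axis] - n0
  } else {
    zero_box <- NULL
  }
  boxes <- split_box(box, n_networks)
  labels <- seq_len(n_networks)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    set.seed(seed)
    labels <- sample(labels)
    .Random.seed_restore(old)
  }
  parc <- array(0L, dim = grid_shape)
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    parc[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]] <- labels[i]
  }
  if (!is.null(zero_box)) {
    b <- zero_box
    parc[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]] <- 0L
  }
  parc
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Edge index sets affected by an effect, as a logical V x V matrix builder.
effect_edges <- function(spec, labels) {
  v <- length(labels)
  in_region <- logical(v)
  in_region[spec$region] <- TRUE
  same_net <- outer(labels, labels, "==")
  incident <- outer(in_region, rep(TRUE, v), "&") |
    outer(rep(TRUE, v), in_region, "&")
  sel <- switch(spec$mode,
                between_network_gain = incident & !same_net,
                within_network_gain = incident & same_net,
                global_gain = incident)
  diag(sel) <- FALSE
  sel
}

# Target correlation matrix for one subject: base block structure plus all
# applicable effects. Labels are the parcellation labels of mask voxels;
# label-0 voxels form their own "network" for the purpose of the base
# block pattern.
target_correlation <- function(config, labels, subject_row = NULL) {
  v <- length(labels)
  same_net <- outer(labels, labels, "==")
  C <- matrix(config$base_between_corr, v, v)
  C[same_net] <- config$base_within_corr
  for (spec in config$effects) {
    if (!is.null(subject_row) && !identical(subject_row$group,
                                            spec$target_group)) next
    delta <- spec$delta_corr
    if (!is.null(spec$covariate_link) && !is.null(subject_row)) {
      cov_val <- subject_row[[spec$covariate_link$covariate]]
      cov_ctr <- subject_row[[paste0(".ctr_", spec$covariate_link$covariate)]]
      delta <- delta + spec$covariate_link$slope * (cov_val - (cov_ctr %||% 0))
    }
    if (any(spec$region > v)) stop("effect region outside the voxel grid")
    sel <- effect_edges(spec, labels)
    C[sel] <- C[sel] + delta
  }
  C[C > 0.99] <- 0.99
  C[C < -0.99] <- -0.99
  diag(C) <- 1
  C
}

# Cholesky factor with nearest-positive-definite repair (Higham projection
# via Matrix::nearPD) when the assembled target is not PD.
chol_with_repair <- function(C) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    warning("target correlation not positive definite; applying nearest-PD repair")
    C <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
    R <- chol(C)
  }
  R
}

subject_seed <- function(config_seed, sim_id) {
  as.integer((as.numeric(config_seed) * 7919 + 131071 * sim_id) %% 2147483647)
}

#' Simulate one subject's 4-D image and motion table
#'
#' Time points are independent draws from a multivariate normal with the
#' subject's target correlation matrix (block structure plus applicable
#' effects), plus independent Gaussian observation noise. The motion table
#' carries small sub-threshold jitter and `n_motion_spikes` sustained
#' translation steps of 0.8 mm, each of which trips the 0.5 mm FD threshold
#' exactly once. Deterministic given `(config$seed, sim_id)`.
#'
#' @param config A [synth_config()].
#' @param parcellation 3-D label array from [make_parcellation()].
#' @param subject_row One-row data frame with at least `group` and `sim_id`.
#' @param chol_factor Optional precomputed Cholesky factor of the subject's
#'   target correlation (reusable across subjects with identical targets).
#' @return List with `image` (4-D array), `motion` (data frame) and
#'   `n_spikes`.
#' @export
simulate_subject <- function(config, parcellation, subject_row,
                             chol_factor = NULL) {
  stopifnot(inherits(config, "synth_config"))
  coords <- mask_coords(array(TRUE, dim = config$grid_shape))
  labels <- parcellation[coords_to_linear(coords, config$grid_shape)]
  if (is.null(chol_factor)) {
    chol_factor <- chol_with_repair(
      target_correlation(config, labels, subject_row))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subject_seed(config$seed, subject_row$sim_id))
  nt <- config$n_timepoints
  v <- nrow(coords)
  signal_mat <- matrix(rnorm(nt * v), nt, v) %*% chol_factor
  signal_mat <- signal_mat + config$noise_sd * matrix(rnorm(nt * v), nt, v)
  img <- array(0, dim = c(config$grid_shape, nt))
  flat <- matrix(img, ncol = nt)
  flat[coords_to_linear(coords, config$grid_shape), ] <- t(signal_mat)
  img <- array(flat, dim = c(config$grid_shape, nt))
  # motion: gentle random walk translations, rotations at zero
  steps <- matrix(rnorm(nt * 3, sd = 0.02), nt, 3)
  trans <- apply(steps, 2L, cumsum)
  if (config$n_motion_spikes > 0) {
    eligible <- seq(10L, nt - 5L)
    at <- sort(sample(eligible, config$n_motion_spikes))
    for (a in at) trans[a:nt, 1L] <- trans[a:nt, 1L] + 0.8
  }
  motion <- data.frame(tx = trans[, 1L], ty = trans[, 2L], tz = trans[, 3L],
                       rx = 0, ry = 0, rz = 0)
  list(image = img, motion = motion, n_spikes = config$n_motion_spikes)
}

# Draw subject covariates with the study-like marginal structure: ~85%
# female, ages ~N(38, 12) truncated to 18-70, SSRI/SNRI use in half of the
# clinical groups and none of the HCs, and symptom scores whose group means
# and spreads follow the published demographics table.
draw_subjects <- function(config) {
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  age <- round(clamp(rnorm(n, 38, 12), 18, 70), 1)
  sex <- ifelse(runif(n) < 0.85, "F", "M")
  ssri <- ifelse(groups == "HC", 0L, rbinom(n, 1L, 0.5))
  score <- function(means, sds, lo, hi) {
    m <- means[groups]; s <- sds[groups]
    m[is.na(m)] <- means[["HC"]]; s[is.na(s)] <- sds[["HC"]]
    round(clamp(rnorm(n, m, s), lo, hi))
  }
  sdq20 <- score(c(FND = 34.7, PC = 22.0, HC = 20.3),
                 c(FND = 12.4, PC = 4.5, HC = 0.6), 20, 100)
  phq15 <- score(c(FND = 13.2, PC = 6.3, HC = 2.6),
                 c(FND = 6.2, PC = 3.7, HC = 2.2), 0, 30)
  tibble::tibble(
    id = sprintf("sub-%03d", seq_len(n)), group = groups,
    age = age, sex = sex, ssri = ssri, sdq20 = sdq20, phq15 = phq15,
    sim_id = seq_len(n), qc_status = "included",
    qc_reason = NA_character_)
}

#' Simulate a full cohort
#'
#' Generates the parcellation, subject covariate table and per-subject
#' images and motion tables described by `config`. The whole cohort is a
#' deterministic function of `config` (including its seed).
#'
#' @param config A [synth_config()].
#' @return A `synth_cohort` list: `images`, `motion_tables` (named by
#'   subject id), `mask`, `parcellation`, `subjects` tibble, `truth` (the
#'   effect list) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  parc <- make_parcellation(config$grid_shape, config$n_networks,
                            seed = config$seed,
                            label0_frac = config$label0_frac)
  old <- .Random.seed_save()
  set.seed(config$seed)
  subjects <- draw_subjects(config)
  .Random.seed_restore(old)
  # centre covariate-linked covariates on the target group's mean
  for (spec in config$effects) {
    if (is.null(spec$covariate_link)) next
    nm <- spec$covariate_link$covariate
    ctr <- mean(subjects[[nm]][subjects$group == spec$target_group])
    subjects[[paste0(".ctr_", nm)]] <- ctr
  }
  coords <- mask_coords(array(TRUE, dim = config$grid_shape))
  labels <- parc[coords_to_linear(coords, config$grid_shape)]
  # cache Cholesky factors per group when no covariate link applies
  has_link <- vapply(config$effects,
                     function(s) !is.null(s$covariate_link), logical(1L))
  chol_cache <- list()
  images <- list(); motions <- list()
  for (i in seq_len(nrow(subjects))) {
    row <- subjects[i, ]
    linked <- any(has_link & vapply(config$effects, function(s)
      identical(s$target_group, row$group), logical(1L)))
    ch <- NULL
    if (!linked) {
      key <- row$group
      if (is.null(chol_cache[[key]])) {
        chol_cache[[key]] <- chol_with_repair(
          target_correlation(config, labels, row))
      }
      ch <- chol_cache[[key]]
    }
    sim <- simulate_subject(config, parc, row, chol_factor = ch)
    images[[row$id]] <- sim$image
    motions[[row$id]] <- sim$motion
  }
  structure(list(images = images, motion_tables = motions,
                 mask = array(1L, dim = config$grid_shape),
                 parcellation = parc, subjects = subjects,
                 truth = config$effects, config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects (%s), grid %s, %d effect(s)\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", "),
              paste(x$config$grid_shape, collapse = "x"),
              length(x$truth)))
  invisible(x)
}
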