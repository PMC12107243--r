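# Shared fixtures, built in code. The tiny pipeline cohort is simulated
# once per test run and cached.

# 3-voxel worked example: edges AB = 0.5, AC = 0.3, BC = 0.2; A, B in
# network 1, C in network 2.
toy_conn <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.3
  w[2, 3] <- w[3, 2] <- 0.2
  voxelgraph:::new_conn_matrix(w, cbind(x = 1:3, y = 1L, z = 1L),
                               "isocortical", c(3L, 1L, 1L),
                               labels = c(1L, 1L, 2L))
}

# random symmetric nonnegative zero-diagonal matrix over v voxels arranged
# on a 1-D grid
random_conn <- function(v, seed = NULL, scope = "isocortical",
                        n_networks = 7L) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(runif(v * v), v, v)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  voxelgraph:::new_conn_matrix(w, cbind(x = seq_len(v), y = 1L, z = 1L),
                               scope, c(v, 1L, 1L),
                               labels = sample.int(n_networks, v,
                                                   replace = TRUE))
}

# subject table for map-level inference tests (no images involved)
fake_subjects <- function(n_a = 30L, n_b = 30L, n_hc = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_a + n_b + n_hc
  tibble::tibble(
    id = sprintf("s%03d", seq_len(n)),
    group = rep(c("FND", "PC", "HC"), c(n_a, n_b, n_hc)),
    age = round(runif(n, 20, 60), 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.85, 0.15)),
    ssri = c(stats::rbinom(n_a + n_b, 1, 0.5), rep(0L, n_hc)),
    sdq20 = round(runif(n, 20, 60)),
    phq15 = round(runif(n, 0, 25)),
    qc_status = "included", qc_reason = NA_character_)
}

fake_map_set <- function(values, grid_shape, metric = "integration",
                         scope = "isocortical") {
  map_set(values, metric = metric, scope = scope,
          voxel_index = mask_coords(grid_shape), grid_shape = grid_shape)
}

# small end-to-end cohort + pipeline result, cached across test files
tiny_env <- new.env(parent = emptyenv())
tiny_pipeline <- function() {
  if (is.null(tiny_env$res)) {
    cfg <- synth_config(grid_shape = c(6L, 6L, 6L), n_timepoints = 130L,
                        group_sizes = c(FND = 4L, PC = 4L, HC = 4L),
                        n_motion_spikes = 1L, seed = 42L)
    tiny_env$cohort <- simulate_cohort(cfg)
    tiny_env$res <- suppressWarnings(
      run_pipeline(tiny_env$cohort, analysis_params(n_iter = 200L,
                                                    seed = 7L)))
  }
  list(cohort = tiny_env$cohort, res = tiny_env$res)
}
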