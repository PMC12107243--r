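# Seed-based post hoc analysis: peak finding, ROI geometry, Fisher-z maps
# and seven-network composition.

mk_zmap <- function(z, grid) {
  structure(list(z = z, voxel_index = mask_coords(grid), grid_shape = grid,
                 metric = "integration"), class = "zmap")
}

test_that("peaks are the masked argmax per hemisphere with index ties", {
  grid <- c(10L, 6L, 6L)
  vi <- mask_coords(grid)
  hemi <- ifelse(vi[, 1] <= 5, "left", "right")
  z <- rep(0, nrow(vi))
  left_peak <- which(hemi == "left")[50]
  right_peak <- which(hemi == "right")[20]
  z[left_peak] <- 4; z[right_peak] <- 5
  mask <- z > 0
  pk <- find_peaks(mk_zmap(z, grid), mask)
  expect_equal(pk$left, left_peak)
  expect_equal(pk$right, right_peak)

  # tie in z: lowest voxel index wins
  z2 <- rep(0, nrow(vi))
  ties <- which(hemi == "left")[c(30, 80)]
  z2[ties] <- 4
  pk2 <- suppressWarnings(find_peaks(mk_zmap(z2, grid), z2 > 0))
  expect_equal(pk2$left, min(ties))

  # peak outside the intersection mask: next-highest eligible voxel
  z3 <- rep(0, nrow(vi))
  best <- which(hemi == "left")[10]; second <- which(hemi == "left")[60]
  z3[best] <- 6; z3[second] <- 4
  inter <- rep(TRUE, nrow(vi)); inter[best] <- FALSE
  pk3 <- suppressWarnings(find_peaks(mk_zmap(z3, grid), z3 > 0, inter))
  expect_equal(pk3$left, second)

  # an empty hemisphere is skipped with a warning
  z4 <- rep(0, nrow(vi)); z4[left_peak] <- 3
  expect_warning(pk4 <- find_peaks(mk_zmap(z4, grid), z4 > 0), "right")
  expect_null(pk4$right)
})

test_that("seed ROIs are 27-voxel cubes, clipped at grid edges", {
  grid <- c(8L, 8L, 8L)
  vi <- mask_coords(grid)
  interior <- which(vi[, 1] == 4 & vi[, 2] == 4 & vi[, 3] == 4)
  corner <- which(vi[, 1] == 1 & vi[, 2] == 1 & vi[, 3] == 1)
  face <- which(vi[, 1] == 4 & vi[, 2] == 4 & vi[, 3] == 1)
  expect_length(build_seed(interior, vi, grid)$member_voxels, 27L)
  expect_length(build_seed(corner, vi, grid)$member_voxels, 8L)
  expect_length(build_seed(face, vi, grid)$member_voxels, 18L)
  s <- build_seed(interior, vi, grid)
  expect_true(s$centre %in% s$member_voxels)
  # members are exactly the Chebyshev-1 neighbourhood
  cheb <- apply(abs(sweep(vi, 2, vi[interior, ])), 1, max)
  expect_setequal(s$member_voxels, which(cheb <= 1))
})

test_that("seed-to-voxel maps are Fisher-z with clipping and exclusion", {
  set.seed(1)
  grid <- c(8L, 8L, 5L)
  v <- prod(grid)
  vi <- mask_coords(grid)
  n <- 203                       # so that 1/sqrt(n - 3) is round
  X <- matrix(rnorm(n * v), n, v)
  ts <- voxel_ts(X, vi, 2, grid)
  seed <- build_seed(which(vi[, 1] == 3 & vi[, 2] == 3 & vi[, 3] == 1),
                     vi, grid)
  # plant a voxel equal to the seed mean, and one at exact r = 0.5
  seed_mean <- rowMeans(X[, seed$member_voxels])
  sm <- (seed_mean - mean(seed_mean)) / sd(seed_mean)
  out_rows <- setdiff(seq_len(v), seed$member_voxels)
  ortho <- residuals(lm(X[, out_rows[2]] ~ sm))
  ortho <- (ortho - mean(ortho)) / sd(ortho)
  X[, out_rows[1]] <- seed_mean
  X[, out_rows[2]] <- 0.5 * sm + sqrt(0.75) * ortho
  ts <- voxel_ts(X, vi, 2, grid)
  res <- seed_to_voxel(ts, seed)
  expect_false(any(seed$member_voxels %in% res$voxel_rows))
  i1 <- match(out_rows[1], res$voxel_rows)
  i2 <- match(out_rows[2], res$voxel_rows)
  expect_gt(res$values[i1], atanh(1 - 1e-6))   # clipped, huge positive
  expect_true(is.finite(res$values[i1]))
  expect_equal(res$values[i2], atanh(0.5), tolerance = 1e-10)
  expect_equal(round(res$values[i2], 4), 0.5493)
  # uncorrelated noise voxels: |z| < 3/sqrt(n-3) for at least 99%
  noise <- setdiff(seq_along(res$values), c(i1, i2))
  expect_gte(mean(abs(res$values[noise]) < 3 / sqrt(n - 3)), 0.99)
  # rescaling a voxel's series leaves its correlation untouched
  X2 <- X; X2[, out_rows[2]] <- 40 * X2[, out_rows[2]] + 7
  res2 <- seed_to_voxel(voxel_ts(X2, vi, 2, grid), seed)
  expect_equal(res2$values[i2], res$values[i2], tolerance = 1e-10)
})

test_that("network composition covers the six non-seed networks", {
  set.seed(2)
  grid <- c(6L, 6L, 6L)
  v <- prod(grid)
  subj <- fake_subjects(10, 10)
  labels <- rep_len(1:7, v)
  # group difference confined to voxels of networks 3 and 4
  vals <- matrix(rnorm(20 * v, sd = 0.5), 20, dimnames = list(subj$id, NULL))
  target <- labels %in% c(3, 4)
  vals[subj$group == "FND", target] <- vals[subj$group == "FND", target] + 2
  ms <- fake_map_set(vals, grid, metric = "seed_left")
  out <- seed_glm_and_compose(ms, subj, labels, seed_label = 2L,
                              covariates = character(0), n_iter = 300,
                              seed = 5)
  expect_equal(sum(out$composition$percent), 100, tolerance = 0.01)
  expect_false(2L %in% out$composition$network)
  expect_equal(nrow(out$composition), 6L)
  dominant <- out$composition$network[out$composition$percent > 10]
  expect_setequal(dominant, c(3L, 4L))
  expect_gt(sum(out$composition$percent[out$composition$network %in%
                                          c(3, 4)]), 80)

  # effect confined to one network dominates its composition end to end
  vals2 <- matrix(rnorm(20 * v, sd = 0.5), 20,
                  dimnames = list(subj$id, NULL))
  t2 <- labels == 5
  vals2[subj$group == "FND", t2] <- vals2[subj$group == "FND", t2] + 2
  out2 <- seed_glm_and_compose(fake_map_set(vals2, grid,
                                            metric = "seed_left"),
                               subj, labels, seed_label = 2L,
                               covariates = character(0), n_iter = 300,
                               seed = 5)
  expect_gt(out2$composition$percent[out2$composition$network == 5], 80)
  expect_equal(sum(out2$composition$percent), 100, tolerance = 0.01)
})

test_that("composition arithmetic excludes the seed network exactly", {
  all_lab <- rep(1:7, each = 10)
  # all significant voxels in one network -> 100% for it, 0 elsewhere
  comp <- network_composition(rep(5L, 12), all_lab, seed_label = 2L)
  expect_equal(comp$percent[comp$network == 5], 100)
  expect_equal(sum(comp$n_voxels), 12L)
  expect_false(2L %in% comp$network)
  expect_equal(nrow(comp), 6L)
  # seed-network voxels are discarded from numerator and denominator
  comp2 <- network_composition(c(rep(2L, 5), rep(3L, 5), rep(4L, 15)),
                               all_lab, seed_label = 2L)
  expect_equal(comp2$n_voxels[comp2$network %in% c(3, 4)], c(5L, 15L))
  expect_equal(comp2$percent[comp2$network == 4], 75)
  expect_equal(sum(comp2$percent), 100, tolerance = 1e-10)
  # no significant voxels: empty composition reported as zeros
  comp3 <- network_composition(integer(0), all_lab, seed_label = 2L)
  expect_true(all(comp3$percent == 0))
})
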