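# Group inference: GLM z-maps, cluster extraction, the permutation null and
# clusterwise correction.

test_that("null data give the nominal suprathreshold fraction", {
  set.seed(1)
  grid <- c(16L, 16L, 8L)           # 2048 voxels
  subj <- fake_subjects(40, 40)
  vals <- matrix(rnorm(80 * prod(grid)), 80,
                 dimnames = list(subj$id, NULL))
  zm <- glm_contrast(fake_map_set(vals, grid), subj,
                     covariates = character(0))
  frac <- mean(abs(zm$z) > 1.96)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  expect_equal(zm$df, 80L - 2L)
})

test_that("an injected 1-SD shift yields strong z inside the region", {
  set.seed(2)
  grid <- c(10L, 10L, 10L)
  subj <- fake_subjects(30, 30)
  vals <- matrix(rnorm(60 * prod(grid)), 60,
                 dimnames = list(subj$id, NULL))
  region <- 1:100
  vals[subj$group == "FND", region] <- vals[subj$group == "FND", region] + 1
  zm <- glm_contrast(fake_map_set(vals, grid), subj,
                     covariates = character(0))
  expect_gt(mean(zm$z[region]), 3)
})

test_that("a covariate that explains the group difference absorbs it", {
  set.seed(3)
  grid <- c(8L, 8L, 4L)
  subj <- fake_subjects(40, 40)
  # ssri prevalence differs by group; maps depend only on ssri
  subj$ssri <- ifelse(subj$group == "FND", rbinom(80, 1, 0.8),
                      rbinom(80, 1, 0.2))
  vals <- matrix(rnorm(80 * prod(grid), sd = 0.3), 80,
                 dimnames = list(subj$id, NULL)) + 2 * subj$ssri
  unadj <- glm_contrast(fake_map_set(vals, grid), subj,
                        covariates = character(0))
  adj <- glm_contrast(fake_map_set(vals, grid), subj, covariates = "ssri")
  expect_gt(mean(unadj$z), 2)                  # difference present unadjusted
  expect_lt(abs(mean(adj$z)), 0.3)             # absorbed by the covariate
  expect_gt(mean(abs(adj$z) > 1.96), 0)        # but still ~nominal noise
  expect_lt(mean(abs(adj$z) > 1.96), 0.12)
})

test_that("healthy controls never enter the contrast", {
  set.seed(4)
  grid <- c(4L, 4L, 4L)
  subj <- fake_subjects(10, 10, 10)
  vals <- matrix(rnorm(30 * prod(grid)), 30,
                 dimnames = list(subj$id, NULL))
  zm <- glm_contrast(fake_map_set(vals, grid), subj,
                     covariates = character(0))
  expect_equal(sum(zm$n_per_group), 20L)
})

test_that("cluster extraction respects threshold, signs and connectivity", {
  grid <- c(10L, 10L, 10L)
  vi <- mask_coords(grid)
  z <- rep(0, prod(grid))
  zm <- structure(list(z = z, voxel_index = vi, grid_shape = grid,
                       metric = "test"), class = "zmap")
  expect_equal(nrow(cluster_extract(zm)$clusters), 0L)

  # one 3x3x3 block of z = 5
  block <- vi[, 1] %in% 2:4 & vi[, 2] %in% 2:4 & vi[, 3] %in% 2:4
  zm$z <- ifelse(block, 5, 0)
  cl <- cluster_extract(zm)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$extent, 27L)
  expect_equal(cl$clusters$sign, 1L)

  # two diagonal-touching blocks: one component under 26, two under 6
  b1 <- vi[, 1] %in% 1:2 & vi[, 2] %in% 1:2 & vi[, 3] %in% 1:2
  b2 <- vi[, 1] %in% 3:4 & vi[, 2] %in% 3:4 & vi[, 3] %in% 3:4
  zm$z <- ifelse(b1 | b2, 5, 0)
  expect_equal(nrow(cluster_extract(zm, connectivity = 26)$clusters), 1L)
  expect_equal(nrow(cluster_extract(zm, connectivity = 6)$clusters), 2L)

  # opposite signs never merge
  zm$z <- ifelse(b1, 5, ifelse(b2, -5, 0))
  zm$z[vi[, 1] == 2 & vi[, 2] == 2 & vi[, 3] == 3] <- -5  # adjacent negative
  cl <- cluster_extract(zm, connectivity = 26)
  expect_equal(sort(unique(cl$clusters$sign)), c(-1L, 1L))
})

test_that("the permutation null is deterministic and correctly used", {
  set.seed(5)
  grid <- c(8L, 8L, 8L)
  subj <- fake_subjects(15, 15)
  vals <- matrix(rnorm(30 * prod(grid)), 30,
                 dimnames = list(subj$id, NULL))
  ms <- fake_map_set(vals, grid)
  n1 <- monte_carlo_null(ms, subj, covariates = character(0),
                         n_iter = 300, seed = 11)
  n2 <- monte_carlo_null(ms, subj, covariates = character(0),
                         n_iter = 300, seed = 11)
  expect_identical(n1$max_extents, n2$max_extents)
  expect_length(n1$max_extents, 300L)
  expect_true(all(n1$max_extents >= 0))
  expect_warning(
    monte_carlo_null(ms, subj, covariates = character(0), n_iter = 50),
    "unstable")
})

test_that("corrected p-values follow the +1 permutation convention", {
  grid <- c(6L, 6L, 6L)
  vi <- mask_coords(grid)
  z <- rep(0, prod(grid)); z[vi[, 1] <= 3 & vi[, 2] <= 3 & vi[, 3] <= 2] <- 6
  zm <- structure(list(z = z, voxel_index = vi, grid_shape = grid,
                       metric = "test"), class = "zmap")
  cl <- cluster_extract(zm)
  null <- structure(list(max_extents = rep(5L, 999),
                         params = list(threshold = 1.96, two_sided = TRUE,
                                       connectivity = 26L, n_iter = 999L)),
                    class = "cluster_null")
  res <- correct_clusters(zm, cl, null)
  # observed extent 18 beats every null max: p = 1 / (1 + n_iter)
  expect_equal(res$clusters$p_corrected, 1 / 1000)
  expect_true(all(res$corrected_mask[z == 6]))

  # a singleton dominated by the null is removed with p = 1
  z2 <- rep(0, prod(grid)); z2[1] <- 6
  zm2 <- structure(list(z = z2, voxel_index = vi, grid_shape = grid,
                        metric = "test"), class = "zmap")
  res2 <- correct_clusters(zm2, cluster_extract(zm2), null)
  expect_equal(res2$clusters$p_corrected, 1)
  expect_false(any(res2$corrected_mask))

  # mismatched parameters are refused
  bad <- null; bad$params$connectivity <- 6L
  expect_error(correct_clusters(zm, cl, bad), "refusing")
})

test_that("intersection maps implement voxelwise AND", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  c3 <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(intersection_map(list(a, a)), a)
  expect_equal(intersection_map(list(a, !a)), rep(FALSE, 4))
  expect_equal(intersection_map(list(a, b, c3)), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(intersection_map(list(a, c(TRUE, FALSE))), "grids")
})
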