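# Denoising stages: framewise displacement, confound regression, band-pass
# filtering and fixed-length volume selection.

zero_motion <- function(n) {
  data.frame(tx = numeric(n), ty = 0, tz = 0, rx = 0, ry = 0, rz = 0)
}

test_that("framewise displacement follows the Power convention", {
  ms <- framewise_displacement(zero_motion(20))
  expect_true(all(ms$fd == 0))
  expect_length(ms$scrubbed_volume_ids, 0L)
  expect_equal(ms$usable_volumes, 20L)

  # single 0.6 mm tx step between volumes 10 and 11
  m <- zero_motion(20); m$tx[11:20] <- 0.6
  ms <- framewise_displacement(m)
  expect_equal(ms$fd[10], 0.6)
  expect_equal(ms$scrubbed_volume_ids, 11L)
  expect_equal(ms$usable_volumes, 19L)

  # rotation-only: 0.01 rad at radius 50 mm gives exactly 0.5 mm,
  # which is NOT above the strict > 0.5 threshold
  m <- zero_motion(10); m$rx[6:10] <- 0.01
  ms <- framewise_displacement(m, rotation_radius_mm = 50)
  expect_equal(ms$fd[5], 0.5)
  expect_length(ms$scrubbed_volume_ids, 0L)

  expect_error(framewise_displacement(zero_motion(10)[, 1:5]), "6 columns")
})

test_that("confound regression is exact OLS with orthogonal residuals", {
  set.seed(1)
  n <- 80
  ts <- voxel_ts(matrix(rnorm(n * 5), n, 5), cbind(1:5, 1L, 1L), 2,
                 c(5L, 1L, 1L))
  # intercept only -> mean-centred
  out <- regress_confounds(ts, matrix(1, n, 1))
  expect_equal(out$data, scale(ts$data, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
  # voxel equal to a confound -> residual ~ 0
  conf <- cbind(1, rnorm(n))
  ts2 <- ts; ts2$data[, 3] <- conf[, 2] * 2.5
  out2 <- regress_confounds(ts2, conf)
  expect_lt(max(abs(out2$data[, 3])), 1e-10)
  # orthogonality of residuals to every confound column
  conf3 <- cbind(1, matrix(rnorm(n * 4), n, 4))
  out3 <- regress_confounds(ts, conf3)
  expect_lt(max(abs(crossprod(conf3, out3$data))), 1e-8)
  # idempotence
  out4 <- regress_confounds(out3, conf3)
  expect_lt(max(abs(out4$data - out3$data)), 1e-10)
  # rank-deficient confounds: dropped with warning, still proceeds
  dup <- cbind(conf3, conf3[, 2])
  expect_warning(out5 <- regress_confounds(ts, dup), "dependent")
  expect_equal(out5$data, out3$data, tolerance = 1e-10)
})

test_that("band-pass keeps the pass band and kills DC and fast signal", {
  tr <- 2; n <- 200; tt <- (0:(n - 1)) * tr
  mk <- function(f) sin(2 * pi * f * tt)
  X <- cbind(rep(1, n), mk(0.04), mk(0.2))
  ts <- voxel_ts(X, cbind(1:3, 1L, 1L), tr, c(3L, 1L, 1L))
  out <- bandpass(ts)$data
  # amplitude at a known frequency via sine/cosine regression on the
  # central 60% (independent FFT-style oracle, avoids edge transients)
  amp <- function(y, f) {
    idx <- round(n * 0.2):round(n * 0.8)
    s <- sin(2 * pi * f * tt[idx]); cc <- cos(2 * pi * f * tt[idx])
    co <- coef(lm(y[idx] ~ s + cc))
    sqrt(co[2]^2 + co[3]^2)
  }
  expect_lt(max(abs(out[, 1])), 0.1)            # DC removed
  expect_gt(amp(out[, 2], 0.04), 0.9)           # pass band preserved
  expect_lt(amp(out[, 2], 0.04), 1.1)
  expect_lt(amp(out[, 3], 0.2), 0.1)            # stop band attenuated
  # zero phase: pass-band sinusoid not shifted (high positive correlation
  # with the input over the central window)
  idx <- 40:160
  expect_gt(cor(out[idx, 2], X[idx, 2]), 0.99)
  expect_error(bandpass(ts, 0.01, 0.3), "Nyquist")
})

test_that("the filtering recursion matches the reference IIR filter", {
  set.seed(2)
  x <- rnorm(150)
  bw <- signal::butter(4, c(0.04, 0.32), "pass")
  # single forward pass of the internal recursion (no padding) must equal
  # signal::filter exactly
  fwd <- local({
    b <- bw$b; a <- bw$a; M <- matrix(x); Y <- matrix(0, nrow(M), 1)
    for (t in seq_len(nrow(M))) {
      acc <- b[1] * M[t, ]
      for (j in seq_len(length(b) - 1)) if (t > j) acc <- acc + b[j + 1] * M[t - j, ]
      for (j in seq_len(length(a) - 1)) if (t > j) acc <- acc - a[j + 1] * Y[t - j, ]
      Y[t, ] <- acc / a[1]
    }
    Y
  })
  expect_equal(as.numeric(fwd), as.numeric(signal::filter(bw, x)),
               tolerance = 1e-12)
})

test_that("volume selection retains exactly 120 volumes or excludes", {
  v <- 4
  mk_run <- function(n) voxel_ts(matrix(rnorm(n * v), n, v),
                                 cbind(1:v, 1L, 1L), 2, c(v, 1L, 1L))
  set.seed(3)
  # 150 volumes, none scrubbed -> first 120, ids 1..120
  r <- mk_run(150)
  out <- select_volumes(r, framewise_displacement(zero_motion(150)))
  expect_s3_class(out, "voxel_ts")
  expect_equal(nrow(out$data), 120L)
  expect_equal(out$kept_volume_ids$volume, 1:120)
  expect_equal(out$data, r$data[1:120, ], ignore_attr = TRUE)

  # 130 volumes with 15 scrubbed -> 115 usable -> exclusion("motion")
  m <- zero_motion(130)
  jumps <- seq(10, 94, by = 6)[1:15]
  for (j in jumps) m$tx[j:130] <- m$tx[j:130] + 0.8
  ms <- framewise_displacement(m)
  expect_equal(length(ms$scrubbed_volume_ids), 15L)
  out <- select_volumes(mk_run(130), ms)
  expect_s3_class(out, "subject_exclusion")
  expect_equal(out$reason, "motion")
  expect_equal(out$usable_volumes, 115L)

  # two runs with 70 usable each -> 70 from run 1 then 50 from run 2
  r1 <- mk_run(70); r2 <- mk_run(70)
  ms0 <- framewise_displacement(zero_motion(70))
  out <- select_volumes(list(r1, r2), list(ms0, ms0))
  expect_equal(nrow(out$data), 120L)
  expect_equal(out$kept_volume_ids$run, rep(1:2, c(70, 50)))
  expect_equal(out$data[1:70, ], r1$data, ignore_attr = TRUE)
  expect_equal(out$data[71:120, ], r2$data[1:50, ], ignore_attr = TRUE)

  # mismatched voxel sets refuse
  r3 <- voxel_ts(matrix(rnorm(70 * v), 70, v), cbind(1:v, 2L, 1L), 2,
                 c(v, 2L, 1L))
  expect_error(select_volumes(list(r1, r3), list(ms0, ms0)), "share")
})

test_that("the stage order is confounds, then filter, then scrub/select", {
  set.seed(4)
  dims <- c(3L, 3L, 3L)
  img <- array(rnorm(27 * 140), dim = c(dims, 140))
  m <- zero_motion(140); m$tx[60:140] <- 0.8   # one scrubbed volume (60)
  mask <- array(TRUE, dims)
  got <- prep_subject(img, m, mask, 2)
  # manual composition in the documented order
  ts <- image_to_ts(img, mask, 2)
  ts <- regress_confounds(ts, build_confounds(m))
  ts <- bandpass(ts)
  manual <- select_volumes(ts, framewise_displacement(m))
  expect_equal(got$data, manual$data, tolerance = 1e-12)
  expect_equal(nrow(got$data), 120L)
  # scrubbing before filtering gives a different answer (order matters)
  ts2 <- image_to_ts(img, mask, 2)
  ts2 <- regress_confounds(ts2, build_confounds(m))
  keep <- setdiff(1:140, 60)
  ts2$data <- ts2$data[keep, ]
  ts2 <- bandpass(ts2)
  expect_gt(max(abs(ts2$data[1:120, ] - got$data)), 1e-6)
})
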