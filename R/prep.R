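# Functional time-series container and the denoising stages applied before
# connectivity estimation: confound regression, band-pass filtering,
# framewise-displacement scrubbing and fixed-length volume selection.

#' Construct a masked voxel time-series object
#'
#' @param data Numeric matrix, time points in rows and voxels in columns.
#' @param voxel_index Integer matrix of (x, y, z) grid coordinates, one row
#'   per data column.
#' @param tr_seconds Repetition time in seconds.
#' @param grid_shape Integer 3-vector of grid dimensions.
#' @param kept_volume_ids Optional data frame (`run`, `volume`) recording the
#'   original identity of each retained row; defaults to run 1, rows 1..T.
#' @return An object of class `voxel_ts`.
#' @export
voxel_ts <- function(data, voxel_index, tr_seconds, grid_shape,
                     kept_volume_ids = NULL) {
  data <- as.matrix(data)
  voxel_index <- as.matrix(voxel_index)
  stopifnot(ncol(data) == nrow(voxel_index), ncol(voxel_index) == 3L,
            is.numeric(tr_seconds), tr_seconds > 0)
  if (anyNA(data)) stop("time series must not contain missing values")
  if (anyDuplicated(coords_to_linear(voxel_index, grid_shape)) > 0L)
    stop("duplicate voxels in voxel_index")
  if (is.null(kept_volume_ids)) {
    kept_volume_ids <- data.frame(run = 1L, volume = seq_len(nrow(data)))
  }
  structure(
    list(data = data, voxel_index = voxel_index,
         tr_seconds = tr_seconds, grid_shape = as.integer(grid_shape),
         kept_volume_ids = kept_volume_ids),
    class = "voxel_ts"
  )
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf("<voxel_ts> %d volumes x %d voxels, TR = %gs, grid %s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds,
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Extract in-mask voxel time series from a 4-D image array
#'
#' @param img 4-D array (x, y, z, time).
#' @param mask 3-D mask array.
#' @inheritParams voxel_ts
#' @export
image_to_ts <- function(img, mask, tr_seconds) {
  stopifnot(length(dim(img)) == 4L, all(dim(img)[1:3] == dim(mask)))
  coords <- mask_coords(mask)
  nt <- dim(img)[4L]
  flat <- matrix(img, ncol = nt)
  voxel_ts(t(flat[coords_to_linear(coords, dim(mask)), , drop = FALSE]),
           coords, tr_seconds, dim(mask))
}

#' Framewise displacement and scrubbing decisions
#'
#' FD follows the Power convention: at the transition into volume t + 1,
#' `FD = sum |delta translation| + r * sum |delta rotation|`, with rotations
#' (radians) converted to arc length on a sphere of radius
#' `rotation_radius_mm` (default 50 mm). A volume is scrubbed when its
#' incoming transition exceeds `threshold_mm` strictly; the first volume has
#' no incoming transition and is never scrubbed.
#'
#' @param motion Data frame or matrix with 6 columns
#'   (tx, ty, tz in mm; rx, ry, rz in radians), one row per volume.
#' @param rotation_radius_mm Sphere radius used to convert rotations to mm.
#' @param threshold_mm Scrubbing threshold (strict `>` comparison).
#' @return A `motion_summary` list: `fd` (length T - 1),
#'   `scrubbed_volume_ids`, `usable_volumes`, and the parameters used.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50,
                                   threshold_mm = 0.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion table must have exactly 6 columns (tx, ty, tz, rx, ry, rz)")
  if (nrow(motion) < 2L) stop("motion table needs at least 2 rows")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  scrubbed <- which(fd > threshold_mm) + 1L
  structure(
    list(fd = unname(fd), scrubbed_volume_ids = scrubbed,
         usable_volumes = nrow(motion) - length(scrubbed),
         threshold_mm = threshold_mm,
         rotation_radius_mm = rotation_radius_mm),
    class = "motion_summary"
  )
}

#' Assemble a confound design matrix
#'
#' Columns: intercept, the 6 rigid-motion parameters and their first
#' derivatives (backward differences, zero-padded), optional linear and
#' quadratic trends, and optionally the top principal components of
#' designated noise-tissue series (a compcor-style emulation; each element of
#' `compcor_series` contributes `n_compcor` components).
#'
#' @param motion 6-column motion table, one row per volume.
#' @param trends Include linear + quadratic trend columns (default TRUE).
#' @param compcor_series Optional named list of time x voxel matrices of
#'   noise-tissue signal (e.g. lateral ventricles, white matter).
#' @param n_compcor Components per noise set (default 5).
#' @return A numeric matrix with named columns; the intercept is always
#'   present.
#' @export
build_confounds <- function(motion, trends = TRUE, compcor_series = NULL,
                            n_compcor = 5L) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion table must have 6 columns")
  nt <- nrow(motion)
  deriv <- rbind(0, diff(motion))
  out <- cbind(intercept = rep(1, nt), motion, deriv)
  colnames(out) <- c("intercept", paste0("mot", 1:6), paste0("dmot", 1:6))
  if (trends) {
    tt <- seq_len(nt) / nt
    out <- cbind(out, trend_lin = tt - mean(tt),
                 trend_quad = (tt - mean(tt))^2)
  }
  # constant motion columns (e.g. rotations held at zero) are redundant
  # with the intercept; drop them silently
  keep <- c(TRUE, apply(out[, -1L, drop = FALSE], 2L,
                        function(x) any(x != x[1L])))
  out <- out[, keep, drop = FALSE]
  if (!is.null(compcor_series)) {
    for (nm in names(compcor_series)) {
      x <- scale(as.matrix(compcor_series[[nm]]), scale = FALSE)
      k <- min(n_compcor, ncol(x), nt - 1L)
      pcs <- svd(x, nu = k, nv = 0)$u[, seq_len(k), drop = FALSE]
      colnames(pcs) <- paste0(nm, "_pc", seq_len(k))
      out <- cbind(out, pcs)
    }
  }
  out
}

#' Remove confound signal from every voxel series by OLS
#'
#' Each voxel series is replaced by its ordinary-least-squares residual on
#' the confound matrix (an intercept is appended if absent). Rank-deficient
#' confound matrices are handled by dropping aliased columns with a warning.
#' Residuals are orthogonal to every retained confound column, so the
#' operation is idempotent.
#'
#' @param ts A `voxel_ts`.
#' @param confounds Numeric matrix with rows matching `ts$data`.
#' @return A `voxel_ts` of residuals.
#' @export
regress_confounds <- function(ts, confounds) {
  stopifnot(inherits(ts, "voxel_ts"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts$data))
    stop("confound rows must match time-series rows")
  if (!any(apply(confounds, 2L, function(c) all(c == c[1L]) && c[1L] != 0)))
    confounds <- cbind(intercept = 1, confounds)
  qr_x <- qr(confounds)
  if (qr_x$rank < ncol(confounds)) {
    drop <- qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(confounds))]
    warning(sprintf("dropping %d linearly dependent confound column(s)",
                    length(drop)))
    confounds <- confounds[, -drop, drop = FALSE]
    qr_x <- qr(confounds)
  }
  res <- ts$data - confounds %*% qr.coef(qr_x, ts$data)
  ts$data <- unname(res)
  ts
}

# Zero-phase forward-backward IIR filtering of every column of X, with
# odd-reflection padding of 3 * (n_coef - 1) samples at both ends to tame
# edge transients (the scipy filtfilt padding convention). The recursion is
# vectorized across columns, so a whole masked brain filters in one call.
filtfilt_mat <- function(b, a, X) {
  X <- as.matrix(X)
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (nrow(X) <= npad)
    stop(sprintf("need more than %d time points for stable filtering", npad))
  pad_odd <- function(M) {
    top <- 2 * matrix(M[1L, ], npad, ncol(M), byrow = TRUE) -
      M[npad:1 + 1L, , drop = FALSE]
    bot <- 2 * matrix(M[nrow(M), ], npad, ncol(M), byrow = TRUE) -
      M[nrow(M) - seq_len(npad), , drop = FALSE]
    rbind(top, M, bot)
  }
  iir <- function(M) {
    nb <- length(b); na <- length(a)
    Y <- matrix(0, nrow(M), ncol(M))
    for (t in seq_len(nrow(M))) {
      acc <- b[1L] * M[t, ]
      for (j in seq_len(nb - 1L)) if (t > j) acc <- acc + b[j + 1L] * M[t - j, ]
      for (j in seq_len(na - 1L)) if (t > j) acc <- acc - a[j + 1L] * Y[t - j, ]
      Y[t, ] <- acc / a[1L]
    }
    Y
  }
  rev_rows <- function(M) M[nrow(M):1L, , drop = FALSE]
  P <- pad_odd(X)
  Y <- rev_rows(iir(rev_rows(iir(P))))
  Y[npad + seq_len(nrow(X)), , drop = FALSE]
}

#' Band-pass filter voxel time series (zero phase)
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero-phase), passing fluctuations between `low_hz` and `high_hz`.
#' The defaults bracket the conventional resting-state band 0.01-0.08 Hz.
#'
#' @param ts A `voxel_ts`.
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 TR)`.
#' @param order Butterworth order (default 4).
#' @return A filtered `voxel_ts`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08, order = 4L) {
  stopifnot(inherits(ts, "voxel_ts"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist))
    stop(sprintf("require 0 < low_hz < high_hz < Nyquist (%.4g Hz)", nyquist))
  bw <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  ts$data <- filtfilt_mat(bw$b, bw$a, ts$data)
  ts
}

#' Drop scrubbed volumes, concatenate runs and retain a fixed count
#'
#' Volumes flagged by [framewise_displacement()] are removed from each run,
#' runs are concatenated in order, and the first `n_keep` surviving volumes
#' are retained so every subject contributes the same number of time points
#' to the connectivity matrix. Subjects with fewer than `n_keep` usable
#' volumes are returned as an exclusion with reason `"motion"`.
#'
#' @param runs A `voxel_ts` or list of `voxel_ts` sharing voxels and TR.
#' @param motion_summaries A `motion_summary` or list, one per run.
#' @param n_keep Number of volumes to retain (default 120).
#' @return A `voxel_ts` with exactly `n_keep` rows, or a
#'   `subject_exclusion` object.
#' @export
select_volumes <- function(runs, motion_summaries, n_keep = 120L) {
  if (inherits(runs, "voxel_ts")) runs <- list(runs)
  if (inherits(motion_summaries, "motion_summary"))
    motion_summaries <- list(motion_summaries)
  stopifnot(length(runs) == length(motion_summaries), length(runs) >= 1L)
  ref <- runs[[1L]]
  for (r in runs[-1L]) {
    if (!identical(r$voxel_index, ref$voxel_index) ||
        !identical(r$tr_seconds, ref$tr_seconds))
      stop("runs must share voxel_index and TR")
  }
  pieces <- vector("list", length(runs))
  ids <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    keep <- setdiff(seq_len(nrow(runs[[i]]$data)),
                    motion_summaries[[i]]$scrubbed_volume_ids)
    pieces[[i]] <- runs[[i]]$data[keep, , drop = FALSE]
    ids[[i]] <- data.frame(run = i, volume = keep)
  }
  data <- do.call(rbind, pieces)
  ids <- do.call(rbind, ids)
  if (nrow(data) < n_keep) {
    return(structure(list(reason = "motion", usable_volumes = nrow(data),
                          required = n_keep),
                     class = "subject_exclusion"))
  }
  voxel_ts(data[seq_len(n_keep), , drop = FALSE], ref$voxel_index,
           ref$tr_seconds, ref$grid_shape,
           kept_volume_ids = ids[seq_len(n_keep), , drop = FALSE])
}

#' @export
print.subject_exclusion <- function(x, ...) {
  cat(sprintf("<subject_exclusion> reason = %s (%d of %d usable volumes)\n",
              x$reason, x$usable_volumes, x$required))
  invisible(x)
}

#' Full single-subject denoising chain
#'
#' Fixed stage order: confound regression, band-pass filtering, then
#' scrubbing and volume selection. Scrubbed volumes are deleted after
#' filtering, so filter transients never leak across gaps.
#'
#' @param img 4-D array (or list of arrays, one per run).
#' @param motion Motion table (or list, one per run).
#' @param mask 3-D mask array.
#' @param tr_seconds Repetition time.
#' @param fd_threshold_mm Scrubbing threshold (default 0.5 mm).
#' @param n_keep Volumes to retain (default 120).
#' @param band Pass band in Hz (default `c(0.01, 0.08)`).
#' @param compcor_sets Optional named list of 3-D masks of noise-tissue
#'   voxels whose top principal components join the confounds.
#' @return A cleaned `voxel_ts`, or a `subject_exclusion`.
#' @export
prep_subject <- function(img, motion, mask, tr_seconds,
                         fd_threshold_mm = 0.5, n_keep = 120L,
                         band = c(0.01, 0.08), compcor_sets = NULL) {
  if (!is.list(img) || is.array(img)) img <- list(img)
  if (!is.list(motion) || is.data.frame(motion)) motion <- list(motion)
  stopifnot(length(img) == length(motion))
  runs <- vector("list", length(img))
  summaries <- vector("list", length(img))
  for (i in seq_along(img)) {
    ts <- image_to_ts(img[[i]], mask, tr_seconds)
    cc <- NULL
    if (!is.null(compcor_sets)) {
      cc <- lapply(compcor_sets, function(m) {
        image_to_ts(img[[i]], m, tr_seconds)$data
      })
    }
    conf <- build_confounds(motion[[i]], compcor_series = cc)
    ts <- regress_confounds(ts, conf)
    ts <- bandpass(ts, band[1L], band[2L])
    runs[[i]] <- ts
    summaries[[i]] <- framewise_displacement(motion[[i]],
                                             threshold_mm = fd_threshold_mm)
  }
  select_volumes(runs, summaries, n_keep = n_keep)
}
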