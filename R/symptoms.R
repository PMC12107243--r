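# Cluster-mean symptom correlations: per-subject means over significant
# clusters, IQR outlier removal on the connectivity variable, Spearman
# correlation with a t-approximation p-value, and Benjamini-Hochberg FDR
# within (cohort pair, metric) families.

#' Per-subject mean normalized value over each significant cluster
#'
#' @param maps A normalized `map_set`.
#' @param result A `group_inference` (significant clusters are used) or a
#'   `cluster_set`/tibble with `cluster_id` and `voxels` columns.
#' @return Tibble: `id`, `cluster_id`, `metric`, `mean_value`.
#' @export
cluster_means <- function(maps, result) {
  stopifnot(inherits(maps, "map_set"))
  tab <- if (inherits(result, "group_inference")) {
    result$clusters[result$clusters$significant, , drop = FALSE]
  } else if (inherits(result, "cluster_set")) {
    result$clusters
  } else {
    result
  }
  if (!nrow(tab)) {
    return(tibble::tibble(id = character(), cluster_id = integer(),
                          metric = character(), mean_value = numeric()))
  }
  empty <- lengths(tab$voxels) == 0L
  if (any(empty)) {
    warning(sprintf("%d empty cluster(s) skipped", sum(empty)))
    tab <- tab[!empty, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    vx <- tab$voxels[[i]]
    tibble::tibble(id = rownames(maps$values),
                   cluster_id = tab$cluster_id[i], metric = maps$metric,
                   mean_value = unname(rowMeans(maps$values[, vx,
                                                            drop = FALSE])))
  })
  dplyr::bind_rows(out)
}

#' Filter values outside the 1.5 IQR Tukey fences
#'
#' Quartiles use linear interpolation (type 7); comparison is strict, so a
#' zero IQR never drops anything. With fewer than 4 values no filtering is
#' applied (with a warning).
#'
#' @param values Numeric vector.
#' @return List: `kept` (logical), `values` (the retained subset),
#'   `fences`.
#' @export
iqr_outlier_filter <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    warning("fewer than 4 values; no outlier filtering applied")
    return(list(kept = ok, values = values[ok], fences = NULL))
  }
  f <- iqr_fences(values)
  kept <- ok & !f$outlier
  list(kept = kept, values = values[kept],
       fences = c(lower = f$lower, upper = f$upper))
}

#' Spearman rank correlation with mid-ranks and t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks); the two-sided p-value comes from the t approximation at n - 2
#' degrees of freedom. For small samples (`n <= 10`) an exact permutation
#' p-value is available behind `exact = TRUE`. Incomplete pairs are dropped
#' pairwise.
#'
#' @param x,y Paired numeric vectors.
#' @param exact Use exact permutation p for n <= 10.
#' @return Tibble: `rho`, `n`, `p_raw`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble::tibble(rho = NA_real_, n = n, p_raw = NA_real_))
  }
  rho <- cor(rx, ry)
  if (exact && n <= 10L) {
    perms <- perm_all(n)
    obs <- abs(rho)
    count <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(cor(rx, ry[perms[i, ]])) >= obs - 1e-12) count <- count + 1L
    }
    p <- count / nrow(perms)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
    p <- min(1, p)
  }
  tibble::tibble(rho = rho, n = n, p_raw = p)
}

perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Benjamini-Hochberg correction within correlation families
#'
#' Adds `p_fdr` by applying the BH step-up procedure separately within each
#' family, identified by the `family` column (conventionally the cohort
#' pair and graph metric).
#'
#' @param results Tibble with `p_raw` and `family` columns.
#' @return The tibble with a `p_fdr` column (`p_fdr >= p_raw`).
#' @export
fdr_correct <- function(results) {
  stopifnot(all(c("p_raw", "family") %in% names(results)))
  results$p_fdr <- NA_real_
  for (fam in unique(results$family)) {
    rows <- which(results$family == fam & !is.na(results$p_raw))
    if (!length(rows)) next
    results$p_fdr[rows] <- p.adjust(results$p_raw[rows], method = "BH")
  }
  results
}

#' Cluster-mean symptom correlations across the documented cohort pairings
#'
#' For every significant cluster of each metric, Spearman-correlates the
#' per-subject cluster means with symptom scores: SDQ-20 and PHQ-15 within
#' the FND cohort, and PHQ-15 only across FND + PC. Outliers on the
#' connectivity variable (only) are removed with the 1.5 IQR rule per
#' cluster x metric x cohort pairing before correlating; FDR families are
#' (cohort pair, metric).
#'
#' @param mean_tables Named list of cluster-mean tibbles (one per metric)
#'   from [cluster_means()].
#' @param subjects Subject tibble with `sdq20`, `phq15`.
#' @param fnd_groups Character vector of group labels treated as FND.
#' @return Tibble: cohort, metric, cluster_id, symptom, n, rho, p_raw,
#'   p_fdr, family.
#' @export
symptom_correlations <- function(mean_tables, subjects,
                                 fnd_groups = "FND") {
  combos <- list(
    list(cohort = "FND", groups = fnd_groups, symptoms = c("sdq20", "phq15")),
    list(cohort = "FND+PC", groups = c(fnd_groups, "PC"),
         symptoms = "phq15"))
  rows <- list()
  for (metric in names(mean_tables)) {
    tab <- mean_tables[[metric]]
    if (!nrow(tab)) next
    for (cb in combos) {
      ids <- subjects$id[subjects$group %in% cb$groups &
                           subjects$qc_status == "included"]
      for (cl in unique(tab$cluster_id)) {
        sub <- tab[tab$cluster_id == cl & tab$id %in% ids, ]
        sub <- sub[match(intersect(ids, sub$id), sub$id), ]
        flt <- iqr_outlier_filter(sub$mean_value)
        kept_ids <- sub$id[flt$kept]
        for (sym in cb$symptoms) {
          scores <- subjects[[sym]][match(kept_ids, subjects$id)]
          vals <- sub$mean_value[flt$kept]
          ok <- !is.na(scores)
          if (sum(ok) < 4L) next
          ct <- spearman_cor(vals[ok], scores[ok])
          rows[[length(rows) + 1L]] <- tibble::tibble(
            cohort = cb$cohort, metric = metric, cluster_id = cl,
            symptom = sym, n = ct$n, rho = ct$rho, p_raw = ct$p_raw,
            family = paste(cb$cohort, metric, sep = ":"))
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(cohort = character(), metric = character(),
                          cluster_id = integer(), symptom = character(),
                          n = integer(), rho = numeric(), p_raw = numeric(),
                          family = character(), p_fdr = numeric()))
  }
  fdr_correct(dplyr::bind_rows(rows))
}
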