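#' Centroid fiber of a cluster
#'
#' The member with minimum mean MDF distance to all other members (ties go
#' to the lowest fiber index).
#'
#' @param cluster_fibers non-empty list of equally sampled [fiber]s.
#' @return the centroid [fiber].
#' @export
centroid_fiber <- function(cluster_fibers) {
  if (length(cluster_fibers) == 0L) stop("empty cluster")
  if (length(cluster_fibers) == 1L) return(cluster_fibers[[1]])
  D <- cpp_pairwise_mdf(fiber_array(tractogram(cluster_fibers)))
  means <- rowSums(D) / (nrow(D) - 1)
  cluster_fibers[[which.min(means)]]
}

# split a tractogram into per-cluster fiber lists, dropping outliers
split_clusters <- function(t_rs, assignments, exclude_outliers = TRUE) {
  keep <- if (exclude_outliers) !assignments$outlier else rep(TRUE, nrow(assignments))
  split(t_rs$fibers[keep], assignments$label[keep])
}

#' Davies-Bouldin index of a parcellation
#'
#' `DB = (1/n) sum_k max_{i != j} (alpha_i + alpha_j) / d(c_i, c_j)` where
#' `alpha_i` is the mean pairwise MDF distance within cluster i (0 for
#' singletons) and `d(c_i, c_j)` the MDF distance between the clusters'
#' centroid fibers. Lower is better. Coincident centroid fibers across
#' clusters give an infinite contribution, which is reported as such.
#'
#' @param clusters list of fiber lists (one per non-empty cluster), all
#'   resampled to a common np.
#' @param max_fibers per-cluster subsample cap for the scatter term
#'   (default 300; keeps large parcellations tractable). Set `Inf` for the
#'   exact computation.
#' @param seed subsampling seed.
#' @return the DB index (non-negative; possibly `Inf`).
#' @export
db_index <- function(clusters, max_fibers = 300, seed = 1L) {
  clusters <- clusters[lengths(clusters) > 0]
  n <- length(clusters)
  if (n < 2L) stop("DB index needs at least 2 non-empty clusters")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  alpha <- vapply(clusters, function(fl) {
    if (length(fl) < 2L) return(0)
    if (length(fl) > max_fibers) fl <- fl[sort(sample.int(length(fl), max_fibers))]
    D <- cpp_pairwise_mdf(fiber_array(tractogram(fl)))
    mean(D[upper.tri(D)])
  }, numeric(1))
  cents <- lapply(clusters, centroid_fiber)
  Dc <- cpp_pairwise_mdf(fiber_array(tractogram(cents)))
  total <- 0
  for (i in seq_len(n)) {
    r <- -Inf
    for (j in seq_len(n)[-i]) {
      rij <- if (Dc[i, j] > 0) (alpha[i] + alpha[j]) / Dc[i, j] else Inf
      if (rij > r) r <- rij
    }
    total <- total + r
  }
  total / n
}

#' White matter parcellation generalization (WMPG)
#'
#' Fraction of the atlas clusters detected in a subject; a cluster is
#' detected when strictly more than `min_fibers` fibers are assigned to it
#' (a cluster with exactly `min_fibers` members does not count).
#'
#' @param labels integer vector of non-outlier hard labels.
#' @param nc_total total number of atlas clusters.
#' @param min_fibers strict lower bound on the member count (default 20).
#' @return fraction in \[0, 1\].
#' @export
wmpg <- function(labels, nc_total, min_fibers = 20) {
  stopifnot(nc_total >= 1)
  sizes <- tabulate(labels, nbins = nc_total)
  sum(sizes > min_fibers) / nc_total
}

#' Tract anatomical profile coherence (TAPC)
#'
#' Per cluster, the mean Dice score between each member fiber's region set
#' and the cluster's tract anatomical profile; the subject score is the
#' unweighted mean over non-empty clusters.
#'
#' @param clusters list of labelled fiber lists.
#' @param threshold profile threshold (default 0.40).
#' @return list with `score` and per-cluster values `per_cluster`.
#' @export
tapc <- function(clusters, threshold = 0.40) {
  clusters <- clusters[lengths(clusters) > 0]
  if (length(clusters) == 0L) stop("empty parcellation")
  per <- vapply(clusters, function(fl) {
    prof <- tract_anatomical_profile(fl, threshold)
    mean(vapply(fl, dice_anatomical, numeric(1), profile = prof))
  }, numeric(1))
  list(score = mean(per), per_cluster = per)
}

#' Tract surface profile coherence (TSPC)
#'
#' Per cluster, the mean of the tract surface profile fractions over all
#' parcels intersected by the cluster's endpoints; the subject score is the
#' unweighted mean over clusters with at least one labelled endpoint.
#'
#' @param clusters list of fiber lists with endpoint parcels.
#' @return list with `score`, `per_cluster`, and the indices of clusters
#'   excluded for having no labelled endpoints.
#' @export
tspc <- function(clusters) {
  clusters <- clusters[lengths(clusters) > 0]
  if (length(clusters) == 0L) stop("empty parcellation")
  per <- vapply(clusters, function(fl) {
    prof <- tract_surface_profile(fl)
    if (length(prof$fractions) == 0L) return(NA_real_)
    mean(prof$fractions)
  }, numeric(1))
  list(score = mean(per, na.rm = TRUE), per_cluster = per,
       excluded = which(is.na(per)))
}

#' Parcellation quality report
#'
#' Computes the four parcellation metrics on a clustered tractogram:
#' Davies-Bouldin index (compactness/separation), WMPG (fraction of
#' clusters detected), and, when the fibers carry anatomical labels, TAPC
#' and TSPC (anatomical and cortical-termination coherence). Outlier-flagged
#' fibers are excluded throughout.
#'
#' @param t_rs the resampled (and, for TAPC/TSPC, labelled) [tractogram].
#' @param assignments assignment data frame ([infer()] output).
#' @param nc_total total cluster count of the atlas.
#' @param exclude_outliers drop flagged fibers (default TRUE).
#' @param db_max_fibers subsample cap for [db_index()].
#' @return object of class `parcellation_report` with fields `db`, `wmpg`,
#'   `tapc`, `tspc` and per-cluster breakdowns.
#' @export
evaluate_parcellation <- function(t_rs, assignments, nc_total,
                                  exclude_outliers = TRUE,
                                  db_max_fibers = 300) {
  clusters <- split_clusters(t_rs, assignments, exclude_outliers)
  keep <- if (exclude_outliers) !assignments$outlier else rep(TRUE, nrow(assignments))
  has_anatomy <- length(clusters) > 0 && fiber_has_labels(clusters[[1]][[1]])
  report <- list(
    db = db_index(clusters, max_fibers = db_max_fibers),
    wmpg = wmpg(assignments$label[keep], nc_total),
    tapc = if (has_anatomy) tapc(clusters) else NULL,
    tspc = if (has_anatomy) tspc(clusters) else NULL,
    nc_total = nc_total, n_fibers = sum(keep),
    cluster_sizes = tabulate(assignments$label[keep], nbins = nc_total))
  class(report) <- "parcellation_report"
  report
}

#' @export
print.parcellation_report <- function(x, ...) {
  cat(sprintf("Parcellation report (%d fibers, %d clusters):\n",
              x$n_fibers, x$nc_total))
  cat(sprintf("  DB index : %.4f (lower is better)\n", x$db))
  cat(sprintf("  WMPG     : %.4f\n", x$wmpg))
  if (!is.null(x$tapc)) cat(sprintf("  TAPC     : %.4f\n", x$tapc$score))
  if (!is.null(x$tspc)) cat(sprintf("  TSPC     : %.4f\n", x$tspc$score))
  invisible(x)
}

#' Write a parcellation report to JSON and CSV
#'
#' @param report a `parcellation_report`.
#' @param json_path path for the summary JSON (NULL to skip).
#' @param csv_path path for the per-cluster CSV breakdown (NULL to skip).
#' @return the report, invisibly.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(db = report$db, wmpg = report$wmpg,
                              tapc = if (!is.null(report$tapc)) report$tapc$score,
                              tspc = if (!is.null(report$tspc)) report$tspc$score,
                              n_fibers = report$n_fibers,
                              nc_total = report$nc_total),
                         json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(csv_path)) {
    df <- data.frame(cluster = seq_len(report$nc_total),
                     size = report$cluster_sizes)
    if (!is.null(report$tapc)) {
      v <- rep(NA_real_, report$nc_total)
      v[as.integer(names(report$tapc$per_cluster))] <- report$tapc$per_cluster
      df$tapc <- v
    }
    if (!is.null(report$tspc)) {
      v <- rep(NA_real_, report$nc_total)
      v[as.integer(names(report$tspc$per_cluster))] <- report$tspc$per_cluster
      df$tspc <- v
    }
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(report)
}
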