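#' Clustering-stage training configuration
#'
#' @param lambda weight of the KL clustering loss in the total loss
#'   `L = Lp + lambda * Lc` (default 0.1).
#' @param iters1,lr1 long phase of the clustering stage (default 2000 at
#'   1e-4, matching the pretraining schedule shape).
#' @param iters2,lr2 refinement phase (default 200 at 1e-5).
#' @param batch_pairs fiber pairs per iteration (default 256; the KL loss
#'   sees both pair members, so 512 fibers per batch).
#' @param profile_update_interval iterations between refreshes of the target
#'   distribution and the anatomical/surface profiles (default 200).
#' @param epsilon floor applied to the (1 - Dice) factors of the anatomical
#'   assignment before inversion (default 0.1, capping each factor's boost
#'   at 10x so that anatomy modulates but never drowns the geometric
#'   assignment probability).
#' @param seed integer RNG seed.
#' @return object of class `train_config`.
#' @export
train_config <- function(lambda = 0.1, iters1 = 2000, lr1 = 1e-4,
                         iters2 = 200, lr2 = 1e-5, batch_pairs = 256,
                         profile_update_interval = 200, epsilon = 0.1,
                         seed = 1L) {
  stopifnot(lambda >= 0, epsilon > 0, profile_update_interval >= 1)
  structure(list(lambda = lambda, iters1 = iters1, lr1 = lr1, iters2 = iters2,
                 lr2 = lr2, batch_pairs = batch_pairs,
                 profile_update_interval = as.integer(profile_update_interval),
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

#' Outlier-removal configuration
#'
#' @param n non-negative standard-deviation multiplier of the per-cluster
#'   threshold `T_c = m_c - n * s_c` (default 1).
#' @return object of class `outlier_config`.
#' @export
outlier_config <- function(n = 1) {
  stopifnot(n >= 0)
  structure(list(n = n), class = "outlier_config")
}

#' k-means initialisation of cluster centroids
#'
#' k-means++ seeding followed by Lloyd iterations on the embeddings; fully
#' reproducible from the seed.
#'
#' @param embeddings n x n_e matrix.
#' @param nc number of clusters (needs `n >= nc`).
#' @param seed integer RNG seed.
#' @return list with `centroids` (nc x n_e) and `labels` (length n, 1-based).
#' @export
kmeans_init <- function(embeddings, nc, seed = 1L) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < nc) stop("need at least nc = ", nc, " fibers for k-means")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  centers <- kmeanspp_seed(embeddings, nc)
  km <- suppressWarnings(stats::kmeans(embeddings, centers = centers,
                                       iter.max = 100, algorithm = "Lloyd"))
  centroids <- unname(km$centers)
  list(centroids = centroids, labels = unname(km$cluster))
}

# k-means++ seeding (base stats::kmeans has none)
kmeanspp_seed <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1) + 1) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[i, ], n, ncol(x), byrow = TRUE))^2))
  }
  # nudge exact duplicates so stats::kmeans accepts the centers
  dup <- duplicated(round(centers, 12))
  if (any(dup)) centers[dup, ] <- centers[dup, ] + 1e-9 * seq_len(sum(dup))
  centers
}

#' Geometric soft assignment (Student's-t kernel)
#'
#' `q_j = (1 + ||z - mu_j||^2)^-1 / sum_j' (1 + ||z - mu_j'||^2)^-1`:
#' the Student's-t similarity (one degree of freedom) between an embedding
#' and each cluster centroid, normalised to a probability vector.
#'
#' @param z embedding vector (or n x n_e matrix for many fibers).
#' @param centroids nc x n_e centroid matrix.
#' @return probability vector (or n x nc matrix); rows sum to 1.
#' @export
soft_assign_geometric <- function(z, centroids) {
  z <- if (is.null(dim(z))) matrix(z, 1) else as.matrix(z)
  w <- student_t_kernel(z, centroids)
  q <- w / rowSums(w)
  if (nrow(q) == 1L) drop(q) else q
}

student_t_kernel <- function(z, centroids) {
  d2 <- outer(rowSums(z^2), rep(1, nrow(centroids))) +
        outer(rep(1, nrow(z)), rowSums(centroids^2)) -
        2 * z %*% t(centroids)
  1 / (1 + pmax(d2, 0))
}

#' Anatomically informed soft assignment
#'
#' Extends the geometric assignment with two anatomical agreement factors:
#' `q_j` is proportional to `[(1 + ||z - mu_j||^2) * (1 - Da_j) * (1 - Dc_j)]^-1`,
#' where `Da_j` is the Dice score between the fiber's region set and cluster
#' j's tract anatomical profile and `Dc_j` the fiber's endpoint agreement
#' with cluster j's tract surface profile. Each `(1 - D)` factor is floored
#' at `epsilon` before inversion so a perfect agreement yields the maximal
#' finite weight; the default floor of 0.1 caps the boost at 10x per factor,
#' which keeps the within-cluster ranking of assignment probabilities (used
#' by outlier removal) governed by geometry. With all-zero agreement scores this reduces exactly to
#' [soft_assign_geometric()].
#'
#' @param f a [fiber] carrying point labels and endpoint parcels.
#' @param z its embedding vector.
#' @param model a [fiber_cluster] model (or any list with `centroids`,
#'   `anatomical_profiles`, `surface_profiles`).
#' @param epsilon floor for the agreement factors (default 0.1).
#' @return probability vector over clusters, summing to 1.
#' @export
soft_assign_anatomical <- function(f, z, model, epsilon = 0.1) {
  da <- vapply(model$anatomical_profiles, function(p) dice_anatomical(f, p),
               numeric(1))
  dc <- vapply(model$surface_profiles, function(p) endpoint_agreement(f, p),
               numeric(1))
  soft_assign_anatomical_scores(z, model$centroids, da, dc, epsilon)
}

soft_assign_anatomical_scores <- function(z, centroids, da, dc, epsilon = 0.1) {
  w_geo <- drop(student_t_kernel(matrix(z, 1), centroids))
  w <- w_geo / (pmax(1 - da, epsilon) * pmax(1 - dc, epsilon))
  w / sum(w)
}

#' Self-training target distribution
#'
#' Sharpens a soft-assignment matrix: `p_ij` proportional to
#' `q_ij^2 / f_j` with soft cluster frequencies `f_j = sum_i q_ij`, rows
#' renormalised. Confident assignments reinforce themselves while the
#' frequency normalisation discourages cluster collapse. Empty (zero
#' frequency) clusters are dropped from the computation for the batch.
#'
#' @param Q n x nc matrix of soft assignments (rows sum to 1).
#' @return n x nc matrix P with rows summing to 1.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  live <- f > 0
  P <- matrix(0, nrow(Q), ncol(Q))
  Pl <- sweep(Q[, live, drop = FALSE]^2, 2, f[live], "/")
  P[, live] <- Pl / rowSums(Pl)
  dimnames(P) <- dimnames(Q)
  P
}

#' KL clustering loss
#'
#' `KL(P || Q)` averaged over rows (fibers): the self-training loss that
#' pulls the soft assignments Q towards the sharpened targets P.
#'
#' @param Q,P matched n x nc matrices with normalised rows.
#' @return non-negative number; 0 iff `P == Q`.
#' @export
clustering_loss <- function(Q, P) {
  Q <- as.matrix(Q); P <- as.matrix(P)
  stopifnot(all(dim(Q) == dim(P)))
  q <- pmax(Q, 1e-12)
  terms <- ifelse(P > 0, P * log(P / q), 0)
  sum(terms) / nrow(Q)
}

#' Total training loss
#'
#' @param lp distance-prediction (pretext) loss.
#' @param lc KL clustering loss.
#' @param lambda clustering-loss weight (default 0.1).
#' @return `lp + lambda * lc`.
#' @export
total_loss <- function(lp, lc, lambda = 0.1) {
  stopifnot(lambda >= 0)
  lp + lambda * lc
}

#' Recompute per-cluster anatomical and surface profiles
#'
#' Rebuilds both profile tables from the current hard labels. Clusters with
#' no members get empty profiles.
#'
#' @param labels integer vector of 1-based hard cluster labels.
#' @param fibers list of labelled [fiber]s (same order as `labels`).
#' @param nc number of clusters.
#' @param threshold anatomical-profile fraction threshold (default 0.40).
#' @return list with `anatomical_profiles` and `surface_profiles`, each a
#'   length-nc list.
#' @export
update_profiles <- function(labels, fibers, nc, threshold = 0.40) {
  anatomical <- vector("list", nc)
  surface <- vector("list", nc)
  empty_a <- structure(list(regions = integer(0), threshold = threshold),
                       class = "tract_anatomical_profile")
  empty_s <- structure(list(fractions = numeric(0)),
                       class = "tract_surface_profile")
  for (j in seq_len(nc)) {
    members <- fibers[labels == j]
    if (length(members) == 0L) {
      anatomical[[j]] <- empty_a
      surface[[j]] <- empty_s
    } else {
      anatomical[[j]] <- tract_anatomical_profile(members, threshold)
      surface[[j]] <- tract_surface_profile(members)
    }
  }
  list(anatomical_profiles = anatomical, surface_profiles = surface)
}

#' Flag outlier fibers with a cluster-adaptive threshold
#'
#' Per cluster c the mean `m_c` and sample standard deviation `s_c`
#' (divisor N-1; 0 for singleton clusters) of the members' maximum
#' assignment probabilities `q_m` are computed, and members with
#' `q_m < T_c = m_c - n * s_c` (strictly) are flagged. Flagged fibers stay
#' in the assignment record but are excluded from downstream metrics and
#' outputs.
#'
#' @param assignments data frame with columns `label` and `qm` (one row per
#'   fiber), as produced by [infer()].
#' @param cfg an [outlier_config] (or the multiplier `n` directly).
#' @return the data frame with its `outlier` column set.
#' @export
remove_outliers <- function(assignments, cfg = outlier_config()) {
  n <- if (inherits(cfg, "outlier_config")) cfg$n else as.numeric(cfg)
  stopifnot(n >= 0)
  out <- logical(nrow(assignments))
  for (j in unique(assignments$label)) {
    idx <- which(assignments$label == j)
    qm <- assignments$qm[idx]
    s <- if (length(qm) > 1L) stats::sd(qm) else 0
    thr <- mean(qm) - n * s
    out[idx] <- qm < thr
  }
  assignments$outlier <- out
  assignments
}

#' Choose the outlier multiplier that removes a target fraction of fibers
#'
#' Scans `n` downward until the flagged fraction is at least `fraction`
#' (matching a removal budget, e.g. a known contamination rate).
#'
#' @param assignments data frame with `label` and `qm`.
#' @param fraction target flagged fraction in (0, 1).
#' @param grid candidate multipliers (default a fine descending grid).
#' @return the selected multiplier `n`.
#' @export
match_outlier_fraction <- function(assignments, fraction,
                                   grid = seq(3, 0, by = -0.01)) {
  stopifnot(fraction > 0, fraction < 1)
  for (n in grid) {
    flagged <- mean(remove_outliers(assignments, outlier_config(n))$outlier)
    if (flagged >= fraction) return(n)
  }
  0
}
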