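#' Fit a fiber-clustering model (atlas) to a tractogram
#'
#' Runs the full two-stage pipeline: (1) pretraining, where the Siamese
#' edge-convolution encoder learns to regress pairwise MDF distances so that
#' embedding-space distances mirror fiber-space distances regardless of
#' point order; (2) clustering, where k-means initialises `nc` centroids in
#' embedding space and the encoder and centroids are fine-tuned jointly
#' against `L = Lp + lambda * Lc`, with `Lc` the KL self-training loss on the
#' Student's-t soft assignments. When anatomical volumes are supplied, hard
#' assignments and the per-cluster tract anatomical / surface profiles use
#' the anatomically informed assignment and are refreshed iteratively.
#' Finally, fibers with low maximum assignment probability are flagged by
#' the cluster-adaptive rule `q_m < m_c - n * s_c`.
#'
#' @param x a [tractogram] (world-mm coordinates).
#' @param nc number of clusters (default 800 for whole-brain parcellation;
#'   use small values for bundle-scale problems).
#' @param regions optional [label_volume] of anatomical regions.
#' @param parcels optional [label_volume] of cortical endpoint parcels.
#' @param np points per fiber for the network input (default 14).
#' @param min_length_mm length filter applied before training (default 40).
#' @param encoder an [encoder_config]; its `np` must match `np`.
#' @param train a [train_config] (clustering stage; `lambda`, schedule,
#'   profile refresh cadence).
#' @param pretrain_iters1,pretrain_lr1,pretrain_iters2,pretrain_lr2,batch_pairs
#'   pretraining schedule (defaults: 2000 at 1e-4, then 200 at 1e-5,
#'   batch 256).
#' @param outlier an [outlier_config].
#' @param seed master RNG seed for the whole fit.
#' @param verbose print stage progress.
#' @return an object of class `fiber_cluster`: the trained encoder, the
#'   centroids, the profile tables, and the training-data assignments.
#' @export
fiber_cluster <- function(x, nc = 800, regions = NULL, parcels = NULL,
                          np = 14, min_length_mm = 40,
                          encoder = encoder_config(np = np),
                          train = train_config(),
                          pretrain_iters1 = 2000, pretrain_lr1 = 1e-4,
                          pretrain_iters2 = 200, pretrain_lr2 = 1e-5,
                          batch_pairs = 256,
                          outlier = outlier_config(), seed = 1L,
                          verbose = TRUE) {
  stopifnot(inherits(x, "tractogram"), nc >= 2)
  if (encoder$np != np) stop("encoder$np must equal np")
  anatomy <- !is.null(regions) && !is.null(parcels)
  say <- function(...) if (verbose) message(sprintf(...))

  t_full <- filter_by_length(x, min_length_mm)
  if (length(t_full$fibers) < nc)
    stop("fewer fibers than clusters after length filtering")
  if (anatomy) t_full <- label_tractogram(t_full, regions, parcels)
  t_rs <- resample_tractogram(t_full, np)
  arr <- fiber_array(t_rs)

  say("pretraining encoder on %d fibers (%d + %d iterations)",
      dim(arr)[3], pretrain_iters1, pretrain_iters2)
  pre <- pretrain(t_rs, encoder, iters1 = pretrain_iters1, lr1 = pretrain_lr1,
                  iters2 = pretrain_iters2, lr2 = pretrain_lr2,
                  batch_pairs = batch_pairs, seed = seed)

  say("k-means initialisation (nc = %d)", nc)
  Z <- encode(arr, encoder, pre$params)
  km <- kmeans_init(Z, nc, seed = seed)

  model <- structure(list(
    params = pre$params, encoder = encoder, centroids = km$centroids,
    nc = as.integer(nc), anatomy = anatomy,
    anatomical_profiles = NULL, surface_profiles = NULL,
    train = train, outlier = outlier, np = as.integer(np),
    min_length_mm = min_length_mm, seed = as.integer(seed),
    pretrain_log = pre$log, version = 1L), class = "fiber_cluster")
  if (anatomy) {
    prof <- update_profiles(km$labels, t_rs$fibers, nc)
    model$anatomical_profiles <- prof$anatomical_profiles
    model$surface_profiles <- prof$surface_profiles
  }

  say("clustering stage (%d + %d iterations, lambda = %g)",
      train$iters1, train$iters2, train$lambda)
  model <- train_clustering_stage(t_rs, model, train, verbose = verbose)

  assignments <- infer(t_rs, model)
  assignments <- remove_outliers(assignments, outlier)
  model$assignments <- assignments
  model$call <- match.call()
  model
}

#' Clustering-stage fine-tuning
#'
#' Jointly optimises the encoder parameters and the cluster centroids
#' against `L = Lp + lambda * Lc` (the distance-prediction loss is retained
#' throughout). Training proceeds in chunks of
#' `cfg$profile_update_interval` iterations; between chunks the target
#' distribution is recomputed from the full data set and, when anatomy is
#' available, the hard labels and both profile tables are refreshed using
#' the anatomically informed assignment. The KL loss itself is computed on
#' the geometric (smooth) assignment. Because the pretext loss constrains
#' only pairwise distances (the embedding cloud has a free translation),
#' each refresh also re-anchors the centroids to the soft cluster means
#' before the target distribution is rebuilt (skipped when `lambda = 0`,
#' where the clustering loss is ablated).
#'
#' @param t_rs a [tractogram] resampled to the model's `np` (labelled when
#'   the model uses anatomy).
#' @param model a [fiber_cluster] model skeleton (from the pretraining and
#'   k-means steps).
#' @param cfg a [train_config].
#' @param verbose print per-chunk losses.
#' @return the model with updated `params`, `centroids`, profiles and a
#'   `cluster_log` matrix.
#' @export
train_clustering_stage <- function(t_rs, model, cfg = train_config(),
                                   verbose = FALSE) {
  arr <- fiber_array(t_rs)
  nb <- along_fiber_graph(model$encoder$np, model$encoder$k) - 1L
  ccfg <- cfg_for_cpp(model$encoder)
  params <- model$params
  centroids <- model$centroids
  adam <- NULL
  t0 <- 0L
  logs <- list()
  phases <- list(c(cfg$iters1, cfg$lr1), c(cfg$iters2, cfg$lr2))
  chunk_seed <- cfg$seed + 1000L
  for (ph in phases) {
    remaining <- ph[1]
    lr <- ph[2]
    while (remaining > 0) {
      it <- min(cfg$profile_update_interval, remaining)
      Z <- cpp_encode(arr, params, ccfg, nb)
      Q <- soft_assign_geometric(Z, centroids)
      if (cfg$lambda > 0) {
        # soft k-means recentering: the pretext loss constrains only pairwise
        # distances, so the embedding cloud can drift as a whole; re-anchor
        # the centroids to the soft cluster means at every refresh
        mass <- colSums(Q)
        live <- mass > 0
        centroids[live, ] <- sweep(t(Q[, live, drop = FALSE]) %*% Z, 1,
                                   mass[live], "/")
        Q <- soft_assign_geometric(Z, centroids)
      }
      P <- target_distribution(Q)
      res <- cpp_train(arr, params, ccfg, nb, it, lr, cfg$batch_pairs,
                       seed = chunk_seed, clustering = TRUE,
                       centroids = centroids, Ptarget = t(P),
                       lambda = cfg$lambda, adam_state = adam, t0 = t0,
                       log_every = it)
      params <- res$params
      centroids <- res$centroids
      adam <- res$adam
      t0 <- res$t
      logs[[length(logs) + 1L]] <- res$log
      chunk_seed <- chunk_seed + 1L
      remaining <- remaining - it
      if (model$anatomy) {
        # refresh hard labels and profiles under the anatomical assignment
        model$params <- params
        model$centroids <- centroids
        a <- infer(t_rs, model)
        prof <- update_profiles(a$label, t_rs$fibers, model$nc)
        model$anatomical_profiles <- prof$anatomical_profiles
        model$surface_profiles <- prof$surface_profiles
      }
      if (verbose && length(logs) > 0) {
        last <- logs[[length(logs)]]
        if (nrow(last) > 0)
          message(sprintf("  iter %d: Lp=%.4f Lc=%.4f L=%.4f",
                          as.integer(last[nrow(last), 1]), last[nrow(last), 2],
                          last[nrow(last), 3], last[nrow(last), 4]))
      }
    }
  }
  model$params <- params
  model$centroids <- centroids
  model$cluster_log <- do.call(rbind, logs)
  if (!is.null(model$cluster_log))
    colnames(model$cluster_log) <- c("iteration", "lp", "lc", "total")
  model
}

#' Assign fibers to clusters
#'
#' Embeds each fiber and computes its soft assignment vector: the
#' anatomically informed assignment when the model carries profiles and the
#' fiber carries labels, otherwise the geometric Student's-t assignment.
#' The hard label is the argmax (ties to the lowest cluster index) and
#' `qm` its probability. Outlier flags are initialised to FALSE (set by
#' [remove_outliers()]).
#'
#' @param t_rs a [tractogram] resampled to the model's `np`.
#' @param model a [fiber_cluster] model.
#' @return data frame: `fiber`, `label`, `qm`, `outlier`.
#' @export
infer <- function(t_rs, model) {
  arr <- fiber_array(t_rs)
  Z <- encode(arr, model$encoder, model$params)
  n <- nrow(Z)
  use_anatomy <- model$anatomy && !is.null(model$anatomical_profiles) &&
    fiber_has_labels(t_rs$fibers[[1]])
  labels <- integer(n)
  qm <- numeric(n)
  if (use_anatomy) {
    eps <- if (!is.null(model$train)) model$train$epsilon else 0.1
    da_dc <- precompute_agreement(t_rs$fibers, model)
    for (i in seq_len(n)) {
      q <- soft_assign_anatomical_scores(Z[i, ], model$centroids,
                                         da_dc$da[i, ], da_dc$dc[i, ], eps)
      labels[i] <- which.max(q)
      qm[i] <- q[labels[i]]
    }
  } else {
    Q <- soft_assign_geometric(Z, model$centroids)
    if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
    labels <- max.col(Q, ties.method = "first")
    qm <- Q[cbind(seq_len(n), labels)]
  }
  data.frame(fiber = seq_len(n), label = labels, qm = qm, outlier = FALSE)
}

fiber_has_labels <- function(f) {
  (!is.null(f$point_labels) || !is.null(f$point_labels_full)) &&
    !is.null(f$endpoint_parcels)
}

precompute_agreement <- function(fibers, model) {
  n <- length(fibers)
  nc <- model$nc
  da <- matrix(0, n, nc)
  dc <- matrix(0, n, nc)
  for (i in seq_len(n)) {
    for (j in seq_len(nc)) {
      da[i, j] <- dice_anatomical(fibers[[i]], model$anatomical_profiles[[j]])
      dc[i, j] <- endpoint_agreement(fibers[[i]], model$surface_profiles[[j]])
    }
  }
  list(da = da, dc = dc)
}

#' Predict cluster assignments for a new tractogram
#'
#' Applies the trained atlas to an independently acquired tractogram:
#' length-filters with the training threshold, attaches anatomical labels
#' when volumes are given, resamples to the model's `np`, assigns each fiber
#' to the cluster with the maximum soft assignment probability, and flags
#' outliers with the cluster-adaptive rule.
#'
#' @param object a [fiber_cluster] model.
#' @param newdata a [tractogram].
#' @param regions,parcels optional [label_volume]s; required for the
#'   anatomically informed assignment path.
#' @param outlier an [outlier_config], or NULL to skip flagging.
#' @param filter apply the training length filter (default TRUE).
#' @param ... unused.
#' @return data frame: `fiber`, `label`, `qm`, `outlier`.
#' @export
predict.fiber_cluster <- function(object, newdata, regions = NULL,
                                  parcels = NULL, outlier = object$outlier,
                                  filter = TRUE, ...) {
  stopifnot(inherits(newdata, "tractogram"))
  t <- if (filter) filter_by_length(newdata, object$min_length_mm) else newdata
  if (length(t$fibers) == 0L) stop("no fibers to assign")
  if (!is.null(regions) || !is.null(parcels))
    t <- label_tractogram(t, regions, parcels)
  t_rs <- resample_tractogram(t, object$np)
  a <- infer(t_rs, object)
  if (!is.null(outlier)) a <- remove_outliers(a, outlier)
  a
}

#' @export
print.fiber_cluster <- function(x, ...) {
  cat(sprintf("Fiber clustering model: %d clusters, %d-D embeddings\n",
              x$nc, x$encoder$fc[3]))
  cat(sprintf("  encoder: %d EdgeConv layers (widths %s), np=%d, k=%d\n",
              length(x$encoder$widths),
              paste(x$encoder$widths, collapse = ","), x$encoder$np,
              x$encoder$k))
  cat(sprintf("  anatomy-informed assignment: %s\n",
              if (x$anatomy) "yes" else "no"))
  if (!is.null(x$assignments))
    cat(sprintf("  training data: %d fibers, %.1f%% flagged as outliers\n",
                nrow(x$assignments), 100 * mean(x$assignments$outlier)))
  invisible(x)
}

#' @export
summary.fiber_cluster <- function(object, ...) {
  a <- object$assignments
  sizes <- tabulate(a$label[!a$outlier], nbins = object$nc)
  out <- list(nc = object$nc, n_fibers = nrow(a),
              outlier_fraction = mean(a$outlier),
              cluster_sizes = sizes, qm = summary(a$qm),
              final_loss = if (!is.null(object$cluster_log) &&
                               nrow(object$cluster_log) > 0)
                object$cluster_log[nrow(object$cluster_log), "total"] else NA)
  class(out) <- "summary.fiber_cluster"
  out
}

#' @export
print.summary.fiber_cluster <- function(x, ...) {
  cat(sprintf("Fiber clustering model: %d clusters over %d fibers\n",
              x$nc, x$n_fibers))
  cat(sprintf("  outlier fraction: %.3f\n", x$outlier_fraction))
  cat(sprintf("  cluster sizes: min %d / median %.0f / max %d (non-outlier)\n",
              min(x$cluster_sizes), stats::median(x$cluster_sizes),
              max(x$cluster_sizes)))
  cat("  max assignment probability (qm):\n")
  print(x$qm)
  invisible(x)
}

#' Cluster centroids of a fitted model
#' @param object a [fiber_cluster] model.
#' @param ... unused.
#' @return nc x n_e matrix of embedding-space centroids.
#' @export
coef.fiber_cluster <- function(object, ...) object$centroids

#' Plot a fitted fiber-clustering model
#'
#' Left: the first two principal components of the training embeddings,
#' coloured by hard cluster label (outliers in grey crosses). Right: the
#' training loss trace.
#'
#' @param x a [fiber_cluster] model.
#' @param embeddings optional n x n_e matrix (recomputed embeddings); when
#'   NULL only the loss trace is drawn.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fiber_cluster <- function(x, embeddings = NULL, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(embeddings)) 1 else 2))
  on.exit(graphics::par(op))
  if (!is.null(embeddings)) {
    pc <- stats::prcomp(embeddings)$x[, 1:2]
    cols <- grDevices::hcl.colors(x$nc, "Dark 3")[x$assignments$label]
    pch <- ifelse(x$assignments$outlier, 4L, 16L)
    cols[x$assignments$outlier] <- "grey60"
    graphics::plot(pc, col = cols, pch = pch, xlab = "PC1", ylab = "PC2",
                   main = "embeddings", ...)
  }
  log <- rbind(x$pretrain_log, x$cluster_log)
  if (!is.null(log) && nrow(log) > 0)
    graphics::plot(log[, 1], log[, 4], type = "l", xlab = "iteration",
                   ylab = "loss", main = "training loss")
  invisible(x)
}

#' Save a fitted atlas to disk
#'
#' The atlas bundles the encoder parameters and configuration, centroids,
#' both profile tables and all training configuration in one file.
#'
#' @param model a [fiber_cluster] model.
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_atlas <- function(model, path) {
  stopifnot(inherits(model, "fiber_cluster"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a fitted atlas
#' @param path path written by [save_atlas()].
#' @return a [fiber_cluster] model.
#' @export
load_atlas <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fiber_cluster"))
    stop("not a fiber_cluster atlas: ", path)
  if (is.null(model$version) || model$version > 1L)
    stop("unknown atlas version; this build reads version 1")
  model
}
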