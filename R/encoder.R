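#' Encoder configuration
#'
#' Architecture and input geometry of the edge-convolution fiber encoder:
#' a stack of EdgeConv layers over a fixed along-fiber graph, a pointwise
#' global descriptor over the concatenated layer outputs with max-pooling
#' over points, and a fully connected head producing the embedding.
#'
#' @param np points per fiber after resampling (default 14).
#' @param k neighbours per point in the along-fiber graph (default 4);
#'   neighbours are the k sequence-nearest point indices, identical for
#'   every fiber.
#' @param widths output channels of the EdgeConv layers (default
#'   `c(16, 16, 24, 24, 32)`: five layers sized for CPU training).
#' @param cg width of the global point descriptor (default 96).
#' @param fc widths of the fully connected head; the last entry is the
#'   embedding dimensionality n_e (default `c(64, 32, 10)`).
#' @param slope LeakyReLU negative slope (default 0.2). No normalisation
#'   layers are used; weights are He-initialised.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(np = 14, k = 4, widths = c(16L, 16L, 24L, 24L, 32L),
                           cg = 96, fc = c(64L, 32L, 10L), slope = 0.2) {
  stopifnot(np >= 2, k >= 2, k < np, length(fc) == 3, all(widths > 0),
            all(fc > 0), fc[3] >= 2, cg > 0)
  structure(list(np = as.integer(np), k = as.integer(k),
                 widths = as.integer(widths), cg = as.integer(cg),
                 fc = as.integer(fc), slope = slope),
            class = "encoder_config")
}

#' Along-fiber neighbourhood graph
#'
#' For each point index t, the neighbour set is the k indices nearest to t
#' in sequence position (for interior points with k = 4 that is
#' t-2, t-1, t+1, t+2; at the fiber ends the k nearest valid indices are
#' used). The structure is data-independent: every fiber shares it.
#'
#' @param np number of points per fiber.
#' @param k neighbours per point, `2 <= k < np`.
#' @return integer matrix np x k of 1-based neighbour indices.
#' @export
along_fiber_graph <- function(np, k) {
  if (k >= np) stop("k must be smaller than the number of points")
  if (k < 1) stop("k must be positive")
  nb <- matrix(0L, np, k)
  for (t in seq_len(np)) {
    others <- setdiff(seq_len(np), t)
    d <- abs(others - t)
    # stable order: distance, then index -> deterministic boundary fill
    nb[t, ] <- others[order(d, others)][seq_len(k)]
  }
  nb
}

# canonical parameter list (see src/network.cpp for the layout)
param_shapes <- function(cfg) {
  shapes <- list()
  cin <- 3L
  for (l in seq_along(cfg$widths)) {
    co <- cfg$widths[l]
    shapes[[paste0("We", l)]] <- c(co, 2L * cin)
    shapes[[paste0("be", l)]] <- c(co, 1L)
    cin <- co
  }
  shapes$Wg <- c(cfg$cg, sum(cfg$widths))
  shapes$bg <- c(cfg$cg, 1L)
  dims <- c(cfg$cg, cfg$fc)
  for (i in 1:3) {
    shapes[[paste0("Wf", i)]] <- c(dims[i + 1], dims[i])
    shapes[[paste0("bf", i)]] <- c(dims[i + 1], 1L)
  }
  shapes
}

#' Initialise encoder parameters
#'
#' He-initialised weights (normal with sd `sqrt(2 / fan_in)`), zero biases;
#' fully reproducible from the seed.
#'
#' @param cfg an [encoder_config].
#' @param seed integer RNG seed.
#' @return named list of parameter matrices.
#' @export
init_encoder <- function(cfg, seed = 1L) {
  shapes <- param_shapes(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  params <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (startsWith(nm, "b")) return(matrix(0, sh[1], sh[2]))
    matrix(stats::rnorm(prod(sh), sd = sqrt(2 / sh[2])), sh[1], sh[2])
  })
  names(params) <- names(shapes)
  params
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

cfg_for_cpp <- function(cfg) {
  list(np = cfg$np, k = cfg$k, widths = cfg$widths, cg = cfg$cg,
       fc = cfg$fc, slope = cfg$slope)
}

#' Embed fibers with the encoder
#'
#' Deterministic forward pass of the edge-convolution network.
#'
#' @param t a [tractogram] resampled to `cfg$np` points (or a single
#'   [fiber], or an np x 3 x n array).
#' @param cfg an [encoder_config].
#' @param params parameter list from [init_encoder()] / [pretrain()].
#' @return n x n_e matrix of embeddings (one row per fiber).
#' @export
encode <- function(t, cfg, params) {
  arr <- if (inherits(t, "fiber")) {
    array(t$points, dim = c(nrow(t$points), 3, 1))
  } else if (inherits(t, "tractogram")) fiber_array(t) else as.array(t)
  if (dim(arr)[1] != cfg$np)
    stop("fibers must be resampled to np = ", cfg$np, " points")
  cpp_encode(arr, params, cfg_for_cpp(cfg), along_fiber_graph(cfg$np, cfg$k) - 1L)
}

#' Siamese distance between two fibers
#'
#' Euclidean distance between the two embeddings; exactly symmetric because
#' both subnetworks share one parameter set. After pretraining this predicts
#' the MDF distance.
#'
#' @param a,b [fiber]s resampled to `cfg$np` points.
#' @param cfg an [encoder_config].
#' @param params encoder parameters.
#' @return non-negative number (mm scale after training).
#' @export
siamese_distance <- function(a, b, cfg, params) {
  arr <- array(0, dim = c(cfg$np, 3, 2))
  arr[, , 1] <- a$points
  arr[, , 2] <- b$points
  z <- cpp_encode(arr, params, cfg_for_cpp(cfg),
                  along_fiber_graph(cfg$np, cfg$k) - 1L)
  sqrt(sum((z[1, ] - z[2, ])^2))
}

#' Pretext loss of a batch of fiber pairs
#'
#' Mean squared error between the predicted (embedding-space) distance and
#' the MDF pseudo-label of each pair.
#'
#' @param pairs_a,pairs_b [tractogram]s (or np x 3 x m arrays) holding the
#'   two sides of m pairs.
#' @param cfg an [encoder_config].
#' @param params encoder parameters.
#' @return list with `lp` (the loss) and `labels` (the MDF pseudo-labels).
#' @export
pretrain_loss <- function(pairs_a, pairs_b, cfg, params) {
  A <- if (inherits(pairs_a, "tractogram")) fiber_array(pairs_a) else as.array(pairs_a)
  B <- if (inherits(pairs_b, "tractogram")) fiber_array(pairs_b) else as.array(pairs_b)
  m <- dim(A)[3]
  stopifnot(dim(B)[3] == m, m >= 1)
  batch <- array(0, dim = c(cfg$np, 3, 2 * m))
  batch[, , seq_len(m)] <- A
  batch[, , m + seq_len(m)] <- B
  y <- vapply(seq_len(m), function(i)
    cpp_mdf_distance(A[, , i, drop = FALSE][, , 1], B[, , i, drop = FALSE][, , 1]),
    numeric(1))
  res <- cpp_loss_grad(batch, y, params, cfg_for_cpp(cfg),
                       along_fiber_graph(cfg$np, cfg$k) - 1L,
                       FALSE, matrix(0, 0, 0), matrix(0, 0, 0), 0)
  list(lp = res$lp, labels = y)
}

#' Pretrain the Siamese encoder on the fiber-distance pretext task
#'
#' Trains the network with Adam to regress the MDF distance of randomly
#' drawn fiber pairs (partner resampled per iteration, never the fiber
#' itself). The schedule follows the two-phase pattern of a long phase at
#' `lr1` and a short refinement phase at `lr2`; the desk-scale default is
#' 2000 + 200 iterations at batch 256. A paper-scale schedule (50k + 1k,
#' batch 1024) is available via the arguments.
#'
#' @param t a [tractogram] resampled to `cfg$np` points (>= 2 fibers).
#' @param cfg an [encoder_config].
#' @param iters1,lr1 first training phase (default 2000 at 1e-4).
#' @param iters2,lr2 refinement phase (default 200 at 1e-5).
#' @param batch_pairs fiber pairs per iteration (default 256).
#' @param seed integer RNG seed (weight init and pair sampling).
#' @param params optional warm-start parameters; default fresh He init.
#' @param log_every record the loss every this many iterations.
#' @return list with `params`, `cfg`, `log` (matrix: iteration, Lp, Lc,
#'   total) and `adam` state.
#' @export
pretrain <- function(t, cfg = encoder_config(), iters1 = 2000, lr1 = 1e-4,
                     iters2 = 200, lr2 = 1e-5, batch_pairs = 256, seed = 1L,
                     params = NULL, log_every = 100) {
  arr <- if (inherits(t, "tractogram")) fiber_array(t) else as.array(t)
  if (dim(arr)[3] < 2L) stop("need at least 2 fibers to pretrain")
  if (dim(arr)[1] != cfg$np)
    stop("fibers must be resampled to np = ", cfg$np, " points")
  if (is.null(params)) params <- init_encoder(cfg, seed = seed)
  nb <- along_fiber_graph(cfg$np, cfg$k) - 1L
  empty <- matrix(0, 0, 0)
  r1 <- cpp_train(arr, params, cfg_for_cpp(cfg), nb, iters1, lr1, batch_pairs,
                  seed = as.integer(seed), clustering = FALSE,
                  centroids = empty, Ptarget = empty, lambda = 0,
                  adam_state = NULL, t0 = 0L, log_every = log_every)
  r2 <- cpp_train(arr, r1$params, cfg_for_cpp(cfg), nb, iters2, lr2, batch_pairs,
                  seed = as.integer(seed) + 1L, clustering = FALSE,
                  centroids = empty, Ptarget = empty, lambda = 0,
                  adam_state = r1$adam, t0 = r1$t, log_every = log_every)
  log <- rbind(r1$log, r2$log)
  colnames(log) <- c("iteration", "lp", "lc", "total")
  list(params = r2$params, cfg = cfg, log = log, adam = r2$adam, t = r2$t)
}
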