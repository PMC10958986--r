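# Shared fixtures: small deterministic geometries, a tiny encoder
# configuration for fast network tests, and a small labelled scene.

# straight fiber along x with a given perpendicular offset, np points
straight_fiber <- function(np = 14, length_mm = 13, offset = c(0, 0, 0)) {
  fiber(cbind(seq(0, length_mm, length.out = np) + offset[1],
              offset[2], offset[3]))
}

# a tiny network configuration that trains in seconds
tiny_encoder <- function(np = 8, k = 4) {
  encoder_config(np = np, k = k, widths = c(6L, 6L, 8L, 8L, 8L), cg = 16,
                 fc = c(12L, 8L, 4L), slope = 0.2)
}

# small two-bundle tractogram (already resampled geometry), bundle ids attached
two_bundle_tractogram <- function(n_per = 30, np = 8, sep = 40, jitter = 0.5,
                                  seed = 42) {
  withr::local_seed(seed)
  fibers <- list()
  for (b in 1:2) {
    base <- c(0, (b - 1) * sep, 0)
    for (i in seq_len(n_per)) {
      pts <- cbind(seq(0, 60, length.out = np) + rnorm(1, 0, jitter),
                   base[2] + rnorm(1, 0, jitter),
                   base[3] + rnorm(1, 0, jitter))
      if (i %% 2 == 0) pts <- pts[np:1, ]
      fibers[[length(fibers) + 1L]] <- fiber(pts)
    }
  }
  structure(tractogram(fibers), bundle = rep(1:2, each = n_per))
}

# uniform single-label volume spanning [-s, s]^3
uniform_volume <- function(id = 7L, s = 50, voxel = 5) {
  n <- ceiling(2 * s / voxel)
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -s + voxel / 2
  label_volume(array(id, dim = c(n, n, n)), aff)
}

# two half-space labels split at x = 0 (label 1 for x < 0, 2 for x > 0)
two_slab_volume <- function(s = 50, voxel = 2) {
  n <- ceiling(2 * s / voxel)
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -s + voxel / 2
  xc <- aff[1, 4] + (seq_len(n) - 1) * voxel
  grid <- array(rep(ifelse(xc < 0, 1L, 2L), times = n * n), dim = c(n, n, n))
  label_volume(grid, aff)
}

# MDF recomputed independently in plain R (oracle for the C++ kernel)
mdf_oracle <- function(A, B) {
  np <- nrow(A)
  dd <- mean(sqrt(rowSums((A - B)^2)))
  df <- mean(sqrt(rowSums((A - B[np:1, , drop = FALSE])^2)))
  min(dd, df)
}

# independently coded brute-force DB evaluation, straight from the formula,
# with MDF recomputed in plain R
db_oracle <- function(clusters) {
  np <- nrow(clusters[[1]][[1]]$points)
  mdf <- function(a, b) mdf_oracle(a$points, b$points)
  alpha <- sapply(clusters, function(fl) {
    if (length(fl) < 2) return(0)
    tot <- 0; cnt <- 0
    for (i in seq_along(fl)) for (j in seq_along(fl)) if (i < j) {
      tot <- tot + mdf(fl[[i]], fl[[j]]); cnt <- cnt + 1
    }
    tot / cnt
  })
  cents <- lapply(clusters, function(fl) {
    if (length(fl) == 1) return(fl[[1]])
    means <- sapply(seq_along(fl), function(i)
      mean(sapply(seq_along(fl)[-i], function(j) mdf(fl[[i]], fl[[j]]))))
    fl[[which.min(means)]]
  })
  n <- length(clusters)
  total <- 0
  for (i in seq_len(n)) {
    best <- -Inf
    for (j in seq_len(n)[-i]) {
      d <- mdf(cents[[i]], cents[[j]])
      r <- if (d > 0) (alpha[i] + alpha[j]) / d else Inf
      best <- max(best, r)
    }
    total <- total + best
  }
  total / n
}

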