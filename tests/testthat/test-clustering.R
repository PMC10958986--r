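# Soft assignments, self-training target, losses, profiles, and the
# cluster-adaptive outlier rule.

test_that("k-means initialisation recovers separated groups and is seeded", {
  withr::local_seed(4)
  Z <- rbind(matrix(rnorm(30, 0, 0.1), 10, 3),
             matrix(rnorm(30, 5, 0.1), 10, 3),
             matrix(rnorm(30, -5, 0.1), 10, 3))
  km <- kmeans_init(Z, 3, seed = 1)
  expect_equal(length(unique(km$labels[1:10])), 1L)
  expect_equal(length(unique(km$labels[11:20])), 1L)
  expect_equal(length(unique(km$labels[21:30])), 1L)
  km2 <- kmeans_init(Z, 3, seed = 1)
  expect_identical(km$centroids, km2$centroids)
  # nc = 1 degenerates to the mean
  km1 <- kmeans_init(Z, 1, seed = 1)
  expect_equal(as.numeric(km1$centroids), colMeans(Z))
  expect_error(kmeans_init(Z[1:2, ], 3), "at least")
})

test_that("geometric soft assignment follows the Student's-t kernel", {
  mu <- rbind(c(0, 0), c(3, 0))
  # equidistant -> (0.5, 0.5)
  expect_equal(soft_assign_geometric(c(1.5, 0), mu), c(0.5, 0.5))
  # distances 1 and 2 -> q1 = (1/2) / (1/2 + 1/5)
  q <- soft_assign_geometric(c(1, 0), rbind(c(0, 0), c(3, 0)))
  expect_equal(q[1], 0.714286, tolerance = 1e-6)
  expect_equal(sum(q), 1)
  # z at a centroid with the others far away -> probability ~ 1
  far <- rbind(c(0, 0), c(100, 0), c(0, 100))
  expect_gt(soft_assign_geometric(c(0, 0), far)[1], 0.999)
})

test_that("anatomical assignment reproduces the hand case and reduces to Eq. 1", {
  mu <- rbind(c(1, 0), c(-1, 0))  # z at origin: both squared distances 1
  z <- c(0, 0)
  q <- fibercluster:::soft_assign_anatomical_scores(z, mu, da = c(0.8, 0.2),
                                                    dc = c(0, 0))
  expect_equal(q, c(0.8, 0.2), tolerance = 1e-9)
  # all-zero agreement: identical to the geometric assignment elementwise
  withr::local_seed(6)
  mu2 <- matrix(rnorm(10), 5, 2)
  z2 <- rnorm(2)
  q_an <- fibercluster:::soft_assign_anatomical_scores(z2, mu2, rep(0, 5), rep(0, 5))
  expect_equal(q_an, soft_assign_geometric(z2, mu2), tolerance = 1e-12)
  # perfect Dice is floored: that cluster gets the maximal weight among
  # equal-distance clusters
  q_f <- fibercluster:::soft_assign_anatomical_scores(z, mu, da = c(1, 0),
                                                      dc = c(0, 0))
  expect_gt(q_f[1], q_f[2])
  # monotone: raising one cluster's agreement never lowers its probability
  for (d in seq(0, 1, by = 0.25)) {
    qa <- fibercluster:::soft_assign_anatomical_scores(z, mu, da = c(d, 0.3),
                                                       dc = c(0, 0))
    if (d > 0) expect_gte(qa[1], prev)
    prev <- qa[1]
  }
})

test_that("assignment vectors are normalised probability vectors", {
  withr::local_seed(12)
  mu <- matrix(rnorm(40, sd = 3), 8, 5)
  for (i in 1:50) {
    z <- rnorm(5, sd = 3)
    q1 <- soft_assign_geometric(z, mu)
    q2 <- fibercluster:::soft_assign_anatomical_scores(z, mu, runif(8), runif(8))
    for (q in list(q1, q2)) {
      expect_true(all(q >= 0))
      expect_equal(sum(q), 1, tolerance = 1e-6)
    }
  }
})

test_that("target distribution sharpens with frequency normalisation", {
  # symmetric row is a fixed point
  expect_equal(target_distribution(matrix(c(0.5, 0.5), 1)),
               matrix(c(0.5, 0.5), 1))
  # a single-row batch is a fixed point (frequency cancels)
  expect_equal(target_distribution(matrix(c(0.8, 0.2), 1)),
               matrix(c(0.8, 0.2), 1), tolerance = 1e-12)
  # two-row hand computation
  Q <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  P <- target_distribution(Q)
  expect_equal(P[1, ], c(0.8727, 0.1273), tolerance = 1e-4)
  # rows stay normalised on random input; zero columns are dropped
  withr::local_seed(13)
  Qr <- matrix(runif(200), 20, 10)
  Qr <- Qr / rowSums(Qr)
  Qr[, 4] <- 0
  Qr <- Qr / rowSums(Qr)
  Pr <- target_distribution(Qr)
  expect_equal(rowSums(Pr), rep(1, 20), tolerance = 1e-12)
  expect_equal(Pr[, 4], rep(0, 20))
})

test_that("KL clustering loss matches hand values and Gibbs' inequality", {
  Q <- matrix(c(0.5, 0.5), 1)
  expect_equal(clustering_loss(Q, Q), 0)
  expect_equal(clustering_loss(Q, matrix(c(1, 0), 1)), log(2), tolerance = 1e-9)
  withr::local_seed(14)
  for (i in 1:20) {
    Qr <- matrix(runif(12), 3); Qr <- Qr / rowSums(Qr)
    Pr <- matrix(runif(12), 3); Pr <- Pr / rowSums(Pr)
    expect_gte(clustering_loss(Qr, Pr), 0)
  }
})

test_that("the total loss combines the two terms linearly", {
  expect_equal(total_loss(3, 7, 0), 3)
  expect_equal(total_loss(1, 2, 0.1), 1.2)
  expect_gt(total_loss(2, 2, 0.1), total_loss(1, 2, 0.1))
  expect_gt(total_loss(1, 3, 0.1), total_loss(1, 2, 0.1))
})

test_that("profiles rebuild from hard labels and empty correctly", {
  mk <- function(lab, pair) fiber(diag(3), point_labels = rep(lab, 3),
                                  endpoint_parcels = pair)
  fibers <- list(mk(1L, c(1L, 2L)), mk(1L, c(1L, 2L)), mk(2L, c(3L, 3L)))
  prof <- update_profiles(c(1L, 1L, 2L), fibers, nc = 3)
  expect_equal(prof$anatomical_profiles[[1]]$regions, 1L)
  expect_equal(prof$anatomical_profiles[[2]]$regions, 2L)
  expect_length(prof$anatomical_profiles[[3]]$regions, 0L)
  expect_equal(prof$surface_profiles[[2]]$fractions, c("3" = 1.0))
  # direct computation on the same partition agrees
  expect_equal(prof$anatomical_profiles[[1]],
               tract_anatomical_profile(fibers[1:2]))
  # moving all of cluster 1's members empties it
  prof2 <- update_profiles(c(2L, 2L, 2L), fibers, nc = 3)
  expect_length(prof2$anatomical_profiles[[1]]$regions, 0L)
  # idempotent under unchanged assignments
  expect_equal(update_profiles(c(1L, 1L, 2L), fibers, nc = 3), prof)
})

test_that("the cluster-adaptive outlier rule matches the hand case", {
  a <- data.frame(fiber = 1:5, label = 1L,
                  qm = c(0.9, 0.8, 0.85, 0.95, 0.1), outlier = FALSE)
  expect_equal(mean(a$qm), 0.72)
  expect_equal(sd(a$qm), 0.35107, tolerance = 1e-4)
  flagged <- remove_outliers(a, outlier_config(1))
  expect_equal(which(flagged$outlier), 5L)
  # all equal -> sd 0, threshold = mean, none strictly below
  b <- data.frame(fiber = 1:4, label = 1L, qm = rep(0.7, 4), outlier = FALSE)
  expect_false(any(remove_outliers(b, outlier_config(1))$outlier))
  # n = 0 flags everything strictly below the cluster mean
  c0 <- remove_outliers(a, outlier_config(0))
  expect_equal(which(c0$outlier), which(a$qm < mean(a$qm)))
  # singleton clusters are never flagged
  s <- data.frame(fiber = 1, label = 9L, qm = 0.01, outlier = FALSE)
  expect_false(remove_outliers(s, outlier_config(1))$outlier)
})

test_that("the flagged set shrinks monotonically as n grows", {
  withr::local_seed(15)
  a <- data.frame(fiber = 1:200, label = sample(1:4, 200, replace = TRUE),
                  qm = runif(200), outlier = FALSE)
  prev <- NULL
  for (n in c(0, 0.5, 1, 2)) {
    cur <- which(remove_outliers(a, outlier_config(n))$outlier)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("match_outlier_fraction reaches the requested removal budget", {
  withr::local_seed(16)
  a <- data.frame(fiber = 1:300, label = sample(1:3, 300, replace = TRUE),
                  qm = rbeta(300, 5, 1), outlier = FALSE)
  n <- match_outlier_fraction(a, 0.10)
  frac <- mean(remove_outliers(a, outlier_config(n))$outlier)
  expect_gte(frac, 0.10)
  expect_lt(frac, 0.25)
})
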