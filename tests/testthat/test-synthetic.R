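# Ground-truthed synthetic tractography scenes.

small_spec <- function(seed = 7, ...) {
  args <- list(n_bundles = 3, fibers_per_bundle = 20, n_points = 20,
               seed = seed)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

test_that("scene generation is deterministic given the seed", {
  s1 <- generate_scene(small_spec())
  s2 <- generate_scene(small_spec())
  expect_equal(s1$tractogram, s2$tractogram)
  expect_equal(s1$truth, s2$truth)
  expect_equal(s1$label_volume$grid, s2$label_volume$grid)
  s3 <- generate_scene(small_spec(seed = 8))
  expect_false(isTRUE(all.equal(s1$tractogram, s3$tractogram)))
})

test_that("zero jitter collapses bundles to their centerline up to flips", {
  sc <- generate_scene(small_spec(jitter_mm = 0, outlier_fraction = 0))
  t_rs <- resample_tractogram(sc$tractogram, 14)
  for (b in 1:3) {
    idx <- which(sc$truth$bundle == b)
    D <- pairwise_mdf(tractogram(t_rs$fibers[idx]))
    expect_lt(max(D), 1e-8)
  }
})

test_that("bundles are separated beyond the within-bundle spread", {
  sc <- generate_scene(small_spec())
  t_rs <- resample_tractogram(sc$tractogram, 14)
  inl <- which(!sc$truth$outlier)
  D <- pairwise_mdf(tractogram(t_rs$fibers[inl]))
  b <- sc$truth$bundle[inl]
  same <- outer(b, b, "==") & upper.tri(D)
  diff <- outer(b, b, "!=") & upper.tri(D)
  expect_gt(min(D[diff]), max(D[same]))
})

test_that("stored point reversal changes order but never any MDF", {
  sc_flip <- generate_scene(small_spec(flip_prob = 1))
  sc_none <- generate_scene(small_spec(flip_prob = 0))
  t1 <- resample_tractogram(sc_flip$tractogram, 10)
  t0 <- resample_tractogram(sc_none$tractogram, 10)
  for (i in seq(1, 60, by = 7)) {
    expect_equal(t1$fibers[[i]]$points, t0$fibers[[i]]$points[10:1, ],
                 tolerance = 1e-9)
    expect_equal(mdf_distance(t1$fibers[[i]], t1$fibers[[1]]),
                 mdf_distance(t0$fibers[[i]], t0$fibers[[1]]), tolerance = 1e-9)
  }
})

test_that("within-bundle spread scales linearly with the jitter level", {
  spread <- sapply(c(0.5, 1), function(j) {
    sc <- generate_scene(small_spec(jitter_mm = j, outlier_fraction = 0))
    t_rs <- resample_tractogram(sc$tractogram, 14)
    idx <- which(sc$truth$bundle == 1)
    D <- pairwise_mdf(tractogram(t_rs$fibers[idx]))
    mean(D[upper.tri(D)])
  })
  expect_equal(spread[2] / spread[1], 2, tolerance = 0.25)
})

test_that("each bundle's slab traversal is recoverable as its profile", {
  sc <- generate_scene(small_spec())
  t <- label_tractogram(sc$tractogram, sc$label_volume, sc$parcel_volume)
  for (b in 1:3) {
    idx <- which(sc$truth$bundle == b & !sc$truth$outlier)
    prof <- tract_anatomical_profile(t$fibers[idx], 0.4)
    # true region set: slabs crossed by the centerline
    ctr <- fibercluster:::spline_curve(sc$centerlines[[b]], 50)
    truth <- sort(unique(fibercluster:::lookup_labels(ctr, sc$label_volume)))
    truth <- truth[truth > 0]
    expect_equal(prof$regions, truth)
  }
  # endpoint parcels: two unique parcels per bundle, so the surface profile
  # of a bundle is 50/50 and its TSPC optimum is 0.5
  idx1 <- which(sc$truth$bundle == 1 & !sc$truth$outlier)
  sp <- tract_surface_profile(t$fibers[idx1])
  expect_length(sp$fractions, 2L)
  expect_equal(unname(sp$fractions), c(0.5, 0.5), tolerance = 0.05)
})

test_that("planted outliers are displaced far beyond the bundle spread", {
  sc <- generate_scene(small_spec(seed = 9))
  t_rs <- resample_tractogram(sc$tractogram, 14)
  ctr <- lapply(sc$centerlines, function(cc) fibercluster:::spline_curve(cc, 14))
  d <- sapply(seq_len(nrow(sc$truth)), function(i)
    fibercluster:::cpp_mdf_distance(t_rs$fibers[[i]]$points,
                                    ctr[[sc$truth$bundle[i]]]))
  expect_gt(min(d[sc$truth$outlier]), 5 * max(d[!sc$truth$outlier]) / 2)
  expect_gt(median(d[sc$truth$outlier]), 5 * median(d[!sc$truth$outlier]))
})

test_that("scenes write to TRK + NIfTI + JSON and read back", {
  sc <- generate_scene(small_spec())
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  t <- read_tractogram(paths["tractogram"])
  expect_length(t$fibers, length(sc$tractogram$fibers))
  expect_equal(t$fibers[[5]]$points, sc$tractogram$fibers[[5]]$points,
               tolerance = 1e-4)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$bundle, sc$truth$bundle)
  vol <- read_label_volume(paths["labels"])
  expect_equal(vol$grid, sc$label_volume$grid, ignore_attr = TRUE)
})

test_that("the adjusted Rand index behaves as an agreement score", {
  truth <- rep(1:4, each = 25)
  expect_equal(adjusted_rand_index(truth, truth), 1)
  # permuting label ids changes nothing
  perm <- c(3L, 1L, 4L, 2L)[truth]
  expect_equal(adjusted_rand_index(truth, perm), 1)
  # independent labels give ARI near 0
  withr::local_seed(20)
  rnd <- sample(1:4, 100, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(truth, rnd)), 0.1)
  # cross-check a small case against the closed-form contingency computation
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(1, 1, 2, 2, 2, 3)
  # pairs: sum_ij C(n_ij,2)=1+1=2... computed by hand: n_ij = {2,1;1,2;0,0,1}
  # sum_ij = C(2,2)+C(1,2)+C(1,2)+C(2,2)+C(1,2) = 1+0+0+1+0 = 2
  # a sums: C(3,2)+C(2,2)+C(1,2) = 3+1+0 = 4 ; b sums: 3+1 = 4; C(6,2)=15
  # expected = 16/15; max = 4; ari = (2-16/15)/(4-16/15)
  expect_equal(adjusted_rand_index(a, b), (2 - 16 / 15) / (4 - 16 / 15),
               tolerance = 1e-12)
})

test_that("truth_report scores assignments against the sidecar", {
  sc <- generate_scene(small_spec())
  a <- data.frame(fiber = seq_len(nrow(sc$truth)), label = sc$truth$bundle,
                  qm = 1, outlier = sc$truth$outlier)
  tr <- truth_report(sc, a)
  expect_equal(tr$ari, 1)
  expect_equal(tr$outlier_recall, 1)
  expect_equal(tr$outlier_precision, 1)
})

test_that("contradictory specs are rejected", {
  expect_error(synthetic_spec(n_bundles = 0, seed = 1))
  expect_error(synthetic_spec(seed = 1, outlier_fraction = 1.2))
  expect_error(synthetic_spec())
})
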