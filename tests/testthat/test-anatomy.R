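# Anatomical labelling, profiles, and the two agreement scores.

test_that("points inside a uniform volume all get its label", {
  vol <- uniform_volume(id = 7L)
  f <- label_fiber_points(straight_fiber(np = 10, length_mm = 30,
                                         offset = c(-15, 0, 0)), vol)
  expect_equal(f$point_labels, rep(7L, 10))
})

test_that("the label changes exactly at a half-space boundary", {
  vol <- two_slab_volume(s = 50, voxel = 2)
  # points at x = -9.5, ..., 9.5: negative x -> 1, positive -> 2
  pts <- cbind(seq(-9.5, 9.5, by = 1), 0, 0)
  f <- label_fiber_points(fiber(pts), vol)
  expect_equal(f$point_labels, rep(c(1L, 2L), each = 10))
})

test_that("points outside the grid get label 0", {
  vol <- uniform_volume(id = 3L, s = 10)
  f <- label_fiber_points(fiber(rbind(c(0, 0, 0), c(500, 0, 0))), vol)
  expect_equal(f$point_labels, c(3L, 0L))
})

test_that("endpoints attach to the nearest nonzero parcel voxel", {
  grid <- array(0L, dim = c(9, 9, 9))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -8
  grid[3, 5, 5] <- 4L   # world (-4, 0, 0)
  grid[7, 5, 5] <- 9L   # world (4, 0, 0)
  parcels <- label_volume(grid, aff)
  f <- label_fiber_endpoints(fiber(rbind(c(-3, 0, 0), c(3.5, 0, 0))), parcels)
  expect_equal(f$endpoint_parcels, c(4L, 9L))
  # an endpoint well outside any parcel is still assigned to the nearest one
  g <- label_fiber_endpoints(fiber(rbind(c(-30, 0, 0), c(30, 0, 0))), parcels)
  expect_equal(g$endpoint_parcels, c(4L, 9L))
  # equidistant tie resolves to the lowest parcel id
  h <- label_fiber_endpoints(fiber(rbind(c(0, 0, 0), c(0, 1, 0))), parcels)
  expect_equal(h$endpoint_parcels, c(4L, 4L))
  expect_error(label_fiber_endpoints(f, label_volume(array(0L, c(3, 3, 3)))),
               "nonzero")
})

test_that("tract anatomical profile applies the strict 40% rule", {
  # 10 fibers: region 1 everywhere, region 2 in 5 (50%), region 3 in 4 (40%)
  fibers <- lapply(1:10, function(i) {
    labs <- c(1L, if (i <= 5) 2L else 1L, if (i <= 4) 3L else 1L)
    fiber(cbind(0:2, 0, 0), point_labels = labs)
  })
  prof <- tract_anatomical_profile(fibers)
  expect_equal(prof$regions, c(1L, 2L))
  # all fibers share one region
  shared <- lapply(1:4, function(i) fiber(diag(3), point_labels = rep(5L, 3)))
  expect_equal(tract_anatomical_profile(shared)$regions, 5L)
  # every fiber unique among 10 -> empty profile
  uniq <- lapply(1:10, function(i) fiber(diag(3), point_labels = rep(i, 3)))
  expect_length(tract_anatomical_profile(uniq)$regions, 0L)
  expect_error(tract_anatomical_profile(list()), "empty")
})

test_that("raising the profile threshold never adds regions", {
  withr::local_seed(3)
  fibers <- lapply(1:20, function(i)
    fiber(diag(3), point_labels = sample(1:6, 3, replace = TRUE)))
  prev <- NULL
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- tract_anatomical_profile(fibers, thr)$regions
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("tract surface profile computes endpoint fractions", {
  mk <- function(pair) fiber(diag(3), endpoint_parcels = pair)
  all7 <- tract_surface_profile(lapply(1:4, function(i) mk(c(7L, 7L))))
  expect_equal(all7$fractions, c("7" = 1.0))
  half <- tract_surface_profile(lapply(1:4, function(i) mk(c(1L, 2L))))
  expect_equal(half$fractions, c("1" = 0.5, "2" = 0.5))
  # 5 fibers, 10 endpoints: 7 in parcel 1, 2 in parcel 2, 1 in parcel 3
  fl <- list(mk(c(1L, 1L)), mk(c(1L, 1L)), mk(c(1L, 1L)), mk(c(1L, 2L)),
             mk(c(2L, 3L)))
  prof <- tract_surface_profile(fl)
  expect_equal(prof$fractions, c("1" = 0.7, "2" = 0.2, "3" = 0.1))
  expect_equal(sum(prof$fractions), 1.0)
  expect_error(tract_surface_profile(list()), "empty")
})

test_that("Dice agreement matches hand computations and stays in [0,1]", {
  prof <- structure(list(regions = c(2L, 3L, 4L), threshold = 0.4),
                    class = "tract_anatomical_profile")
  f123 <- fiber(diag(3), point_labels = c(1L, 2L, 3L))
  expect_equal(dice_anatomical(f123, prof), 2 * 2 / 6)
  same <- fiber(diag(3), point_labels = c(2L, 3L, 4L))
  expect_equal(dice_anatomical(same, prof), 1.0)
  disj <- fiber(diag(3), point_labels = c(8L, 9L, 9L))
  expect_equal(dice_anatomical(disj, prof), 0.0)
  # both sets empty -> 0 by convention (background-only labels)
  empty_prof <- structure(list(regions = integer(0), threshold = 0.4),
                          class = "tract_anatomical_profile")
  bg <- fiber(diag(3), point_labels = c(0L, 0L, 0L))
  expect_equal(dice_anatomical(bg, empty_prof), 0)
})

test_that("endpoint agreement sums profile fractions over the fiber's parcels", {
  prof <- structure(list(fractions = c("1" = 0.5, "2" = 0.5)),
                    class = "tract_surface_profile")
  f <- fiber(diag(3), endpoint_parcels = c(1L, 2L))
  expect_equal(endpoint_agreement(f, prof), 1.0)
  prof2 <- structure(list(fractions = c("9" = 0.7, "3" = 0.3)),
                     class = "tract_surface_profile")
  f99 <- fiber(diag(3), endpoint_parcels = c(9L, 9L))
  expect_equal(endpoint_agreement(f99, prof2), 0.7)
  fx <- fiber(diag(3), endpoint_parcels = c(5L, 6L))
  expect_equal(endpoint_agreement(fx, prof2), 0.0)
})

test_that("agreement scores are bounded for random inputs", {
  withr::local_seed(11)
  for (i in 1:20) {
    f <- fiber(diag(3), point_labels = sample(0:5, 3, replace = TRUE),
               endpoint_parcels = sample(0:5, 2, replace = TRUE))
    fl <- lapply(1:5, function(j)
      fiber(diag(3), point_labels = sample(0:5, 3, replace = TRUE),
            endpoint_parcels = sample(1:5, 2, replace = TRUE)))
    pa <- tract_anatomical_profile(fl, 0.4)
    ps <- tract_surface_profile(fl)
    expect_gte(dice_anatomical(f, pa), 0); expect_lte(dice_anatomical(f, pa), 1)
    expect_gte(endpoint_agreement(f, ps), 0)
    expect_lte(endpoint_agreement(f, ps), 1)
  }
})
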