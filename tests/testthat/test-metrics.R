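# Parcellation quality metrics: centroid fiber, DB, WMPG, TAPC, TSPC.

test_that("centroid fiber minimises the mean MDF to the other members", {
  one <- list(straight_fiber())
  expect_identical(centroid_fiber(one), one[[1]])
  # collinear parallel fibers at offsets 0, 1, 5: the offset-1 fiber wins
  fl <- list(straight_fiber(offset = c(0, 0, 0)),
             straight_fiber(offset = c(0, 1, 0)),
             straight_fiber(offset = c(0, 5, 0)))
  expect_equal(centroid_fiber(fl)$points[1, 2], 1)
  # exact duplicates tie -> lowest index
  dup <- list(straight_fiber(), straight_fiber(), straight_fiber(offset = c(0, 2, 0)))
  expect_identical(centroid_fiber(dup), dup[[1]])
  expect_error(centroid_fiber(list()), "empty")
})

test_that("DB index matches hand evaluation and the brute-force oracle", {
  # two singleton clusters have zero scatter -> DB 0
  s1 <- list(list(straight_fiber()), list(straight_fiber(offset = c(0, 9, 0))))
  expect_equal(db_index(s1), 0)
  # constructed case: alpha = (1, 2), centroid separation 10 -> 0.3
  A <- lapply(c(0, 0.75, 1.5), function(o) straight_fiber(offset = c(0, o, 0)))
  B <- lapply(c(9.25, 10.75, 12.25), function(o) straight_fiber(offset = c(0, o, 0)))
  expect_equal(db_index(list(A, B)), 0.3, tolerance = 1e-12)
  # random partitions agree with the independent brute force
  withr::local_seed(17)
  for (rep in 1:8) {
    nclust <- sample(2:4, 1)
    clusters <- lapply(seq_len(nclust), function(j) {
      center <- rnorm(3, sd = 30)
      lapply(seq_len(sample(2:6, 1)), function(i)
        fiber(matrix(rnorm(8 * 3, sd = 2), 8, 3) +
              matrix(center, 8, 3, byrow = TRUE) + cbind(seq(0, 50, length.out = 8), 0, 0)))
    })
    expect_equal(db_index(clusters), db_oracle(clusters), tolerance = 1e-9)
  }
})

test_that("merging two distant tight clusters does not decrease DB", {
  A <- lapply(c(0, 0.5, 1), function(o) straight_fiber(offset = c(0, o, 0)))
  B <- lapply(c(50, 50.5, 51), function(o) straight_fiber(offset = c(0, o, 0)))
  C <- lapply(c(100, 100.5, 101), function(o) straight_fiber(offset = c(0, o, 0)))
  separate <- db_index(list(A, B, C))
  merged <- db_index(list(c(A, B), C))
  expect_gte(merged, separate)
})

test_that("WMPG applies the strict over-20-fibers rule", {
  labels <- rep(1:3, times = c(25, 20, 21))
  expect_equal(wmpg(labels, nc_total = 3), 2 / 3)  # exactly 20 not detected
  expect_equal(wmpg(labels, nc_total = 4), 2 / 4)
  expect_equal(wmpg(integer(0), nc_total = 5), 0)
  expect_equal(wmpg(rep(1, 100), nc_total = 1), 1)
})

test_that("TAPC matches the hand-worked cluster", {
  # two fibers with region sets {1,2} and {1}: profile (40%) = {1,2};
  # Dice = 1.0 and 0.6667 -> TAPC 0.8333
  f1 <- fiber(diag(3), point_labels = c(1L, 2L, 1L))
  f2 <- fiber(diag(3), point_labels = c(1L, 1L, 1L))
  res <- tapc(list(list(f1, f2)))
  expect_equal(res$score, 5 / 6, tolerance = 1e-12)
  # perfect coherence
  res1 <- tapc(list(list(f1, f1), list(f2, f2)))
  expect_equal(res1$score, 1.0)
  # fibers with only background labels give a zero cluster score
  bg <- fiber(diag(3), point_labels = c(0L, 0L, 0L))
  expect_equal(tapc(list(list(bg, bg)))$score, 0)
})

test_that("TSPC averages the surface profile over intersected parcels", {
  mk <- function(pair) fiber(diag(3), endpoint_parcels = pair)
  # all endpoints in two parcels 50/50
  expect_equal(tspc(list(lapply(1:4, function(i) mk(c(1L, 2L)))))$score, 0.5)
  # spread evenly over 10 parcels
  even <- lapply(1:5, function(i) mk(c(2L * i - 1L, 2L * i)))
  expect_equal(tspc(list(even))$score, 0.1)
  # hand case: fractions (0.7, 0.2, 0.1) -> mean 1/3
  fl <- list(mk(c(1L, 1L)), mk(c(1L, 1L)), mk(c(1L, 1L)), mk(c(1L, 2L)),
             mk(c(2L, 3L)))
  expect_equal(tspc(list(fl))$score, 1 / 3, tolerance = 1e-12)
})

test_that("metrics are invariant to fiber order and point flips", {
  withr::local_seed(18)
  mkc <- function(center) lapply(1:4, function(i)
    fiber(cbind(seq(0, 40, length.out = 8), center + rnorm(1), rnorm(1)),
          point_labels = rep(sample(1:3, 1), 8),
          endpoint_parcels = sample(1:4, 2, replace = TRUE)))
  cl <- list(mkc(0), mkc(30))
  base <- c(db_index(cl), tapc(cl)$score, tspc(cl)$score)
  perm <- lapply(cl, function(fl) fl[c(3, 1, 4, 2)])
  flip <- lapply(cl, function(fl) lapply(fl, flip_fiber))
  expect_equal(c(db_index(perm), tapc(perm)$score, tspc(perm)$score), base)
  expect_equal(c(db_index(flip), tapc(flip)$score, tspc(flip)$score), base)
})

test_that("evaluate_parcellation assembles a coherent report", {
  withr::local_seed(19)
  t <- two_bundle_tractogram(n_per = 25, np = 8)
  vol <- two_slab_volume()
  # place parcels near line ends
  grid <- array(0L, dim = c(9, 9, 9))
  aff <- diag(c(12, 12, 12, 1)); aff[1:3, 4] <- -48
  grid[1, 5, 5] <- 1L; grid[9, 5, 5] <- 2L
  parcels <- label_volume(grid, aff)
  t <- label_tractogram(t, vol, parcels)
  a <- data.frame(fiber = seq_along(t$fibers),
                  label = attr(t, "bundle"), qm = 1, outlier = FALSE)
  a$outlier[1] <- TRUE
  rep <- evaluate_parcellation(t, a, nc_total = 2)
  expect_s3_class(rep, "parcellation_report")
  expect_gte(rep$db, 0)
  expect_equal(rep$wmpg, 1)
  expect_true(rep$tapc$score >= 0 && rep$tapc$score <= 1)
  expect_true(rep$tspc$score >= 0 && rep$tspc$score <= 1)
  expect_equal(rep$n_fibers, length(t$fibers) - 1L)
  # idempotent
  rep2 <- evaluate_parcellation(t, a, nc_total = 2)
  expect_equal(rep2$db, rep$db)
  # writing the report produces valid JSON + CSV
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, jp, cp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$wmpg, 1)
  expect_equal(nrow(utils::read.csv(cp)), 2L)
})
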