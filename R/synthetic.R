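#' Specification of a synthetic tractography scene
#'
#' Describes bundles of spatially coherent streamlines at brain scale:
#' each bundle is a cubic centerline through randomized control points
#' inside a cube, fibers are jittered copies of the centerline, a stated
#' fraction of fibers is stored with reversed point order (tractography
#' orientation is arbitrary), and a fraction of fibers is turned into
#' outliers by kinking their interior control points. A slab label volume
#' and a per-bundle endpoint parcel volume provide co-registered anatomy
#' with known ground truth.
#'
#' @param n_bundles number of bundles (default 10).
#' @param fibers_per_bundle fibers per bundle (default 200).
#' @param n_points stored points per fiber (default 28; downsampling to the
#'   network resolution happens later in the pipeline).
#' @param jitter_mm isotropic normal jitter of the control points within a
#'   bundle (default 1 mm).
#' @param flip_prob probability that a fiber is stored end-reversed
#'   (default 0.5).
#' @param outlier_fraction fraction of fibers planted as outliers
#'   (default 0.05).
#' @param outlier_shift_mm displacement of the interior control points of a
#'   planted outlier (default 20 mm, i.e. far outside the bundle spread).
#' @param extent_mm side of the cube containing the scene (default 150,
#'   brain scale; centerline lengths of 80-120 mm clear the 40 mm filter by
#'   construction).
#' @param min_separation_mm minimum centerline-to-centerline MDF distance
#'   between bundles (default 20 mm; with the default 1 mm jitter this is a
#'   well-separated preset).
#' @param n_slabs number of anatomical slab regions along z (default 5).
#' @param voxel_mm voxel size of the label volumes (default 2 mm).
#' @param parcel_radius_mm radius of the endpoint parcel zones (default 6).
#' @param seed mandatory integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bundles = 10, fibers_per_bundle = 200,
                           n_points = 28, jitter_mm = 1, flip_prob = 0.5,
                           outlier_fraction = 0.05, outlier_shift_mm = 20,
                           extent_mm = 150, min_separation_mm = 20,
                           n_slabs = 5, voxel_mm = 2, parcel_radius_mm = 6,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory for scene generation")
  stopifnot(n_bundles >= 1, fibers_per_bundle >= 1, n_points >= 4,
            jitter_mm >= 0, flip_prob >= 0, flip_prob <= 1,
            outlier_fraction >= 0, outlier_fraction < 1,
            n_slabs >= 1, voxel_mm > 0)
  structure(list(n_bundles = as.integer(n_bundles),
                 fibers_per_bundle = as.integer(fibers_per_bundle),
                 n_points = as.integer(n_points), jitter_mm = jitter_mm,
                 flip_prob = flip_prob, outlier_fraction = outlier_fraction,
                 outlier_shift_mm = outlier_shift_mm, extent_mm = extent_mm,
                 min_separation_mm = min_separation_mm,
                 n_slabs = as.integer(n_slabs), voxel_mm = voxel_mm,
                 parcel_radius_mm = parcel_radius_mm,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# natural cubic curve through 4 control points, sampled at n points by
# chord-length parameterisation
spline_curve <- function(ctrl, n) {
  u <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  u <- u / u[length(u)]
  uu <- seq(0, 1, length.out = n)
  cbind(stats::spline(u, ctrl[, 1], xout = uu, method = "natural")$y,
        stats::spline(u, ctrl[, 2], xout = uu, method = "natural")$y,
        stats::spline(u, ctrl[, 3], xout = uu, method = "natural")$y)
}

sample_centerline <- function(half, rng_len = c(80, 120)) {
  repeat {
    start <- stats::runif(3, -half * 0.85, half * 0.85)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    len <- stats::runif(1, rng_len[1], rng_len[2])
    end <- start + len * dir
    if (all(abs(end) < half * 0.85)) break
  }
  chord <- end - start
  # perpendicular bow for curvature
  perp <- stats::rnorm(3)
  perp <- perp - sum(perp * chord) * chord / sum(chord^2)
  perp <- perp / sqrt(sum(perp^2)) * stats::runif(1, 0, len / 8)
  rbind(start,
        start + chord / 3 + perp,
        start + 2 * chord / 3 + perp,
        end)
}

#' Generate a ground-truthed synthetic scene
#'
#' Deterministic given the spec's seed. Bundle centerlines are rejected
#' until all pairwise centerline MDF distances exceed
#' `min_separation_mm` and all endpoint zones are disjoint; fibers are
#' spline curves through jittered control points; planted outliers have
#' their interior control points kicked by `outlier_shift_mm` (kinked
#' fibers of distinctly different position and shape). The label volume
#' partitions the cube into z-slabs; the parcel volume labels a sphere
#' around each bundle endpoint with a unique parcel id (2 per bundle).
#'
#' @param spec a [synthetic_spec].
#' @return object of class `synthetic_scene`: `tractogram`,
#'   `truth` (data frame: bundle, outlier), `label_volume`,
#'   `parcel_volume`, `spec`, and the bundle `centerlines`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  half <- spec$extent_mm / 2
  np_chk <- 14L

  # --- bundle centerlines with separation + endpoint-zone rejection
  ctrls <- list()
  check <- list()
  guard <- 0L
  while (length(ctrls) < spec$n_bundles) {
    guard <- guard + 1L
    if (guard > 5000L) stop("could not place separated bundles; relax the spec")
    cand <- sample_centerline(half)
    curve <- spline_curve(cand, np_chk)
    ok <- TRUE
    for (i in seq_along(ctrls)) {
      if (cpp_mdf_distance(curve, check[[i]]) < spec$min_separation_mm) { ok <- FALSE; break }
      ends_a <- cand[c(1, 4), , drop = FALSE]
      ends_b <- ctrls[[i]][c(1, 4), , drop = FALSE]
      dmin <- min(sqrt(outer(rowSums(ends_a^2), rep(1, 2)) +
                       outer(rep(1, 2), rowSums(ends_b^2)) -
                       2 * ends_a %*% t(ends_b)))
      if (dmin < 2 * spec$parcel_radius_mm + 2) { ok <- FALSE; break }
    }
    if (ok) {
      ctrls[[length(ctrls) + 1L]] <- cand
      check[[length(check) + 1L]] <- curve
    }
  }

  # --- fibers
  n_total <- spec$n_bundles * spec$fibers_per_bundle
  n_out <- floor(spec$outlier_fraction * n_total)
  fibers <- vector("list", n_total)
  bundle_id <- rep(seq_len(spec$n_bundles), each = spec$fibers_per_bundle)
  outlier_flag <- logical(n_total)
  outlier_idx <- if (n_out > 0) sort(sample.int(n_total, n_out)) else integer(0)
  outlier_flag[outlier_idx] <- TRUE
  for (i in seq_len(n_total)) {
    ctrl <- ctrls[[bundle_id[i]]]
    ctrl <- ctrl + matrix(stats::rnorm(12, sd = spec$jitter_mm), 4, 3)
    if (outlier_flag[i]) {
      for (row in 2:3) {
        kick <- stats::rnorm(3)
        kick <- kick / sqrt(sum(kick^2)) * spec$outlier_shift_mm
        ctrl[row, ] <- ctrl[row, ] + kick
      }
    }
    pts <- spline_curve(ctrl, spec$n_points)
    if (stats::runif(1) < spec$flip_prob) pts <- pts[spec$n_points:1, ]
    fibers[[i]] <- fiber(pts)
  }

  # --- slab label volume
  ext <- half + 10
  nvox <- ceiling(2 * ext / spec$voxel_mm)
  affine <- diag(c(spec$voxel_mm, spec$voxel_mm, spec$voxel_mm, 1))
  affine[1:3, 4] <- -ext + spec$voxel_mm / 2  # voxel centre of index 0
  zc <- affine[3, 4] + (seq_len(nvox) - 1) * spec$voxel_mm
  slab <- pmin(pmax(ceiling((zc + ext) / (2 * ext / spec$n_slabs)), 1L),
               spec$n_slabs)
  grid <- array(rep(as.integer(slab), each = nvox * nvox),
                dim = c(nvox, nvox, nvox))
  labels <- label_volume(grid, affine)

  # --- endpoint parcel volume: one unique parcel per bundle end
  pgrid <- array(0L, dim = c(nvox, nvox, nvox))
  ax <- affine[1, 4] + (seq_len(nvox) - 1) * spec$voxel_mm
  r_vox <- ceiling(spec$parcel_radius_mm / spec$voxel_mm)
  for (b in seq_len(spec$n_bundles)) {
    ends <- spline_curve(ctrls[[b]], spec$n_points)[c(1, spec$n_points), ]
    for (e in 1:2) {
      id <- 2L * (b - 1L) + e
      ctr <- ends[e, ]
      ivox <- round((ctr - affine[1:3, 4]) / spec$voxel_mm) + 1
      rng <- function(c0) max(1, c0 - r_vox):min(nvox, c0 + r_vox)
      for (ix in rng(ivox[1])) for (iy in rng(ivox[2])) for (iz in rng(ivox[3])) {
        d2 <- (ax[ix] - ctr[1])^2 + (ax[iy] - ctr[2])^2 + (ax[iz] - ctr[3])^2
        if (d2 <= spec$parcel_radius_mm^2 && pgrid[ix, iy, iz] == 0L)
          pgrid[ix, iy, iz] <- id
      }
    }
  }
  parcels <- label_volume(pgrid, affine)

  structure(list(
    tractogram = tractogram(fibers, source = sprintf("synthetic seed=%d", spec$seed)),
    truth = data.frame(fiber = seq_len(n_total), bundle = bundle_id,
                       outlier = outlier_flag),
    label_volume = labels, parcel_volume = parcels,
    centerlines = ctrls, spec = spec), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d bundles x %d fibers (%d planted outliers), seed %d\n",
              x$spec$n_bundles, x$spec$fibers_per_bundle,
              sum(x$truth$outlier), x$spec$seed))
  invisible(x)
}

#' Write a scene to disk (TRK + NIfTI + JSON truth sidecar)
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param basename file stem (default "scene").
#' @return named vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, basename = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tractogram = file.path(dir, paste0(basename, ".trk")),
    labels = file.path(dir, paste0(basename, "_labels.nii.gz")),
    parcels = file.path(dir, paste0(basename, "_parcels.nii.gz")),
    truth = file.path(dir, paste0(basename, "_truth.json")))
  write_tractogram(scene$tractogram, paths["tractogram"])
  write_label_volume(scene$label_volume, paths["labels"])
  write_label_volume(scene$parcel_volume, paths["parcels"])
  jsonlite::write_json(list(spec = unclass(scene$spec),
                            bundle = scene$truth$bundle,
                            outlier = scene$truth$outlier),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Score predicted assignments against a scene's ground truth
#'
#' Adjusted Rand index between the true bundle ids and the predicted hard
#' labels (outlier-flagged fibers excluded), plus precision/recall of the
#' planted-outlier flags.
#'
#' @param scene a `synthetic_scene`.
#' @param assignments assignment data frame covering the scene's fibers.
#' @return list with `ari`, `outlier_precision`, `outlier_recall`.
#' @export
truth_report <- function(scene, assignments) {
  stopifnot(nrow(assignments) == nrow(scene$truth))
  keep <- !assignments$outlier
  ari <- adjusted_rand_index(scene$truth$bundle[keep], assignments$label[keep])
  tp <- sum(assignments$outlier & scene$truth$outlier)
  list(ari = ari,
       outlier_precision = if (sum(assignments$outlier) > 0)
         tp / sum(assignments$outlier) else NA_real_,
       outlier_recall = if (sum(scene$truth$outlier) > 0)
         tp / sum(scene$truth$outlier) else NA_real_)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions, 1 for identical
#' partitions and approximately 0 for independent ones.
#'
#' @param a,b integer label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
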