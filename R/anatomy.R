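#' Construct a label volume
#'
#' An integer 3-D array of anatomical region (or cortical parcel) ids with a
#' voxel-to-world affine, in the style of a FreeSurfer parcellation resampled
#' into the diffusion space. Id 0 is background.
#'
#' @param grid 3-D integer array of non-negative region ids.
#' @param affine 4x4 voxel-to-world-mm transform (0-based voxel indices).
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(grid, affine = diag(4)) {
  grid <- as.array(grid)
  storage.mode(grid) <- "integer"
  if (length(dim(grid)) != 3L) stop("grid must be a 3-D array")
  if (any(grid < 0L)) stop("region ids must be non-negative")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(grid = grid, affine = affine), class = "label_volume")
}

#' Read a label volume from a NIfTI file
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return a [label_volume]; the xform is used as the voxel-to-world affine.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(round(as.array(img)), structure(RNifti::xform(img), dim = c(4, 4)))
}

#' Write a label volume to a NIfTI file
#' @param vol a [label_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world-mm coordinates (n x 3) -> nearest-voxel region ids; 0 outside grid
lookup_labels <- function(points, vol) {
  inv <- solve(vol$affine)
  vox <- t(inv %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
  idx <- round(vox) + 1  # 0-based voxel -> R index
  d <- dim(vol$grid)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
            idx[, 2] >= 1 & idx[, 2] <= d[2] &
            idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- integer(nrow(points))
  if (any(inside))
    out[inside] <- vol$grid[cbind(idx[inside, 1], idx[inside, 2], idx[inside, 3])]
  out
}

#' Label every point of a fiber with its anatomical region
#'
#' Each point receives the region id of the voxel that contains it
#' (nearest-voxel lookup after the world-to-voxel transform); points outside
#' the volume get label 0.
#'
#' @param f a [fiber].
#' @param vol a [label_volume] of anatomical regions.
#' @return the fiber with `point_labels` set.
#' @export
label_fiber_points <- function(f, vol) {
  stopifnot(inherits(f, "fiber"), inherits(vol, "label_volume"))
  f$point_labels <- lookup_labels(f$points, vol)
  f
}

#' Label the endpoints of a fiber with cortical parcels
#'
#' Each fiber end is assigned the parcel id of the nearest nonzero-labelled
#' voxel centre (Euclidean distance in world mm), approximating assignment to
#' the closest point of the cortical surface. Ties go to the lowest parcel
#' id, deterministically.
#'
#' @param f a [fiber].
#' @param parcels a [label_volume] of cortical parcels with at least one
#'   nonzero voxel.
#' @return the fiber with `endpoint_parcels` set.
#' @export
label_fiber_endpoints <- function(f, parcels) {
  stopifnot(inherits(f, "fiber"), inherits(parcels, "label_volume"))
  centers <- parcel_voxel_centers(parcels)
  if (nrow(centers$xyz) == 0L) stop("parcel volume has no nonzero voxels")
  ends <- f$points[c(1L, nrow(f$points)), , drop = FALSE]
  f$endpoint_parcels <- nearest_parcel(ends, centers)
  f
}

# cache-friendly precomputation shared by label_tractogram
parcel_voxel_centers <- function(parcels) {
  nz <- which(parcels$grid != 0L, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(list(xyz = matrix(0, 0, 3), ids = integer(0)))
  ids <- parcels$grid[nz]
  xyz <- t(parcels$affine %*% rbind(t(nz - 1), 1))[, 1:3, drop = FALSE]
  ord <- order(ids)  # ascending id so that ties resolve to the lowest id
  list(xyz = xyz[ord, , drop = FALSE], ids = ids[ord])
}

nearest_parcel <- function(points, centers) {
  out <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (centers$xyz[, 1] - points[i, 1])^2 +
          (centers$xyz[, 2] - points[i, 2])^2 +
          (centers$xyz[, 3] - points[i, 3])^2
    out[i] <- centers$ids[which.min(d2)]  # which.min: first (lowest id) on ties
  }
  out
}

#' Attach anatomical labels to every fiber of a tractogram
#'
#' Convenience wrapper applying [label_fiber_points()] and (optionally)
#' [label_fiber_endpoints()] to each fiber.
#'
#' @param t a [tractogram].
#' @param regions a [label_volume] of anatomical regions, or NULL to skip.
#' @param parcels a [label_volume] of cortical parcels, or NULL to skip.
#' @return the labelled [tractogram].
#' @export
label_tractogram <- function(t, regions = NULL, parcels = NULL) {
  stopifnot(inherits(t, "tractogram"))
  if (!is.null(regions))
    t$fibers <- lapply(t$fibers, label_fiber_points, vol = regions)
  if (!is.null(parcels)) {
    centers <- parcel_voxel_centers(parcels)
    if (nrow(centers$xyz) == 0L) stop("parcel volume has no nonzero voxels")
    ends <- do.call(rbind, lapply(t$fibers, function(f)
      f$points[c(1L, nrow(f$points)), , drop = FALSE]))
    ids <- nearest_parcel(ends, centers)
    for (i in seq_along(t$fibers))
      t$fibers[[i]]$endpoint_parcels <- ids[c(2L * i - 1L, 2L * i)]
  }
  t
}

# distinct nonzero region ids of a fiber (full-resolution labels are kept on
# resampled fibers under point_labels_full)
fiber_regions <- function(f) {
  lab <- f$point_labels
  if (is.null(lab)) lab <- f$point_labels_full
  if (is.null(lab)) stop("fiber has no point labels; run label_fiber_points first")
  sort(unique(lab[lab > 0L]))
}

#' Tract anatomical profile of a cluster
#'
#' The set of anatomical regions intersected by more than a stated fraction
#' (default 40%) of the cluster's fibers; the threshold is strict
#' (a region present in exactly 40% of fibers is excluded).
#'
#' @param cluster_fibers non-empty list of labelled [fiber]s.
#' @param threshold fraction in (0, 1); default 0.40.
#' @return object of class `tract_anatomical_profile` with fields `regions`
#'   (integer vector) and `threshold`.
#' @export
tract_anatomical_profile <- function(cluster_fibers, threshold = 0.40) {
  if (length(cluster_fibers) == 0L) stop("empty cluster")
  stopifnot(threshold > 0, threshold < 1)
  region_sets <- lapply(cluster_fibers, fiber_regions)
  counts <- table(unlist(region_sets))
  keep <- as.integer(names(counts))[counts / length(cluster_fibers) > threshold]
  structure(list(regions = sort(keep), threshold = threshold),
            class = "tract_anatomical_profile")
}

#' Tract surface profile of a cluster
#'
#' For each cortical parcel, the fraction of the cluster's fiber endpoints
#' terminating in that parcel (2 endpoints per fiber; background endpoints
#' are dropped from the listing, so fractions sum to 1 only when every
#' endpoint carries a nonzero parcel).
#'
#' @param cluster_fibers non-empty list of [fiber]s with endpoint parcels.
#' @return object of class `tract_surface_profile`: named numeric vector
#'   `fractions` (names = parcel ids).
#' @export
tract_surface_profile <- function(cluster_fibers) {
  if (length(cluster_fibers) == 0L) stop("empty cluster")
  parcels <- unlist(lapply(cluster_fibers, function(f) {
    if (is.null(f$endpoint_parcels))
      stop("fiber has no endpoint parcels; run label_fiber_endpoints first")
    f$endpoint_parcels
  }))
  parcels <- parcels[parcels > 0L]
  fr <- table(parcels) / (2L * length(cluster_fibers))
  fractions <- as.numeric(fr)
  names(fractions) <- names(fr)
  structure(list(fractions = fractions), class = "tract_surface_profile")
}

#' Dice overlap between a fiber's regions and a cluster's anatomical profile
#'
#' `2 |intersect(F, P)| / (|F| + |P|)` over distinct nonzero region ids, 0
#' when both sets are empty.
#'
#' @param fiber a labelled [fiber].
#' @param profile a [tract_anatomical_profile].
#' @return Dice score in \[0, 1\].
#' @export
dice_anatomical <- function(fiber, profile) {
  f <- fiber_regions(fiber)
  p <- profile$regions
  if (length(f) + length(p) == 0L) return(0)
  2 * length(intersect(f, p)) / (length(f) + length(p))
}

#' Endpoint agreement between a fiber and a cluster's surface profile
#'
#' The fraction of the cluster's endpoints lying in the cortical parcels
#' touched by the fiber's endpoints: the sum of the cluster's tract surface
#' profile fractions over the fiber's distinct endpoint parcels.
#'
#' @param fiber a [fiber] with endpoint parcels.
#' @param profile a [tract_surface_profile].
#' @return agreement score in \[0, 1\].
#' @export
endpoint_agreement <- function(fiber, profile) {
  if (is.null(fiber$endpoint_parcels))
    stop("fiber has no endpoint parcels; run label_fiber_endpoints first")
  ids <- unique(fiber$endpoint_parcels)
  ids <- ids[ids > 0L]
  sum(profile$fractions[as.character(ids)], na.rm = TRUE)
}
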