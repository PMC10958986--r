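#' Construct a fiber (streamline)
#'
#' A fiber is an ordered polyline of 3-D points in world (RAS) millimetre
#' coordinates, optionally annotated with per-point anatomical region labels
#' and a pair of cortical endpoint parcel labels.
#'
#' @param points numeric matrix with one row per point and 3 columns (x, y, z
#'   in mm); at least 2 rows.
#' @param point_labels optional integer vector of non-negative region ids,
#'   one per point (0 = background / unlabelled).
#' @param endpoint_parcels optional integer vector of length 2: the cortical
#'   parcel id associated with each end of the fiber.
#' @return an object of class `fiber`.
#' @export
fiber <- function(points, point_labels = NULL, endpoint_parcels = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("fiber points must be an n x 3 matrix")
  if (nrow(points) < 2L) stop("a fiber needs at least 2 points")
  if (!all(is.finite(points))) stop("fiber coordinates must be finite")
  if (!is.null(point_labels)) {
    point_labels <- as.integer(point_labels)
    if (length(point_labels) != nrow(points))
      stop("point_labels must match the number of points")
    if (any(point_labels < 0L)) stop("point_labels must be non-negative")
  }
  if (!is.null(endpoint_parcels)) {
    endpoint_parcels <- as.integer(endpoint_parcels)
    if (length(endpoint_parcels) != 2L)
      stop("endpoint_parcels must have length 2")
  }
  structure(list(points = points, point_labels = point_labels,
                 endpoint_parcels = endpoint_parcels),
            class = "fiber")
}

#' Construct a tractogram
#'
#' @param fibers list of [fiber] objects (or n x 3 matrices, which are
#'   promoted).
#' @param space coordinate-convention tag; only `"world-mm"` is used
#'   internally.
#' @param source free-text provenance string.
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(fibers, space = "world-mm", source = "") {
  fibers <- lapply(fibers, function(f) if (inherits(f, "fiber")) f else fiber(f))
  structure(list(fibers = fibers, space = space, source = source),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$fibers)

#' @export
print.tractogram <- function(x, ...) {
  npts <- vapply(x$fibers, function(f) nrow(f$points), integer(1))
  cat(sprintf("Tractogram: %d fibers, %d-%d points each, space=%s\n",
              length(x$fibers), if (length(npts)) min(npts) else 0L,
              if (length(npts)) max(npts) else 0L, x$space))
  invisible(x)
}

#' Arc length of a fiber
#'
#' Sum of consecutive point-to-point Euclidean distances, in mm.
#' @param f a [fiber].
#' @return numeric length in mm.
#' @export
fiber_length <- function(f) {
  p <- f$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Reverse the point order of a fiber
#'
#' A streamline can equivalently start from either end; flipping reverses the
#' stored order, reverses any per-point labels in step, and swaps the
#' endpoint parcels.
#' @param f a [fiber].
#' @return the flipped [fiber].
#' @export
flip_fiber <- function(f) {
  fiber(f$points[nrow(f$points):1, , drop = FALSE],
        point_labels = if (!is.null(f$point_labels)) rev(f$point_labels),
        endpoint_parcels = if (!is.null(f$endpoint_parcels)) rev(f$endpoint_parcels))
}

#' Remove fibers shorter than a threshold
#'
#' Fibers strictly shorter than `min_length_mm` are dropped; a fiber whose
#' arc length equals the threshold exactly is kept.
#' @param t a [tractogram].
#' @param min_length_mm non-negative length threshold in mm (default 40, the
#'   conventional whole-brain tractography filter).
#' @return the filtered [tractogram].
#' @export
filter_by_length <- function(t, min_length_mm = 40) {
  stopifnot(inherits(t, "tractogram"), min_length_mm >= 0)
  keep <- vapply(t$fibers, fiber_length, numeric(1)) >= min_length_mm
  tractogram(t$fibers[keep], space = t$space, source = t$source)
}

#' Resample a fiber to a fixed number of points
#'
#' Places exactly `np` points at equal arc-length intervals along the
#' piecewise-linear curve; the first and last original points are always
#' retained. Per-point labels are deliberately not resampled (full-resolution
#' anatomical labels are kept alongside the downsampled geometry); endpoint
#' parcels are carried over.
#'
#' @param f a [fiber].
#' @param np integer >= 2, number of output points (default 14).
#' @return a [fiber] with `np` points.
#' @export
resample_fiber <- function(f, np = 14) {
  stopifnot(np >= 2)
  p <- f$points
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("cannot resample a zero-length fiber")
  target <- seq(0, total, length.out = np)
  out <- matrix(0, np, 3)
  for (d in 1:3) out[, d] <- stats::approx(s, p[, d], xout = target,
                                           ties = "ordered")$y
  out[1, ] <- p[1, ]
  out[np, ] <- p[nrow(p), ]
  res <- fiber(out, endpoint_parcels = f$endpoint_parcels)
  res$point_labels_full <- f$point_labels
  res
}

#' Resample every fiber of a tractogram
#'
#' @param t a [tractogram].
#' @param np points per fiber (default 14).
#' @return a [tractogram] of `np`-point fibers.
#' @export
resample_tractogram <- function(t, np = 14) {
  tractogram(lapply(t$fibers, resample_fiber, np = np),
             space = t$space, source = t$source)
}

# Stack equally sampled fibers into an np x 3 x n array for the C++ kernels.
fiber_array <- function(t) {
  stopifnot(inherits(t, "tractogram"), length(t$fibers) > 0)
  np <- nrow(t$fibers[[1]]$points)
  bad <- vapply(t$fibers, function(f) nrow(f$points) != np, logical(1))
  if (any(bad)) stop("all fibers must share the same point count; resample first")
  arr <- array(0, dim = c(np, 3, length(t$fibers)))
  for (i in seq_along(t$fibers)) arr[, , i] <- t$fibers[[i]]$points
  arr
}

#' Minimum average direct-flip (MDF) distance between two fibers
#'
#' The mean corresponding-point Euclidean distance between two equally
#' sampled fibers, minimised over the two possible orderings of one fiber:
#' `min(mean_i ||a_i - b_i||, mean_i ||a_i - b_{np+1-i}||)`. Symmetric,
#' non-negative and invariant to flipping either fiber.
#'
#' @param a,b [fiber]s resampled to the same point count.
#' @return distance in mm.
#' @export
mdf_distance <- function(a, b) {
  if (nrow(a$points) != nrow(b$points))
    stop("MDF requires equal point counts; resample both fibers first")
  cpp_mdf_distance(a$points, b$points)
}

#' All pairwise MDF distances of a tractogram
#'
#' @param t a [tractogram] of equally sampled fibers.
#' @return symmetric n x n matrix of distances (mm) with zero diagonal.
#' @export
pairwise_mdf <- function(t) {
  cpp_pairwise_mdf(fiber_array(t))
}
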