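#' Read a tractogram from disk
#'
#' Supported formats: TrackVis `.trk` (binary; the header voxel-to-RAS
#' transform and the TrackVis half-voxel origin convention are applied so
#' coordinates come out in world mm), MRtrix `.tck` (binary, native world
#' mm), VTK legacy polydata `.vtk` (ASCII) and VTK XML polydata `.vtp`
#' (ASCII). The format is inferred from the file extension unless given.
#'
#' @param path file path.
#' @param format one of `"trk"`, `"tck"`, `"vtk"`, `"vtp"`; default inferred
#'   from the extension.
#' @return a [tractogram] in world-mm coordinates.
#' @export
read_tractogram <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- resolve_format(path, format)
  t <- switch(format,
    trk = read_trk(path),
    tck = read_tck(path),
    vtk = read_vtk_legacy(path),
    vtp = read_vtp(path),
    stop("unsupported tractogram format: ", format))
  if (length(t$fibers) == 0L) stop("no streamlines in ", path)
  t
}

#' Write a tractogram to disk
#'
#' Coordinates are preserved within 1e-4 mm on a read-back round trip for
#' every supported format (TRK and TCK store float32).
#'
#' @param t a non-empty [tractogram].
#' @param path output file path.
#' @param format one of `"trk"`, `"tck"`, `"vtk"`, `"vtp"`; default inferred
#'   from the extension.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path, format = NULL) {
  stopifnot(inherits(t, "tractogram"))
  if (length(t$fibers) == 0L) stop("refusing to write an empty tractogram")
  format <- resolve_format(path, format)
  switch(format,
    trk = write_trk(t, path),
    tck = write_tck(t, path),
    vtk = write_vtk_legacy(t, path),
    vtp = write_vtp(t, path),
    stop("unsupported tractogram format: ", format))
  invisible(path)
}

resolve_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(tolower(format), c("trk", "tck", "vtk", "vtp")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("trk", "tck", "vtk", "vtp"))
    stop("cannot infer tractogram format from extension '", ext, "'")
  ext
}

## ---------------------------------------------------------------------------
## TrackVis .trk (format version 2, little-endian, 1000-byte header).
## Points are stored in "voxmm": voxel indices scaled by voxel size, with the
## voxel-center-at-half-voxel convention. world = A %*% (p / voxel_size - 0.5)
## where A is the header vox_to_ras affine.

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6)
  if (!identical(rawToChar(id[1:5]), "TRACK")) stop("not a TRK file: ", path)
  dim3 <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  n_properties <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  A <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
              4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6))
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000L) stop("corrupt TRK header (hdr_size != 1000)")
  if (all(A == 0)) A <- diag(4)  # legacy files without a stored transform
  if (all(voxel_size == 0)) voxel_size <- c(1, 1, 1)
  fibers <- list()
  repeat {
    npts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", npts * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_properties > 0)
      invisible(readBin(con, "numeric", n_properties, size = 4, endian = "little"))
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2, voxel_size, "/") - 0.5
    world <- t(A %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    fibers[[length(fibers) + 1L]] <- fiber(world)
    if (n_count > 0 && length(fibers) == n_count) break
  }
  tractogram(fibers, source = path)
}

write_trk <- function(t, path, voxel_size = c(1, 1, 1), affine = diag(4)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(c(0, 0, 0)), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)   # voxel_order
  writeBin(raw(4), con)
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(raw(2), con)
  writeBin(raw(6), con)
  writeBin(length(t$fibers), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")
  writeBin(1000L, con, size = 4, endian = "little")
  Ainv <- solve(affine)
  for (f in t$fibers) {
    p <- f$points
    vox <- t(Ainv %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
    voxmm <- sweep(vox + 0.5, 2, voxel_size, "*")
    writeBin(nrow(p), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## MRtrix .tck: text header, then float32 triplets in world mm; streamlines
## are separated by a NaN triplet and the stream ends with an Inf triplet.

read_tck <- function(path) {
  sz <- file.size(path)
  rawdata <- readBin(path, "raw", sz)
  pat <- charToRaw("END\n")
  endpos <- NA_integer_
  for (i in which(rawdata == pat[1])) {
    if (i + 3L <= sz && identical(rawdata[i:(i + 3L)], pat)) { endpos <- i + 3L; break }
  }
  if (is.na(endpos)) stop("corrupt TCK header (no END)")
  hdr <- strsplit(rawToChar(rawdata[1:endpos]), "\n", fixed = TRUE)[[1]]
  if (!grepl("^mrtrix tracks", hdr[1])) stop("not a TCK file: ", path)
  offset <- NULL
  datatype <- "Float32LE"
  for (line in hdr[-1]) {
    m <- regmatches(line, regexec("^([^:]+):[[:space:]]*(.*)$", line))[[1]]
    if (length(m) == 3L) {
      if (m[2] == "file") offset <- as.integer(sub("^\\.[[:space:]]*", "", m[3]))
      if (m[2] == "datatype") datatype <- m[3]
    }
  }
  if (is.null(offset)) stop("corrupt TCK header (no file offset)")
  if (datatype != "Float32LE") stop("unsupported TCK datatype: ", datatype)
  if (offset >= sz) stop("no streamlines in ", path)
  raw_vals <- readBin(rawdata[(offset + 1L):sz], "numeric",
                      n = (sz - offset) %/% 4L, size = 4, endian = "little")
  m <- matrix(raw_vals[seq_len(3L * (length(raw_vals) %/% 3L))],
              ncol = 3, byrow = TRUE)
  fibers <- list()
  start <- 1L
  for (i in seq_len(nrow(m))) {
    if (!all(is.finite(m[i, ]))) {
      if (i > start) fibers[[length(fibers) + 1L]] <- fiber(m[start:(i - 1L), , drop = FALSE])
      start <- i + 1L
      if (all(is.infinite(m[i, ]))) break
    }
  }
  tractogram(fibers, source = path)
}

write_tck <- function(t, path) {
  header <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                   length(t$fibers), "\n")
  # the 'file' line records its own byte offset; iterate to the fixed point
  stub <- paste0(header, "file: . ")
  base <- nchar(stub, type = "bytes") + nchar("\nEND\n", type = "bytes")
  offset <- base + 1L
  repeat {
    o2 <- base + nchar(as.character(offset), type = "bytes")
    if (o2 == offset) break
    offset <- o2
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(stub, offset, "\nEND\n"), con, eos = NULL)
  nanrow <- rep(NaN, 3)
  for (f in t$fibers) {
    writeBin(as.numeric(t(f$points)), con, size = 4, endian = "little")
    writeBin(as.numeric(nanrow), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4, endian = "little")
  invisible(path)
}

## ---------------------------------------------------------------------------
## VTK legacy polydata (ASCII): POINTS + LINES sections.

read_vtk_legacy <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^# vtk DataFile", txt[1]))
    stop("not a legacy VTK file: ", path)
  toks <- scan(text = txt[-(1:2)], what = character(), quiet = TRUE)
  ip <- which(toupper(toks) == "POINTS")[1]
  if (is.na(ip)) stop("no POINTS section in ", path)
  n <- as.integer(toks[ip + 1])
  coords <- as.numeric(toks[(ip + 3):(ip + 2 + 3 * n)])
  pts <- matrix(coords, ncol = 3, byrow = TRUE)
  il <- which(toupper(toks) == "LINES")[1]
  if (is.na(il)) stop("no LINES section in ", path)
  nl <- as.integer(toks[il + 1])
  pos <- il + 3
  fibers <- vector("list", nl)
  for (i in seq_len(nl)) {
    m <- as.integer(toks[pos])
    idx <- as.integer(toks[(pos + 1):(pos + m)]) + 1L
    fibers[[i]] <- fiber(pts[idx, , drop = FALSE])
    pos <- pos + m + 1L
  }
  tractogram(fibers, source = path)
}

write_vtk_legacy <- function(t, path) {
  npts <- vapply(t$fibers, function(f) nrow(f$points), integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tractogram", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", sum(npts))), con)
  for (f in t$fibers)
    writeLines(apply(f$points, 1, function(r) paste(format(r, digits = 9,
               scientific = FALSE, trim = TRUE), collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", length(t$fibers), sum(npts) + length(npts)), con)
  off <- 0L
  for (i in seq_along(t$fibers)) {
    writeLines(paste(c(npts[i], seq.int(off, off + npts[i] - 1L)), collapse = " "), con)
    off <- off + npts[i]
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## VTK XML polydata (.vtp), ASCII-encoded DataArrays.

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  arr <- function(xp) {
    node <- xml2::xml_find_first(piece, xp)
    if (inherits(node, "xml_missing")) stop("malformed .vtp: missing ", xp)
    scan(text = xml2::xml_text(node), what = numeric(), quiet = TRUE)
  }
  pts <- matrix(arr(".//Points/DataArray"), ncol = 3, byrow = TRUE)
  conn <- as.integer(arr(".//Lines/DataArray[@Name='connectivity']")) + 1L
  offs <- as.integer(arr(".//Lines/DataArray[@Name='offsets']"))
  start <- 1L
  fibers <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    fibers[[i]] <- fiber(pts[conn[start:offs[i]], , drop = FALSE])
    start <- offs[i] + 1L
  }
  tractogram(fibers, source = path)
}

write_vtp <- function(t, path) {
  npts <- vapply(t$fibers, function(f) nrow(f$points), integer(1))
  coords <- do.call(rbind, lapply(t$fibers, function(f) f$points))
  conn <- seq_len(sum(npts)) - 1L
  offs <- cumsum(npts)
  fmt <- function(x) paste(format(x, digits = 9, scientific = FALSE, trim = TRUE),
                           collapse = " ")
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    '  <PolyData>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="0">',
            sum(npts), length(npts)),
    '      <Points>',
    '        <DataArray type="Float32" NumberOfComponents="3" format="ascii">',
    paste0("          ", fmt(as.numeric(t(coords)))),
    '        </DataArray>',
    '      </Points>',
    '      <Lines>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste0("          ", fmt(conn)),
    '        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste0("          ", fmt(offs)),
    '        </DataArray>',
    '      </Lines>',
    '    </Piece>',
    '  </PolyData>',
    '</VTKFile>')
  writeLines(xml, path)
  invisible(path)
}
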