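# Streamline file I/O: MRtrix .tck and TrackVis .trk dialects.
#
# Coordinates are held in scanner/world mm inside the package. TCK stores
# world mm natively. TRK stores "voxel-mm" (voxel index * voxel size, corner
# origin); the header's vox_to_ras affine maps voxel indices to world mm, so
# on read points are converted via world = A %*% (p / voxel_size - 0.5) and
# the inverse on write (the convention used by TrackVis and nibabel).

#' Write a bundle to an MRtrix .tck file
#'
#' Text header, then little-endian float32 triplets; streamlines are
#' separated by NaN triplets and the stream is terminated by an Inf triplet.
#'
#' @param bundle a `streamline_bundle`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tck <- function(bundle, path) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    "count: ", length(bundle$streamlines), "\n")
  # 'file: . <offset>' must state the byte offset of the binary section;
  # fix the offset by padding the header to a known size.
  base <- paste0(header, "file: . ")
  offset <- nchar(base, type = "bytes") + 20L  # room for offset + "\nEND\n"
  hdr <- paste0(base, format(offset, width = 12), "\nEND\n")
  hdr <- sprintf("%-*s", offset, hdr)
  writeChar(substr(hdr, 1L, offset), con, eos = NULL)
  for (s in bundle$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate "\nEND\n" at the byte level (the data section is binary)
  pat <- charToRaw("\nEND\n")
  lim <- min(4096L, length(raw) - 4L)
  m <- -1L
  for (i in seq_len(lim)) {
    if (raw[i] == pat[1L] && identical(raw[i:(i + 4L)], pat)) { m <- i; break }
  }
  if (m < 0) stop(path, ": truncated TCK header (no END)")
  hdr <- rawToChar(raw[seq_len(m + 4L)])
  fm <- regmatches(hdr, regexpr("file: \\. +[0-9]+", hdr))
  if (!length(fm)) stop(path, ": TCK header missing 'file:' offset")
  offset <- as.integer(sub("file: \\. +", "", fm))
  if (!grepl("Float32LE", hdr)) stop(path, ": unsupported TCK datatype")
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                  n = (length(raw) - offset) %/% 4L, size = 4L,
                  endian = "little")
  if (length(vals) %% 3L != 0L) stop(path, ": truncated TCK data section")
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.na(pts) & !is.infinite(pts)) > 0L
  is_inf <- rowSums(is.infinite(pts)) > 0L
  if (!any(is_inf)) stop(path, ": truncated TCK data (no terminator)")
  end <- which(is_inf)[1L] - 1L
  streamlines <- list()
  cur <- integer(0)
  for (i in seq_len(end)) {
    if (is_nan[i]) {
      if (length(cur)) {
        streamlines[[length(streamlines) + 1L]] <- pts[cur, , drop = FALSE]
        cur <- integer(0)
      }
    } else cur <- c(cur, i)
  }
  if (length(cur))
    streamlines[[length(streamlines) + 1L]] <- pts[cur, , drop = FALSE]
  if (!length(streamlines)) stop(path, ": TCK file contains no streamlines")
  streamline_bundle(streamlines)
}

#' Write a bundle to a TrackVis .trk file
#'
#' World-mm coordinates are converted to the TRK voxel-mm convention using
#' the supplied voxel-to-world affine.
#'
#' @param bundle a `streamline_bundle` (world mm).
#' @param path output path.
#' @param voxel_size_mm voxel size triplet written to the header.
#' @param affine 4x4 voxel-to-world matrix (default: scaling by voxel size,
#'   i.e. world == voxel-mm up to the half-voxel shift).
#' @return the path, invisibly.
#' @export
write_trk <- function(bundle, path, voxel_size_mm = c(2, 2, 2),
                      affine = NULL) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
    affine[1:3, 4] <- voxel_size_mm / 2  # voxel center convention
  }
  affine <- as.matrix(affine)
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5L, eos = NULL)
  writeBin(raw(1L), con)                                   # id_string pad
  writeBin(as.integer(c(100L, 100L, 100L)), con, size = 2L,
           endian = "little")                              # dim
  writeBin(voxel_size_mm, con, size = 4L, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4L, endian = "little")  # origin
  writeBin(0L, con, size = 2L, endian = "little")          # n_scalars
  writeBin(raw(200L), con)                                 # scalar names
  writeBin(0L, con, size = 2L, endian = "little")          # n_properties
  writeBin(raw(200L), con)                                 # property names
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                 # reserved
  writeChar("RAS", con, nchars = 3L, eos = NULL)
  writeBin(raw(5L), con)                                   # pad2 remainder
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")
  writeBin(raw(8L), con)                                   # pad1 + inverts
  writeBin(length(bundle$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")          # version
  writeBin(1000L, con, size = 4L, endian = "little")       # hdr_size
  for (s in bundle$streamlines) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    vox <- t(inv %*% rbind(t(s), 1))[, 1:3, drop = FALSE]  # voxel coords
    pts <- sweep(vox + 0.5, 2L, voxel_size_mm, "*")        # voxel-mm
    writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5L, useBytes = TRUE)
  if (!identical(magic, "TRACK")) stop(path, ": not a TRK file")
  readBin(con, "raw", 1L)
  readBin(con, "integer", 3L, size = 2L, endian = "little")         # dim
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")         # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_properties <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  affine <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                   4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 8L + 24L + 8L)  # reserved, order/pad, IOP, pads
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 1000L)) stop(path, ": corrupt TRK header")
  if (all(affine == 0)) {
    # version-1 files carry no affine; fall back to the voxel-size scaling
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- voxel_size / 2
  }
  if (any(voxel_size <= 0)) stop(path, ": nonpositive voxel size in TRK header")
  streamlines <- list()
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(npts)) break
    need <- npts * (3L + n_scalars)
    vals <- readBin(con, "numeric", need, size = 4L, endian = "little")
    if (length(vals) < need) stop(path, ": truncated TRK track data")
    if (n_properties > 0L)
      readBin(con, "numeric", n_properties, size = 4L, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2L, voxel_size, "/") - 0.5
    world <- t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    streamlines[[length(streamlines) + 1L]] <- world
  }
  if (n_count > 0L && length(streamlines) != n_count)
    stop(path, ": TRK track count mismatch (truncated file?)")
  if (!length(streamlines)) stop(path, ": TRK file contains no streamlines")
  streamline_bundle(streamlines)
}

#' Read a streamline bundle (TCK or TRK)
#'
#' The format is auto-detected from magic bytes (`mrtrix tracks` for TCK,
#' `TRACK` for TRK). Coordinates are returned in world mm; for TRK the
#' header's voxel-to-world affine is applied.
#'
#' @param path file path.
#' @param voxel_size_mm voxel size attached to the returned bundle for
#'   shape-metric voxelization (default 2 mm).
#' @return a `streamline_bundle`.
#' @export
read_streamlines <- function(path, voxel_size_mm = 2.0) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) < 16L) stop(path, ": truncated or empty streamline file")
  magic <- readBin(path, "raw", n = 13L)
  bundle <- if (identical(magic, charToRaw("mrtrix tracks"))) read_tck(path)
    else if (identical(magic[1:5], charToRaw("TRACK"))) read_trk(path)
    else stop(path, ": unknown streamline format (expected TCK or TRK)")
  bundle$voxel_size_mm <- voxel_size_mm
  bundle
}
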