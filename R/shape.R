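# Bundle shape metrics: mean length, span, curl, elongation, diameter,
# volume and surface area, computed from streamline polylines in mm.
# Volume and surface area come from voxelization on an isotropic grid;
# diameter is that of the equivalent-volume cylinder.

#' Arc length of a streamline
#'
#' Sum of Euclidean distances between consecutive points; a single point has
#' length 0.
#'
#' @param polyline numeric n x 3 matrix (mm).
#' @return length in mm.
#' @export
streamline_length <- function(polyline) {
  p <- as.matrix(polyline)
  if (any(!is.finite(p))) stop("non-finite streamline coordinates")
  if (nrow(p) < 2L) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

#' Mean tract length and span of a bundle
#'
#' Length is the per-streamline arc length; span the per-streamline Euclidean
#' distance between first and last point. Both are averaged over streamlines
#' (per-streamline averaging keeps curl >= 1 streamline-wise).
#'
#' @param bundle a `streamline_bundle`.
#' @return named numeric vector `c(mean_length_mm, span_mm)`.
#' @export
bundle_length_and_span <- function(bundle) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  if (!length(bundle$streamlines)) stop("empty bundle")
  lens <- vapply(bundle$streamlines, streamline_length, 0.0)
  spans <- vapply(bundle$streamlines, function(p) {
    sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  }, 0.0)
  c(mean_length_mm = mean(lens), span_mm = mean(spans))
}

#' Curl and elongation
#'
#' `curl = mean_length / span` (>= 1: an arc is never shorter than its
#' chord); `elongation = mean_length / diameter`.
#'
#' @param mean_length_mm mean streamline arc length.
#' @param span_mm mean endpoint distance.
#' @param diameter_mm equivalent-cylinder diameter.
#' @param eps guard below which span/diameter are treated as degenerate.
#' @return a single number.
#' @export
curl <- function(mean_length_mm, span_mm, eps = 1e-9) {
  if (span_mm <= eps)
    stop("undefined curl: span is ~0 (near-closed loop)")
  mean_length_mm / span_mm
}

#' @rdname curl
#' @export
elongation <- function(mean_length_mm, diameter_mm, eps = 1e-9) {
  if (diameter_mm <= eps) stop("undefined elongation: diameter is ~0")
  mean_length_mm / diameter_mm
}

#' Voxelize a bundle
#'
#' Marks every voxel of an axis-aligned isotropic grid that contains at least
#' one streamline point, after supersampling each segment at steps of at most
#' half the voxel size (so a segment cannot jump across a voxel undetected).
#' The grid origin is the floor of the bundle bounding-box minimum, making
#' voxel counts reproducible.
#'
#' @param bundle a `streamline_bundle`.
#' @param voxel_size_mm isotropic voxel size; defaults to the bundle's.
#' @return integer matrix (m x 3) of occupied voxel indices (0-based), with
#'   attributes `voxel_size_mm` and `origin_mm`.
#' @export
voxelize <- function(bundle, voxel_size_mm = NULL) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  vs <- voxel_size_mm %||% bundle$voxel_size_mm
  if (!length(bundle$streamlines)) stop("empty bundle")
  pts <- do.call(rbind, lapply(bundle$streamlines, function(p) {
    if (nrow(p) < 2L) return(p)
    out <- list(p[1, , drop = FALSE])
    for (i in seq_len(nrow(p) - 1L)) {
      a <- p[i, ]; b <- p[i + 1L, ]
      d <- sqrt(sum((b - a)^2))
      nstep <- max(1L, ceiling(d / (vs / 2)))
      t <- seq_len(nstep) / nstep
      out[[i + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                             a[2] + t * (b[2] - a[2]),
                             a[3] + t * (b[3] - a[3]))
    }
    do.call(rbind, out)
  }))
  origin <- floor(apply(pts, 2L, min))
  idx <- floor(sweep(pts, 2L, origin) / vs)
  storage.mode(idx) <- "integer"
  idx <- unique(idx)
  structure(idx, voxel_size_mm = vs, origin_mm = origin)
}

#' Volume and surface area of an occupied voxel set
#'
#' Volume is `count * voxel_size^3`. Surface area counts exposed voxel faces
#' (faces whose 6-neighbor voxel is unoccupied) times `voxel_size^2`.
#'
#' @param voxels occupied voxel index matrix from [voxelize()].
#' @param voxel_size_mm voxel size; defaults to the attribute on `voxels`.
#' @return named numeric vector `c(volume_mm3, surface_area_mm2)`.
#' @export
volume_and_surface <- function(voxels, voxel_size_mm = NULL) {
  vs <- voxel_size_mm %||% attr(voxels, "voxel_size_mm")
  if (is.null(vs)) stop("voxel size not supplied")
  m <- nrow(voxels)
  if (!m) stop("empty voxel set")
  key <- function(v) paste(v[, 1], v[, 2], v[, 3])
  occ <- key(voxels)
  exposed <- 0L
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    nb <- voxels
    nb[, ax] <- nb[, ax] + dir
    exposed <- exposed + sum(!(key(nb) %in% occ))
  }
  c(volume_mm3 = m * vs^3, surface_area_mm2 = exposed * vs^2)
}

#' Equivalent-cylinder diameter of a bundle
#'
#' Diameter of the cylinder that has the bundle's voxelized volume and its
#' mean tract length: `2 * sqrt(volume / (pi * mean_length))`.
#'
#' @param volume_mm3 bundle volume.
#' @param mean_length_mm mean tract length (> 0).
#' @return diameter in mm (0 for zero volume).
#' @export
diameter_from_volume <- function(volume_mm3, mean_length_mm) {
  if (mean_length_mm <= 0) stop("mean length must be > 0")
  if (volume_mm3 == 0) return(0)
  2 * sqrt(volume_mm3 / (pi * mean_length_mm))
}

#' Compute all seven shape metrics of a bundle
#'
#' @param bundle a `streamline_bundle`.
#' @param voxel_size_mm grid resolution for volume/surface (defaults to the
#'   bundle's `voxel_size_mm`, conventionally 2 mm).
#' @return data frame with one row: `mean_length_mm`, `span_mm`, `curl`,
#'   `elongation`, `diameter_mm`, `volume_mm3`, `surface_area_mm2`.
#' @export
compute_shape <- function(bundle, voxel_size_mm = NULL) {
  ls <- bundle_length_and_span(bundle)
  vox <- voxelize(bundle, voxel_size_mm)
  vsa <- volume_and_surface(vox)
  dia <- diameter_from_volume(vsa[["volume_mm3"]], ls[["mean_length_mm"]])
  data.frame(
    mean_length_mm = ls[["mean_length_mm"]],
    span_mm = ls[["span_mm"]],
    curl = curl(ls[["mean_length_mm"]], ls[["span_mm"]]),
    elongation = elongation(ls[["mean_length_mm"]], dia),
    diameter_mm = dia,
    volume_mm3 = vsa[["volume_mm3"]],
    surface_area_mm2 = vsa[["surface_area_mm2"]])
}
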