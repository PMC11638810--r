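# Laterality quotient computation from grayordinate activation maps.
#
# Activation maps are long-format data frames with one row per grayordinate:
# subject_id, grayordinate_id, hemisphere ("left"/"right"), roi, z.

#' Define a region-of-interest family
#'
#' Two ROI families are built in, matching standard language-comprehension
#' laterality analyses: `"frontal"` (Brodmann areas 44 and 45, i.e. the
#' inferior frontal gyrus) and `"temporal"` (anterior temporal lobe areas
#' TGd, TGv, TE1a, TE2a, STGa, STSva, STSda). Custom label sets are allowed.
#'
#' @param family `"frontal"` or `"temporal"`.
#' @param labels optional character vector overriding the default ROI labels.
#' @return an object of class `roi_set` with fields `family` and `labels`.
#' @export
#' @examples
#' roi_set("frontal")$labels
roi_set <- function(family = c("frontal", "temporal"), labels = NULL) {
  family <- match.arg(family)
  if (is.null(labels)) {
    labels <- switch(family,
      frontal  = c("BA44", "BA45"),
      temporal = c("TGd", "TGv", "TE1a", "TE2a", "STGa", "STSva", "STSda"))
  }
  if (!is.character(labels) || length(labels) < 1L || anyDuplicated(labels))
    stop("`labels` must be a non-empty character vector without duplicates")
  structure(list(family = family, labels = labels), class = "roi_set")
}

validate_gray_map <- function(map) {
  need <- c("subject_id", "grayordinate_id", "hemisphere", "roi", "z")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("grayordinate map is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(map$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  if (any(!is.finite(map$z)))
    stop("non-finite z values in grayordinate map")
  key <- paste(map$subject_id, map$grayordinate_id)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, grayordinate_id) pairs in grayordinate map")
  invisible(map)
}

#' Threshold grayordinates at the within-ROI median
#'
#' For a single subject's map, keeps grayordinates whose z value is strictly
#' greater than the median of their own ROI (per hemisphere). With an even
#' count the median is the midpoint of the two central values; if all values
#' in an ROI are equal nothing is retained.
#'
#' @param map data frame for one subject (columns `grayordinate_id`,
#'   `hemisphere`, `roi`, `z`).
#' @param roi_set an [roi_set()]; only its labels are used.
#' @return a list with `retained` (the surviving rows) and `medians`
#'   (data frame: hemisphere, roi, median, n).
#' @export
threshold_by_roi_median <- function(map, roi_set) {
  stopifnot(inherits(roi_set, "roi_set"))
  map <- map[map$roi %in% roi_set$labels, , drop = FALSE]
  if (nrow(map) == 0L)
    stop("no grayordinates found for ROI family '", roi_set$family, "'")
  grp <- interaction(map$hemisphere, map$roi, drop = TRUE)
  meds <- tapply(map$z, grp, stats::median)
  ns <- tapply(map$z, grp, length)
  if (any(ns < 2L)) {
    bad <- names(ns)[ns < 2L]
    stop("ROI(s) with fewer than 2 grayordinates (median threshold undefined): ",
         paste(bad, collapse = ", "))
  }
  keep <- map$z > meds[as.character(grp)]
  parts <- strsplit(names(meds), ".", fixed = TRUE)
  medians <- data.frame(
    hemisphere = vapply(parts, `[`, "", 1L),
    roi = vapply(parts, `[`, "", 2L),
    median = as.numeric(meds),
    n = as.integer(ns),
    row.names = NULL, stringsAsFactors = FALSE)
  list(retained = map[keep, , drop = FALSE], medians = medians)
}

#' Hemisphere activation normalized by grayordinate count
#'
#' Sums the retained (above-median) z values over all ROIs of one hemisphere
#' and divides by that hemisphere's total pre-threshold grayordinate count in
#' the ROI set. Dividing by the pre-threshold count corrects the left/right
#' size imbalance of grayordinate space (the left hemisphere carries roughly
#' 100 more grayordinates than the right); dividing by the retained count
#' would cancel the thresholding instead. `denominator = "retained"` is
#' available for comparison.
#'
#' @param retained data frame of retained rows (from
#'   [threshold_by_roi_median()]).
#' @param total_counts named numeric vector: pre-threshold grayordinate count
#'   per hemisphere (`left`, `right`).
#' @param hemisphere `"left"` or `"right"`.
#' @param denominator `"all"` (pre-threshold count, default) or `"retained"`.
#' @return a single number; 0 when nothing was retained.
#' @export
normalized_hemisphere_activation <- function(retained, total_counts, hemisphere,
                                             denominator = c("all", "retained")) {
  denominator <- match.arg(denominator)
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  rows <- retained[retained$hemisphere == hemisphere, , drop = FALSE]
  denom <- if (denominator == "all") unname(total_counts[hemisphere]) else nrow(rows)
  if (is.na(denom) || denom <= 0)
    stop("zero grayordinate count for hemisphere '", hemisphere, "'")
  sum(rows$z) / denom
}

#' Laterality quotient
#'
#' `LQ = (L - R) / max(L, R)`, a Jaccard–Tanimoto-style asymmetry index over
#' the normalized hemisphere activations. For nonnegative L and R the value
#' lies in `[-1, 1]`, is antisymmetric under swapping hemispheres, and is
#' invariant to rescaling both activations by the same positive constant.
#'
#' @param L,R normalized left/right activation (nonnegative expected).
#' @return LQ in `[-1, 1]` for nonnegative inputs.
#' @export
#' @examples
#' compute_lq(2, 2)  # 0
#' compute_lq(1, 0)  # 1
#' compute_lq(1, 2)  # -0.5
compute_lq <- function(L, R) {
  stopifnot_scalar_number(L, "L"); stopifnot_scalar_number(R, "R")
  m <- max(L, R)
  if (m <= 0)
    stop("undefined LQ: max(L, R) <= 0 (no supra-threshold activation)")
  (L - R) / m
}

#' Classify a laterality quotient
#'
#' Values strictly above +1/3 are left language dominant (`LLD`), strictly
#' below -1/3 right language dominant (`RLD`), and everything in between —
#' including exactly +/- 1/3 — bilateral (`BLR`). The thirds split `[-1, 1]`
#' into three intervals of equal cumulative probability under a uniform LQ.
#'
#' @param lq numeric vector of LQ values in `[-1, 1]`.
#' @return character vector of `"LLD"`, `"BLR"`, `"RLD"`.
#' @export
#' @examples
#' classify_lq(c(0.53, 0.13, -0.64, 1/3))
classify_lq <- function(lq) {
  if (any(!is.finite(lq)) || any(abs(lq) > 1 + 1e-12))
    stop("LQ values must be finite and within [-1, 1]")
  ifelse(lq > 1/3, "LLD", ifelse(lq < -1/3, "RLD", "BLR"))
}

#' Run the full laterality pipeline over a cohort
#'
#' Per subject: threshold each ROI at its within-subject median, normalize
#' the retained z sums by pre-threshold hemisphere grayordinate counts,
#' compute the LQ, and classify. Frontal and temporal families are analyzed
#' independently; pass the appropriate [roi_set()].
#'
#' @param maps long-format data frame for one or more subjects (columns
#'   `subject_id`, `grayordinate_id`, `hemisphere`, `roi`, `z`).
#' @param roi_set an [roi_set()].
#' @param denominator see [normalized_hemisphere_activation()].
#' @return data frame with one row per subject: `subject_id`, `family`,
#'   `L`, `R`, `LQ`, `dominance`, plus `flag_negative` marking subjects where
#'   a normalized activation was negative (sign conventions become fragile).
#' @export
run_laterality <- function(maps, roi_set, denominator = "all") {
  validate_gray_map(maps)
  stopifnot(inherits(roi_set, "roi_set"))
  subjects <- unique(maps$subject_id)
  res <- lapply(subjects, function(sid) {
    m <- maps[maps$subject_id == sid, , drop = FALSE]
    m <- m[m$roi %in% roi_set$labels, , drop = FALSE]
    if (nrow(m) == 0L)
      stop("subject ", sid, ": no grayordinates in ROI family '",
           roi_set$family, "'")
    totals <- c(left = sum(m$hemisphere == "left"),
                right = sum(m$hemisphere == "right"))
    thr <- threshold_by_roi_median(m, roi_set)
    L <- normalized_hemisphere_activation(thr$retained, totals, "left", denominator)
    R <- normalized_hemisphere_activation(thr$retained, totals, "right", denominator)
    lq <- compute_lq(L, R)
    data.frame(subject_id = sid, family = roi_set$family,
               L = L, R = R, LQ = lq, dominance = classify_lq(lq),
               flag_negative = (L < 0 || R < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
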