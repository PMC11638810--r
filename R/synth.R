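# Synthetic cohort generators: activation maps with target LQs, streamline
# bundles with analytically known geometry, and local connectome matrices
# with a planted QA ~ LQ effect plus covariate confounding.
#
# All generators are pure functions of their spec + seed (RNG state is saved
# and restored), so the same spec always yields byte-identical output.

#' Specification of a synthetic activation cohort
#'
#' @param n_subjects number of subjects.
#' @param lq_targets numeric vector in `[-1, 1]`, one target LQ per subject.
#' @param left_count,right_count total grayordinate counts for the left/right
#'   ROI set. Defaults 1000/900 reproduce (at desk scale) the ~100-grayordinate
#'   left excess of grayordinate space; full-resolution surfaces carry 32,492
#'   vertices per hemisphere.
#' @param noise_sd standard deviation of Gaussian noise added to the z values
#'   (z-score units); 0 gives exact LQ recovery.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, lq_targets, left_count = 1000L,
                        right_count = 900L, noise_sd = 0.1, seed = 1L) {
  n_subjects <- stopifnot_count(n_subjects, "n_subjects")
  if (length(lq_targets) != n_subjects)
    stop("`lq_targets` must have length n_subjects")
  if (any(!is.finite(lq_targets)) || any(abs(lq_targets) > 1))
    stop("`lq_targets` must be finite and within [-1, 1]")
  left_count <- stopifnot_count(left_count, "left_count", min = 2L)
  right_count <- stopifnot_count(right_count, "right_count", min = 2L)
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  structure(list(n_subjects = n_subjects, lq_targets = as.numeric(lq_targets),
                 left_count = left_count, right_count = right_count,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Split `total` grayordinates across ROI labels as evenly as possible,
# every ROI getting at least 2 (median threshold needs >= 2).
split_counts <- function(total, labels) {
  k <- length(labels)
  if (total < 2L * k)
    stop("grayordinate count ", total, " too small for ", k,
         " ROIs (need >= 2 per ROI)")
  base <- total %/% k
  counts <- rep(base, k)
  counts[seq_len(total %% k)] <- base + 1L
  setNames(counts, labels)
}

# Normalized activation of one hemisphere's base pattern:
# sum of strictly-above-median z per ROI, over total count.
base_activation <- function(z_by_roi, total) {
  s <- sum(vapply(z_by_roi, function(z) sum(z[z > stats::median(z)]), 0.0))
  s / total
}

#' Generate a synthetic activation cohort with target laterality quotients
#'
#' Each hemisphere of each subject receives a positive base z pattern
#' (`1 + |N(0,1)|` per grayordinate, split across the ROI labels). The two
#' hemispheres are then rescaled by closed-form constants so that the
#' median-threshold laterality pipeline returns exactly the subject's target
#' LQ at `noise_sd = 0`; Gaussian noise is added after scaling. Because the
#' median threshold and the count normalization are both equivariant under
#' positive scaling, the construction is exact, not approximate.
#'
#' @param spec a [cohort_spec()].
#' @param roi_set an [roi_set()]; its labels are used on both hemispheres.
#' @return list with `maps` (long-format grayordinate data frame for all
#'   subjects, see [run_laterality()]) and `truth` (data frame `subject_id`,
#'   `lq_target`).
#' @export
gen_activation_cohort <- function(spec, roi_set) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(roi_set, "roi_set"))
  counts_l <- split_counts(spec$left_count, roi_set$labels)
  counts_r <- split_counts(spec$right_count, roi_set$labels)
  with_seed(spec$seed, {
    maps <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      zs_l <- lapply(counts_l, function(n) 1 + abs(rnorm(n)))
      zs_r <- lapply(counts_r, function(n) 1 + abs(rnorm(n)))
      A_l <- base_activation(zs_l, spec$left_count)
      A_r <- base_activation(zs_r, spec$right_count)
      t <- spec$lq_targets[i]
      # Solve c_l*A_l = L, c_r*A_r = R with (L-R)/max(L,R) = t and max = 1.
      if (t >= 0) { L <- 1; R <- 1 - t } else { L <- 1 + t; R <- 1 }
      c_l <- L / A_l; c_r <- R / A_r
      sid <- sprintf("S%04d", i)
      df_l <- data.frame(
        subject_id = sid,
        hemisphere = "left",
        roi = rep(names(counts_l), counts_l),
        z = unlist(lapply(zs_l, identity), use.names = FALSE) * c_l,
        stringsAsFactors = FALSE)
      df_r <- data.frame(
        subject_id = sid,
        hemisphere = "right",
        roi = rep(names(counts_r), counts_r),
        z = unlist(lapply(zs_r, identity), use.names = FALSE) * c_r,
        stringsAsFactors = FALSE)
      df <- rbind(df_l, df_r)
      if (spec$noise_sd > 0)
        df$z <- df$z + rnorm(nrow(df), sd = spec$noise_sd)
      df$grayordinate_id <- seq_len(nrow(df))
      maps[[i]] <- df
    }
    maps <- do.call(rbind, maps)
    maps <- maps[, c("subject_id", "grayordinate_id", "hemisphere", "roi", "z")]
    truth <- data.frame(subject_id = sprintf("S%04d", seq_len(spec$n_subjects)),
                        lq_target = spec$lq_targets, stringsAsFactors = FALSE)
    list(maps = maps, truth = truth)
  })
}

#' Specification of a synthetic streamline bundle
#'
#' @param shape_kind `"straight"`, `"arc"` or `"helix"` centerline.
#' @param n_streamlines number of streamlines.
#' @param length_mm centerline arc length (straight/helix) — for arcs the
#'   length is `radius_of_curvature_mm * arc_angle_rad`.
#' @param radius_mm tube radius: streamlines are parallel offset copies of
#'   the centerline, offsets inside a disk of this radius.
#' @param arc_angle_rad subtended angle for `"arc"` (in `(0, 2*pi)`).
#' @param curvature_radius_mm radius of the arc / helix cylinder.
#' @param helix_pitch_mm vertical rise per turn for `"helix"`.
#' @param n_points points per streamline.
#' @param jitter_sd_mm per-point Gaussian jitter (0 = clean copies).
#' @param layout `"random"` (offsets uniform in the disk) or `"grid"`
#'   (deterministic disk fill at spacing `grid_spacing_mm`, for voxel-volume
#'   fixtures; `n_streamlines` is then overridden by the grid size).
#' @param grid_spacing_mm spacing of the grid layout.
#' @param seed integer RNG seed.
#' @return an object of class `bundle_spec`.
#' @export
bundle_spec <- function(shape_kind = c("straight", "arc", "helix"),
                        n_streamlines = 20L, length_mm = 100,
                        radius_mm = 1, arc_angle_rad = pi,
                        curvature_radius_mm = 10, helix_pitch_mm = 20,
                        n_points = 100L, jitter_sd_mm = 0,
                        layout = c("random", "grid"), grid_spacing_mm = 1,
                        seed = 1L) {
  shape_kind <- match.arg(shape_kind)
  layout <- match.arg(layout)
  n_streamlines <- stopifnot_count(n_streamlines, "n_streamlines")
  n_points <- stopifnot_count(n_points, "n_points", min = 2L)
  stopifnot_scalar_number(length_mm, "length_mm")
  stopifnot_scalar_number(radius_mm, "radius_mm")
  stopifnot_scalar_number(jitter_sd_mm, "jitter_sd_mm")
  if (length_mm <= 0 && shape_kind != "arc") stop("`length_mm` must be > 0")
  if (radius_mm < 0 || jitter_sd_mm < 0)
    stop("`radius_mm` and `jitter_sd_mm` must be nonnegative")
  if (shape_kind == "arc") {
    if (!(arc_angle_rad > 0 && arc_angle_rad < 2 * pi))
      stop("`arc_angle_rad` must be in (0, 2*pi)")
    if (curvature_radius_mm <= 0) stop("`curvature_radius_mm` must be > 0")
  }
  structure(list(shape_kind = shape_kind, n_streamlines = n_streamlines,
                 length_mm = length_mm, radius_mm = radius_mm,
                 arc_angle_rad = arc_angle_rad,
                 curvature_radius_mm = curvature_radius_mm,
                 helix_pitch_mm = helix_pitch_mm, n_points = n_points,
                 jitter_sd_mm = jitter_sd_mm, layout = layout,
                 grid_spacing_mm = grid_spacing_mm, seed = as.integer(seed)),
            class = "bundle_spec")
}

# Centerline sample (n x 3 matrix) + analytic expectations.
analytic_centerline <- function(spec) {
  n <- spec$n_points
  switch(spec$shape_kind,
    straight = {
      t <- seq(0, spec$length_mm, length.out = n)
      list(points = cbind(t, 0, 0),
           length = spec$length_mm, span = spec$length_mm, curl = 1)
    },
    arc = {
      r <- spec$curvature_radius_mm
      th <- seq(0, spec$arc_angle_rad, length.out = n)
      len <- r * spec$arc_angle_rad
      chord <- 2 * r * sin(spec$arc_angle_rad / 2)
      list(points = cbind(r * cos(th), r * sin(th), 0),
           length = len, span = chord, curl = len / chord)
    },
    helix = {
      r <- spec$curvature_radius_mm
      pitch <- spec$helix_pitch_mm
      # arc length per radian: sqrt(r^2 + (pitch/(2*pi))^2)
      c2 <- pitch / (2 * pi)
      speed <- sqrt(r^2 + c2^2)
      th_max <- spec$length_mm / speed
      th <- seq(0, th_max, length.out = n)
      p <- cbind(r * cos(th), r * sin(th), c2 * th)
      span <- sqrt(sum((p[n, ] - p[1, ])^2))
      list(points = p, length = spec$length_mm, span = span,
           curl = spec$length_mm / span)
    })
}

# Offsets perpendicular to the local tangent would be exact; for these
# gently curved fixtures a constant offset in the plane normal to the
# chord direction is sufficient and keeps arc lengths of copies equal
# for the straight case.
disk_offsets <- function(spec) {
  r <- spec$radius_mm
  if (spec$layout == "grid") {
    s <- spec$grid_spacing_mm
    g <- seq(-r + s / 2, r - s / 2, by = s)
    if (length(g) == 0L) g <- 0
    off <- expand.grid(u = g, v = g)
    off <- off[off$u^2 + off$v^2 <= r^2, , drop = FALSE]
    as.matrix(off)
  } else {
    k <- spec$n_streamlines
    th <- runif(k, 0, 2 * pi)
    rr <- r * sqrt(runif(k))
    cbind(u = rr * cos(th), v = rr * sin(th))
  }
}

#' Generate a synthetic streamline bundle with known geometry
#'
#' The centerline follows the named analytic curve (straight segment,
#' circular arc, or helix); streamlines are offset copies within the tube
#' radius, optionally jittered per point. Analytic expectations for mean
#' length, span and curl of the centerline are attached as the `expected`
#' attribute for use as test oracles (e.g. a straight bundle has curl 1, a
#' semicircular arc curl pi/2).
#'
#' @param spec a [bundle_spec()].
#' @return a `streamline_bundle`: list with `streamlines` (list of n x 3
#'   matrices, mm), `voxel_size_mm`, and attribute `expected`.
#' @export
gen_bundle <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  cl <- analytic_centerline(spec)
  with_seed(spec$seed, {
    off <- disk_offsets(spec)
    k <- nrow(off)
    # offset frame: two unit vectors orthogonal to the overall chord direction
    chord <- cl$points[nrow(cl$points), ] - cl$points[1, ]
    if (sum(chord^2) < 1e-12) chord <- c(1, 0, 0)
    e1 <- chord / sqrt(sum(chord^2))
    ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    e2 <- ref - sum(ref * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    streamlines <- lapply(seq_len(k), function(i) {
      shift <- off[i, 1] * e2 + off[i, 2] * e3
      p <- sweep(cl$points, 2, shift, "+")
      if (spec$jitter_sd_mm > 0)
        p <- p + matrix(rnorm(length(p), sd = spec$jitter_sd_mm), ncol = 3)
      unname(p)
    })
    structure(
      list(streamlines = streamlines, voxel_size_mm = 2.0),
      class = "streamline_bundle",
      expected = list(mean_length_mm = cl$length, span_mm = cl$span,
                      curl = cl$curl, n_streamlines = k))
  })
}

#' Construct a streamline bundle from raw polylines
#'
#' @param streamlines list of numeric matrices (n x 3, mm).
#' @param voxel_size_mm isotropic voxel size used by volume/surface metrics.
#' @return a `streamline_bundle`.
#' @export
streamline_bundle <- function(streamlines, voxel_size_mm = 2.0) {
  if (!is.list(streamlines) || length(streamlines) == 0L)
    stop("`streamlines` must be a non-empty list of matrices")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3L || nrow(s) < 2L || any(!is.finite(s)))
      stop("each streamline must be a finite n x 3 matrix with n >= 2")
    unname(s)
  })
  stopifnot_scalar_number(voxel_size_mm, "voxel_size_mm")
  if (voxel_size_mm <= 0) stop("`voxel_size_mm` must be > 0")
  structure(list(streamlines = streamlines, voxel_size_mm = voxel_size_mm),
            class = "streamline_bundle")
}

#' Specification of a planted QA-LQ effect
#'
#' @param block_start first segment index (1-based) of the contiguous block
#'   carrying the effect.
#' @param block_len number of segments in the block (>= 1).
#' @param effect_r target population correlation between segment QA and the
#'   laterality quotient inside the block, in `(-1, 1)`.
#' @param confound_strength loading of the (standardized) covariate score on
#'   QA at every segment; 0 disables confounding.
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(block_start = 1L, block_len = 0L, effect_r = 0,
                           confound_strength = 0) {
  stopifnot_scalar_number(effect_r, "effect_r")
  if (abs(effect_r) >= 1) stop("`effect_r` must lie in (-1, 1)")
  if (block_len > 0) block_start <- stopifnot_count(block_start, "block_start")
  block_len <- stopifnot_count(block_len, "block_len", min = 0L)
  stopifnot_scalar_number(confound_strength, "confound_strength")
  structure(list(block_start = as.integer(block_start),
                 block_len = block_len, effect_r = effect_r,
                 confound_strength = confound_strength),
            class = "planted_effect")
}

#' Generate a synthetic local connectome matrix with covariates
#'
#' Builds a subjects x segments QA matrix over a 1-D chain of segments
#' (segment i adjacent to i-1 and i+1, uniform 2 mm per segment by default).
#' Covariates follow a healthy-adult cohort: age uniform on 22–35 years, sex
#' Bernoulli(0.5), Edinburgh handedness concentrated near +100 with a
#' left-handed minority (~8%). The laterality quotient is driven by a latent
#' standard normal `u`; inside the planted block the QA latent loads on `u`
#' so that the population Pearson correlation between the QA latent and `u`
#' equals `effect_r` even in the presence of confounding, and QA is a
#' strictly increasing transform of the latent (Spearman-invariant),
#' guaranteeing positivity. Outside the block QA is independent of LQ given
#' the covariates.
#'
#' @param n_subjects,n_segments dimensions of the QA matrix.
#' @param planted a [planted_effect()]; the block must fit inside
#'   `1..n_segments`.
#' @param segment_length_mm physical length per segment (mm).
#' @param lq_sd standard deviation used when mapping the latent to the
#'   reported LQ (LQ = tanh(lq_sd * u), keeping it inside `[-1, 1]`).
#' @param lq optional vector of laterality quotients to use instead of
#'   simulating them (e.g. the output of [run_laterality()]); the planted
#'   effect is then built against the normal scores of these values, so the
#'   rank (Spearman) correlation target still holds.
#' @param seed integer RNG seed.
#' @return list with `matrix` (a `local_connectome`: `qa` matrix plus
#'   `segments` data frame with id, position, orientation, length_mm,
#'   neighbor list) and `covariates` (data frame: subject_id, age, sex,
#'   handedness, lq).
#' @export
gen_local_connectome <- function(n_subjects, n_segments, planted = planted_effect(),
                                 segment_length_mm = 2, lq_sd = 0.6, lq = NULL,
                                 seed = 1L) {
  n_subjects <- stopifnot_count(n_subjects, "n_subjects", min = 3L)
  n_segments <- stopifnot_count(n_segments, "n_segments")
  stopifnot(inherits(planted, "planted_effect"))
  if (planted$block_len > 0 &&
      planted$block_start + planted$block_len - 1L > n_segments)
    stop("planted block exceeds segment range")
  if (!is.null(lq) && length(lq) != n_subjects)
    stop("`lq` must have length n_subjects")
  with_seed(seed, {
    n <- n_subjects
    age <- sample(22:35, n, replace = TRUE)
    sex <- rbinom(n, 1L, 0.5)
    lefty <- runif(n) < 0.08
    handedness <- ifelse(lefty, rnorm(n, -60, 25), rnorm(n, 85, 15))
    handedness <- pmin(100, pmax(-100, handedness))
    if (is.null(lq)) {
      u <- rnorm(n)                    # latent driving LQ
      lq <- tanh(lq_sd * u)
    } else {
      # normal scores of the supplied LQs: rank correlation target preserved
      u <- stats::qnorm((rank(lq, ties.method = "average") - 0.5) / n)
    }
    # standardized confound score from the covariates
    covs <- scale(cbind(age, sex, handedness))
    covs[is.nan(covs)] <- 0            # constant column guard
    w <- c(1, 1, 1) / sqrt(3)
    conf_score <- as.numeric(covs %*% w)
    g <- planted$confound_strength
    r <- planted$effect_r
    v <- g^2 * stats::var(conf_score)  # variance of confound component
    a <- r * sqrt(1 + v)               # lq loading giving cor(latent, u) = r
    if (a^2 > 1)
      stop("effect_r too large for the given confound_strength")
    block <- if (planted$block_len > 0)
      seq(planted$block_start, length.out = planted$block_len) else integer(0)
    eps <- matrix(rnorm(n * n_segments), n, n_segments)
    latent <- g * conf_score + eps     # n x segments
    if (length(block))
      latent[, block] <- g * conf_score + a * u +
        sqrt(1 - a^2) * eps[, block, drop = FALSE]
    qa <- 0.3 * exp(0.15 * latent)     # strictly positive, monotone in latent
    rownames(qa) <- sprintf("S%04d", seq_len(n))
    colnames(qa) <- sprintf("seg%04d", seq_len(n_segments))
    segments <- data.frame(
      id = colnames(qa),
      x = seq_len(n_segments) * segment_length_mm, y = 0, z = 0,
      ox = 1, oy = 0, oz = 0,
      length_mm = segment_length_mm,
      stringsAsFactors = FALSE)
    neighbors <- lapply(seq_len(n_segments), function(i)
      setdiff(c(i - 1L, i + 1L), c(0L, n_segments + 1L)))
    segments$neighbors <- I(neighbors)
    covariates <- data.frame(subject_id = rownames(qa), age = age, sex = sex,
                             handedness = handedness, lq = lq,
                             stringsAsFactors = FALSE)
    list(matrix = local_connectome(qa, segments), covariates = covariates)
  })
}
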