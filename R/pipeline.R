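# End-to-end pipeline over a synthetic cohort: simulate -> laterality ->
# connectometry -> shape -> group statistics, writing all artifacts plus a
# JSON run manifest. Every stage is driven by the one seed, so reruns are
# byte-identical.

#' Run the full laterality/connectometry/shape pipeline on a synthetic cohort
#'
#' Simulates an activation cohort with realistic LQ targets, recovers per-
#' subject laterality, builds a local connectome whose planted block
#' correlates with the recovered LQ (negative effect, as for commissural
#' tracts), runs connectometry, generates one per-subject bundle whose length
#' carries a group effect (left-dominant subjects get longer tracts),
#' computes shape metrics, and compares them across laterality groups with
#' covariate adjustment. All tables and a manifest are written to `outdir`.
#'
#' @param outdir output directory (created if missing).
#' @param n_subjects cohort size (default 100).
#' @param family ROI family, `"frontal"` or `"temporal"`.
#' @param n_segments connectome segments (default 200).
#' @param effect_r planted QA-LQ correlation (default -0.4, the sign of the
#'   commissural finding).
#' @param block_start,block_len planted block (defaults 60, 30).
#' @param group_length_shift_mm added mean tract length for left-dominant
#'   subjects (default 6 mm).
#' @param n_permutations connectometry permutations (default 5000).
#' @param t_threshold,fdr_threshold,min_length_mm,prune_iterations
#'   connectometry parameters (defaults 3, 0.01, 20, 16).
#' @param voxel_size_mm shape-analysis grid resolution (default 2).
#' @param noise_sd activation noise (default 0.1).
#' @param seed master seed.
#' @return invisibly, a list with the in-memory results of every stage and
#'   the written file paths.
#' @export
run_pipeline <- function(outdir, n_subjects = 100L, family = "frontal",
                         n_segments = 200L, effect_r = -0.4,
                         block_start = 60L, block_len = 30L,
                         group_length_shift_mm = 6,
                         n_permutations = 5000L, t_threshold = 3,
                         fdr_threshold = 0.01, min_length_mm = 20,
                         prune_iterations = 16L, voxel_size_mm = 2,
                         noise_sd = 0.1, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  rs <- roi_set(family)

  # -- simulate activation maps with cohort-like LQ targets ------------------
  lq_mean <- if (family == "frontal") 0.33 else 0.17
  lq_sd <- if (family == "frontal") 0.31 else 0.20
  targets <- with_seed(seed, pmin(0.99, pmax(-0.99, rnorm(n_subjects, lq_mean, lq_sd))))
  cohort <- gen_activation_cohort(
    cohort_spec(n_subjects, targets, noise_sd = noise_sd, seed = seed + 1L), rs)
  f_maps <- file.path(outdir, "grayordinates.tsv")
  write_grayordinate_table(cohort$maps, f_maps)

  # -- laterality ------------------------------------------------------------
  lat <- run_laterality(cohort$maps, rs)
  f_lat <- file.path(outdir, "laterality.tsv")
  write_laterality_table(lat, f_lat)

  # -- connectometry on a planted-effect connectome --------------------------
  conn <- gen_local_connectome(
    n_subjects, n_segments,
    planted_effect(block_start, block_len, effect_r, confound_strength = 0.3),
    lq = lat$LQ, seed = seed + 2L)
  f_mat <- file.path(outdir, "connectome.csv")
  f_side <- file.path(outdir, "connectome.json")
  write_connectome_matrix(conn$matrix, conn$covariates, f_mat, f_side)
  cres <- run_connectometry(conn$matrix, conn$covariates,
                            t_threshold = t_threshold,
                            n_permutations = n_permutations,
                            fdr_threshold = fdr_threshold,
                            min_length_mm = min_length_mm,
                            prune_iterations = prune_iterations,
                            seed = seed + 3L)
  f_stats <- file.path(outdir, "segment_stats.tsv")
  write_tsv(cres$stats, f_stats)
  track_df <- do.call(rbind, lapply(c("pos", "neg"), function(s) {
    trs <- cres$tracks[[s]]
    if (!length(trs)) return(NULL)
    data.frame(track_id = paste0(s, seq_along(trs)),
               sign = if (s == "pos") 1L else -1L,
               length_mm = vapply(trs, `[[`, 0.0, "length_mm"),
               significant = vapply(trs, function(t) isTRUE(t$significant), FALSE),
               segments = vapply(trs, function(t)
                 paste(t$segments, collapse = ","), ""),
               stringsAsFactors = FALSE)
  }))
  if (is.null(track_df))
    track_df <- data.frame(track_id = character(0), sign = integer(0),
                           length_mm = numeric(0), significant = logical(0),
                           segments = character(0))
  f_tracks <- file.path(outdir, "tracks.tsv")
  write_tsv(track_df, f_tracks)
  fdr_df <- rbind(
    if (nrow(cres$fdr$pos)) cbind(sign = 1L, cres$fdr$pos),
    if (nrow(cres$fdr$neg)) cbind(sign = -1L, cres$fdr$neg))
  if (is.null(fdr_df))
    fdr_df <- data.frame(sign = integer(0), length_mm = numeric(0),
                         fdr_raw = numeric(0), fdr = numeric(0),
                         significant = logical(0))
  f_fdr <- file.path(outdir, "fdr.tsv")
  write_tsv(fdr_df, f_fdr)

  # -- per-subject bundle + shape metrics ------------------------------------
  shift <- ifelse(lat$dominance == "LLD", group_length_shift_mm, 0)
  base_len <- with_seed(seed + 4L, rnorm(n_subjects, 80, 4)) + shift
  shapes <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    b <- gen_bundle(bundle_spec("straight", n_streamlines = 12L,
                                length_mm = base_len[i], radius_mm = 2,
                                n_points = 25L, jitter_sd_mm = 0.2,
                                seed = seed + 10L + i))
    cbind(data.frame(subject_id = lat$subject_id[i], bundle = "synthetic_tract",
                     stringsAsFactors = FALSE),
          compute_shape(b, voxel_size_mm))
  }))
  f_shapes <- file.path(outdir, "shapes.tsv")
  write_tsv(shapes, f_shapes)

  # -- group statistics --------------------------------------------------------
  covs <- conn$covariates[, c("age", "sex", "handedness")]
  metric_cols <- shapes[, c("mean_length_mm", "span_mm", "curl", "elongation",
                            "diameter_mm", "volume_mm3", "surface_area_mm2")]
  gstats <- compare_shape_by_laterality(metric_cols, lat$dominance, covs)
  f_gstats <- file.path(outdir, "group_tests.tsv")
  write_tsv(gstats$tests, f_gstats)
  reg <- regress_lq_on_feature(lat$LQ, shapes$mean_length_mm, covs)
  f_reg <- file.path(outdir, "lq_regression.tsv")
  write_tsv(data.frame(feature = "mean_length_mm", slope = reg$slope,
                       se = reg$se, t = reg$t, p = reg$p, n = reg$n), f_reg)

  # -- manifest ----------------------------------------------------------------
  config <- list(n_subjects = n_subjects, family = family,
                 n_segments = n_segments, effect_r = effect_r,
                 block_start = block_start, block_len = block_len,
                 group_length_shift_mm = group_length_shift_mm,
                 n_permutations = n_permutations, t_threshold = t_threshold,
                 fdr_threshold = fdr_threshold, min_length_mm = min_length_mm,
                 prune_iterations = prune_iterations,
                 voxel_size_mm = voxel_size_mm, noise_sd = noise_sd,
                 lq_boundary = 1 / 3, seed = seed)
  f_manifest <- file.path(outdir, "manifest.json")
  write_manifest(f_manifest, config,
                 inputs = c(f_maps, f_mat, f_side))
  invisible(list(laterality = lat, connectometry = cres, shapes = shapes,
                 group_tests = gstats, regression = reg,
                 files = c(grayordinates = f_maps, laterality = f_lat,
                           connectome = f_mat, sidecar = f_side,
                           segment_stats = f_stats, tracks = f_tracks,
                           fdr = f_fdr, shapes = f_shapes,
                           group_tests = f_gstats, regression = f_reg,
                           manifest = f_manifest)))
}
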