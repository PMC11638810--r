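# Synthetic generators: seeded determinism, LQ round-trips, bundle geometry
# metadata, planted connectome effects.

test_that("activation generator is deterministic and recovers LQ at zero noise", {
  rs <- roi_set("frontal")
  targets <- seq(-0.9, 0.9, by = 0.3)
  spec <- cohort_spec(length(targets), targets, noise_sd = 0, seed = 7)
  a <- gen_activation_cohort(spec, rs)
  b <- gen_activation_cohort(spec, rs)
  expect_identical(a, b)
  lat <- run_laterality(a$maps, rs)
  expect_equal(lat$LQ, targets, tolerance = 1e-12)
  # lq_target 0 at zero noise recovers 0 to floating tolerance
  z0 <- gen_activation_cohort(cohort_spec(1, 0, noise_sd = 0, seed = 2), rs)
  expect_lt(abs(run_laterality(z0$maps, rs)$LQ), 1e-12)
})

test_that("default grayordinate counts keep the ~100 left excess", {
  spec <- cohort_spec(1, 0.2, noise_sd = 0, seed = 1)
  expect_equal(spec$left_count - spec$right_count, 100L)
  co <- gen_activation_cohort(spec, roi_set("frontal"))
  expect_equal(sum(co$maps$hemisphere == "left"), 1000L)
  expect_equal(sum(co$maps$hemisphere == "right"), 900L)
})

test_that("noisy cohort recovery error stays small", {
  rs <- roi_set("frontal")
  set.seed(11)
  targets <- runif(50, -0.9, 0.9)
  co <- gen_activation_cohort(
    cohort_spec(50, targets, noise_sd = 0.1, seed = 13), rs)
  lat <- run_laterality(co$maps, rs)
  expect_lt(mean(abs(lat$LQ - targets)), 0.05)
})

test_that("cohort_spec rejects invalid inputs", {
  expect_error(cohort_spec(2, c(0, NA), seed = 1), "finite")
  expect_error(cohort_spec(2, c(0, 1.5), seed = 1), "within")
  expect_error(cohort_spec(3, c(0, 1), seed = 1), "length")
  expect_error(cohort_spec(1, 0, noise_sd = -1, seed = 1), "nonnegative")
  # counts too small for a per-ROI median
  expect_error(
    gen_activation_cohort(cohort_spec(1, 0, left_count = 2, right_count = 2,
                                      noise_sd = 0, seed = 1),
                          roi_set("frontal")),
    "too small")
})

test_that("bundle generator matches its analytic metadata", {
  # straight: curl exactly 1 with no jitter
  b <- gen_bundle(bundle_spec("straight", n_streamlines = 3, length_mm = 100,
                              radius_mm = 0.5, jitter_sd_mm = 0, seed = 1))
  m <- bundle_length_and_span(b)
  expect_equal(unname(m["mean_length_mm"] / m["span_mm"]), 1, tolerance = 1e-9)
  ex <- attr(b, "expected")
  expect_equal(ex$curl, 1)
  # semicircular arc: curl pi/2
  arc <- gen_bundle(bundle_spec("arc", n_streamlines = 1, radius_mm = 0,
                                arc_angle_rad = pi, curvature_radius_mm = 10,
                                n_points = 1000, seed = 1))
  ma <- bundle_length_and_span(arc)
  expect_equal(unname(ma["mean_length_mm"] / ma["span_mm"]), pi / 2,
               tolerance = 1e-3)
  expect_equal(attr(arc, "expected")$curl, pi / 2, tolerance = 1e-12)
  # helix: fixed spec -> identical bundle across runs
  hs <- bundle_spec("helix", n_streamlines = 6, length_mm = 80, radius_mm = 1,
                    jitter_sd_mm = 0.3, seed = 5)
  expect_identical(gen_bundle(hs), gen_bundle(hs))
})

test_that("bundle_spec rejects degenerate shapes", {
  expect_error(bundle_spec("straight", length_mm = 0), "length_mm")
  expect_error(bundle_spec("arc", arc_angle_rad = 0), "arc_angle_rad")
  expect_error(bundle_spec("arc", arc_angle_rad = 2 * pi), "arc_angle_rad")
})

test_that("connectome generator: determinism, null behaviour, planted block", {
  # same seed -> identical matrix
  pe <- planted_effect(10, 20, 0.9, confound_strength = 0.3)
  a <- gen_local_connectome(200, 60, pe, seed = 3)
  b <- gen_local_connectome(200, 60, pe, seed = 3)
  expect_identical(a, b)
  # planted block: empirical Spearman rho with LQ within 0.1 of target
  rho_block <- vapply(10:29, function(j)
    cor(rank(a$matrix$qa[, j]), rank(a$covariates$lq)), 0.0)
  expect_true(all(abs(rho_block - 0.9) < 0.1))
  # null: no effect -> small |rho| across segments
  n0 <- gen_local_connectome(500, 40, planted_effect(effect_r = 0), seed = 8)
  rho0 <- vapply(seq_len(40), function(j)
    cor(rank(n0$matrix$qa[, j]), rank(n0$covariates$lq)), 0.0)
  expect_lt(mean(abs(rho0)), 0.06)
  # QA strictly positive, chain adjacency symmetric by construction
  expect_true(all(a$matrix$qa > 0))
  expect_error(planted_effect(1, 5, 1.0), "effect_r")
  expect_error(gen_local_connectome(50, 10, planted_effect(8, 5, 0.5), seed = 1),
               "exceeds")
})

test_that("supplied lq vector is used verbatim and carries the planted effect", {
  lqs <- seq(-0.8, 0.8, length.out = 150)
  g <- gen_local_connectome(150, 30, planted_effect(5, 10, 0.7), lq = lqs,
                            seed = 4)
  expect_identical(g$covariates$lq, lqs)
  rho <- cor(rank(g$matrix$qa[, 10]), rank(lqs))
  expect_gt(rho, 0.4)
})

test_that("covariates look like a healthy-adult cohort", {
  g <- gen_local_connectome(2000, 5, planted_effect(), seed = 21)
  cv <- g$covariates
  expect_true(all(cv$age >= 22 & cv$age <= 35))
  expect_true(all(cv$sex %in% c(0, 1)))
  expect_true(all(abs(cv$handedness) <= 100))
  expect_lt(abs(mean(cv$handedness < 0) - 0.08), 0.03)
  expect_true(all(abs(cv$lq) <= 1))
})
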