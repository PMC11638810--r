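# Connectometry: partial Spearman correlation vs oracle, T conversion, track
# growing vs a connected-components oracle, permutation null, FDR, pruning,
# length filtering, sign coherence and determinism.

test_that("spearman_partial handles perfect monotone relations", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_partial(x, x), 1)
  expect_equal(spearman_partial(x, -x), -1)
  expect_equal(spearman_partial(x, exp(x)), 1)   # rank-based: monotone maps
  expect_true(is.na(spearman_partial(x, rep(1, 7))))
})

test_that("spearman_partial matches the brute-force rank-residual oracle", {
  set.seed(31)
  for (i in 1:50) {
    n <- 30
    k <- sample(0:2, 1)
    x <- rnorm(n)
    covs <- if (k > 0) matrix(rnorm(n * k), n, k) else NULL
    y <- 0.5 * x + rnorm(n) + if (k > 0) covs %*% rep(0.7, k) else 0
    expect_equal(spearman_partial(x, y, covs),
                 oracle_spearman_partial(x, y, covs), tolerance = 1e-10)
  }
  # with ties
  set.seed(32)
  for (i in 1:20) {
    x <- sample(1:5, 20, replace = TRUE)
    y <- sample(1:4, 20, replace = TRUE)
    cv <- matrix(rnorm(20), 20, 1)
    expect_equal(spearman_partial(x, y, cv), oracle_spearman_partial(x, y, cv),
                 tolerance = 1e-10)
  }
})

test_that("t_from_r follows the partial-correlation t formula", {
  expect_equal(t_from_r(0, 27), 0)
  expect_equal(t_from_r(0.5, 27, 0), 5 * 0.5 / sqrt(0.75), tolerance = 1e-12)
  rhos <- seq(-0.9, 0.9, by = 0.1)
  ts <- t_from_r(rhos, 50, 2)
  expect_true(all(diff(ts) > 0))  # monotone in rho
  expect_identical(t_from_r(1, 10), Inf)
  expect_identical(t_from_r(-1, 10), -Inf)
})

test_that("track growing matches the connected-components oracle", {
  skip_if_not_installed("igraph")
  segs <- make_chain_segments(200)
  set.seed(5)
  for (i in 1:100) {
    t <- rnorm(200)
    t[sample(200, 30)] <- 4   # random positive markings
    stats <- data.frame(id = segs$id, rho = 0, t = t)
    got <- select_and_grow(stats, segs, t_threshold = 3)
    want <- oracle_components(which(t >= 3), segs$neighbors)
    got_chains <- lapply(got$pos, `[[`, "segments")
    got_chains <- got_chains[order(vapply(got_chains, min, 0L))]
    expect_equal(got_chains, unname(want))
  }
})

test_that("select_and_grow computes physical track lengths", {
  segs <- make_chain_segments(40)
  t <- rep(0, 40); t[10:21] <- 5
  got <- select_and_grow(data.frame(id = segs$id, rho = 0, t = t), segs)
  expect_length(got$pos, 1L)
  expect_equal(got$pos[[1]]$length_mm, 24)  # 12 segments x 2 mm
  expect_length(got$neg, 0L)
  # nothing passing -> zero tracks
  none <- select_and_grow(data.frame(id = segs$id, rho = 0, t = rep(1, 40)), segs)
  expect_length(none$pos, 0L)
})

test_that("pruning removes singly supported spurs and is idempotent", {
  shared <- list(segments = c(5L, 6L, 7L), length_mm = 6, sign = 1L)
  tracks <- list(shared, shared, shared)
  expect_length(prune_tracks(tracks), 3L)  # all tracks share all segments
  spur <- list(segments = 20L, length_mm = 2, sign = 1L)
  pruned <- prune_tracks(c(tracks, list(spur)))
  expect_length(pruned, 3L)
  expect_identical(prune_tracks(pruned), pruned)  # fixed point
})

test_that("filter_short drops lengths strictly below the cutoff", {
  trk <- function(l) list(segments = 1L, length_mm = l, sign = 1L)
  tracks <- lapply(c(18, 20, 24), trk)
  kept <- filter_short(tracks, 20)
  expect_equal(vapply(kept, `[[`, 0.0, "length_mm"), c(20, 24))
  expect_identical(filter_short(list(), 20), list())
  expect_warning(out <- filter_short(lapply(c(3, 5), trk), 20), "shorter")
  expect_length(out, 0L)
})

test_that("FDR estimation: trivial nulls, empty input, monotone curve", {
  # null never reaches the observed lengths -> FDR 0 everywhere
  f <- estimate_fdr(c(30, 44), null_lengths = c(2, 4, 6), n_permutations = 10)
  expect_true(all(f$table$fdr == 0))
  expect_true(all(f$significant))
  # no observed tracks -> empty, not an error
  f0 <- estimate_fdr(numeric(0), c(1, 2), 10)
  expect_equal(nrow(f0$table), 0L)
  # observed drawn from the null itself -> FDR near 1 at the median length
  set.seed(40)
  null_l <- rexp(2000, 0.1)
  obs <- sample(null_l, 40)
  f1 <- estimate_fdr(obs, null_l, n_permutations = 50)
  med_fdr <- f1$table$fdr[which.min(abs(f1$table$length_mm - median(obs)))]
  expect_gt(med_fdr, 0.5)
  # monotone after step-down smoothing
  expect_true(all(diff(f1$table$fdr) <= 1e-12))
})

test_that("identity permutation reproduces the observed tracks", {
  g <- gen_local_connectome(80, 50, planted_effect(10, 12, 0.7, 0.2), seed = 9)
  st <- segment_stats(g$matrix, g$covariates)
  obs <- select_and_grow(st, g$matrix$segments)
  st2 <- segment_stats(g$matrix, g$covariates)  # same variable, unshuffled
  obs2 <- select_and_grow(st2, g$matrix$segments)
  expect_identical(obs, obs2)
})

test_that("permutation null is seed-deterministic", {
  g <- gen_local_connectome(60, 40, planted_effect(5, 10, 0.5, 0.2), seed = 2)
  n1 <- permutation_null(g$matrix, g$covariates, n_permutations = 25, seed = 77)
  n2 <- permutation_null(g$matrix, g$covariates, n_permutations = 25, seed = 77)
  expect_identical(n1, n2)
})

test_that("negating the study variable swaps positive and negative tracks", {
  g <- gen_local_connectome(120, 60, planted_effect(15, 20, 0.6, 0.2), seed = 6)
  r1 <- run_connectometry(g$matrix, g$covariates, n_permutations = 50, seed = 3)
  cv <- g$covariates
  cv$lq <- -cv$lq
  r2 <- run_connectometry(g$matrix, cv, n_permutations = 50, seed = 3)
  chains <- function(trs) lapply(trs, `[[`, "segments")
  expect_equal(chains(r1$tracks$pos), chains(r2$tracks$neg))
  expect_equal(chains(r1$tracks$neg), chains(r2$tracks$pos))
  expect_equal(r1$stats$rho, -r2$stats$rho, tolerance = 1e-12)
})

test_that("run_connectometry is deterministic and recovers a planted block", {
  g <- gen_local_connectome(200, 80, planted_effect(20, 15, -0.5, 0.3), seed = 12)
  r1 <- run_connectometry(g$matrix, g$covariates, n_permutations = 100, seed = 4)
  r2 <- run_connectometry(g$matrix, g$covariates, n_permutations = 100, seed = 4)
  expect_identical(r1$significant_tracks, r2$significant_tracks)
  sig_neg <- unique(unlist(lapply(r1$significant_tracks$neg, `[[`, "segments")))
  planted <- 20:34
  expect_gte(length(intersect(sig_neg, planted)) / length(planted), 0.8)
  expect_length(r1$significant_tracks$pos, 0L)
})

test_that("two identical groups produce no findings in indicator mode", {
  g <- gen_local_connectome(100, 50, planted_effect(effect_r = 0), seed = 15)
  cv <- g$covariates
  cv$group <- rep(c(0, 1), 50)   # arbitrary split, exchangeable
  r <- run_connectometry(g$matrix, cv, variable = "group",
                         n_permutations = 100, seed = 8)
  expect_length(r$significant_tracks$pos, 0L)
  expect_length(r$significant_tracks$neg, 0L)
})
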