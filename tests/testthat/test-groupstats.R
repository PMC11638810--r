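# Group statistics: ANCOVA vs matrix-algebra oracle, Tukey vs ptukey oracle,
# BH vs hand computation, regression behaviour, F = t^2 identity.

test_that("equal group means give F near 0 and p near 1", {
  set.seed(1)
  g <- rep(c("LLD", "BLR", "RLD"), each = 30)
  y <- rnorm(90)
  y <- y - ave(y, g)  # force identical group means (zero)
  res <- anova_by_group(y, g)
  expect_lt(res$F, 1e-20)
  expect_gt(res$p_raw, 0.999)
})

test_that("ANCOVA agrees with the normal-equations oracle", {
  set.seed(2)
  for (i in 1:10) {
    n <- 60
    g <- sample(c("LLD", "BLR", "RLD"), n, replace = TRUE)
    covs <- data.frame(age = sample(22:35, n, TRUE), sex = rbinom(n, 1, 0.5),
                       handedness = runif(n, -100, 100))
    y <- rnorm(n) + 0.5 * (g == "LLD") + 0.01 * covs$age
    res <- anova_by_group(y, g, covs)
    want <- oracle_ancova_f(y, g, covs)
    expect_equal(res$F, want$F, tolerance = 1e-8)
    expect_equal(res$p_raw, want$p, tolerance = 1e-8)
    expect_equal(res$df, want$df)
    # and without covariates
    res0 <- anova_by_group(y, g)
    want0 <- oracle_ancova_f(y, g)
    expect_equal(res0$F, want0$F, tolerance = 1e-8)
  }
})

test_that("with two groups and no covariates, F equals t squared", {
  set.seed(3)
  g <- rep(c("LLD", "BLR"), c(25, 35))
  y <- rnorm(60) + 0.4 * (g == "LLD")
  res <- anova_by_group(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("a planted one-SD group shift is detected", {
  set.seed(4)
  g <- sample(c("LLD", "BLR", "RLD"), 200, replace = TRUE, prob = c(.5, .4, .1))
  y <- rnorm(200) + (g == "LLD")
  expect_lt(anova_by_group(y, g)$p_raw, 0.01)
})

test_that("small groups are excluded with a warning", {
  y <- c(rnorm(20), rnorm(20), 1.5)
  g <- c(rep("LLD", 20), rep("BLR", 20), "RLD")
  expect_warning(res <- anova_by_group(y, g), "RLD")
  expect_equal(res$groups_used, c("BLR", "LLD"))
})

test_that("Tukey post hoc agrees with the studentized-range oracle", {
  set.seed(5)
  for (i in 1:5) {
    g <- rep(c("LLD", "BLR", "RLD"), times = c(30, 25, 12))
    y <- rnorm(67) + 0.8 * (g == "LLD")
    got <- tukey_posthoc(y, g)
    want <- oracle_tukey(y, g)
    got <- got[match(want$pair, got$pair), ]
    expect_equal(got$diff, want$diff, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(got$p_adj, want$p_adj, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # identical groups -> adjusted p near 1
  set.seed(6)
  y0 <- rnorm(90); g0 <- rep(c("A", "B", "C"), 30)
  y0 <- y0 - ave(y0, g0)
  expect_true(all(tukey_posthoc(y0, g0)$p_adj > 0.999))
})

test_that("BH adjustment matches the hand oracle and its properties", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(fdr_adjust(p), rep(0.04, 4))
  expect_equal(fdr_adjust(p), oracle_bh(p))
  expect_equal(fdr_adjust(0.03), 0.03)       # single p unchanged
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))  # all equal stay equal
  set.seed(7)
  pr <- runif(40)
  adj <- fdr_adjust(pr)
  expect_equal(adj, oracle_bh(pr), tolerance = 1e-12)
  expect_true(all(adj >= pr))                 # adjusted >= raw
  expect_equal(order(adj[order(pr)]), 1:40)   # order-preserving
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("regress_lq_on_feature recovers trivial and null relations", {
  set.seed(8)
  lq <- runif(100, -1, 1)
  r1 <- suppressWarnings(regress_lq_on_feature(lq, lq))  # perfect-fit warning
  expect_equal(r1$slope, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-12)
  # permuted feature: slope near 0, p typically large
  r0 <- regress_lq_on_feature(lq, sample(lq))
  expect_lt(abs(r0$slope), 0.3)
  # agreement with stats::lm reference on a covariate-adjusted fit
  covs <- data.frame(age = rnorm(100), sex = rbinom(100, 1, 0.5))
  feat <- 0.4 * lq + rnorm(100, sd = 0.5)
  got <- regress_lq_on_feature(lq, feat, covs)
  ref <- summary(lm(lq ~ feat + age + sex,
                    data = cbind(data.frame(lq = lq, feat = feat), covs)))
  expect_equal(got$slope, ref$coefficients["feat", "Estimate"], tolerance = 1e-10)
  expect_equal(got$p, ref$coefficients["feat", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("compare_shape_by_laterality applies BH over the metric family", {
  set.seed(9)
  n <- 90
  g <- rep(c("LLD", "BLR", "RLD"), each = 30)
  shapes <- data.frame(m1 = rnorm(n) + (g == "LLD"), m2 = rnorm(n))
  out <- compare_shape_by_laterality(shapes, g)
  expect_equal(out$tests$metric, c("m1", "m2"))
  expect_equal(out$tests$p_fdr, oracle_bh(out$tests$p_raw))
  expect_lt(out$tests$p_raw[1], 0.01)
  expect_named(out$tukey, c("m1", "m2"))
})
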