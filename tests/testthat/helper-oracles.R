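# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take different code paths from the package internals.

# Spearman partial correlation: explicit ranks, residuals from stats::lm,
# then plain Pearson correlation of the residuals.
oracle_spearman_partial <- function(x, y, covs = NULL) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (is.null(covs) || NCOL(covs) == 0L) return(stats::cor(rx, ry))
  cm <- as.matrix(covs)
  ex <- stats::resid(stats::lm(rx ~ cm))
  ey <- stats::resid(stats::lm(ry ~ cm))
  stats::cor(ex, ey)
}

# Connected components of marked segments via igraph.
oracle_components <- function(marked, neighbors) {
  if (!length(marked)) return(list())
  edges <- do.call(rbind, lapply(marked, function(i) {
    nb <- intersect(neighbors[[i]], marked)
    nb <- nb[nb > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  g <- igraph::make_empty_graph(n = length(neighbors), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  comps <- split(seq_along(comp$membership), comp$membership)
  comps <- Filter(function(cp) any(cp %in% marked), comps)
  out <- lapply(comps, function(cp) sort(intersect(as.integer(cp), marked)))
  out[order(vapply(out, min, 0L))]
}

# Covariate-adjusted one-way ANOVA (type II for the group term) via explicit
# normal equations and the extra-sum-of-squares F test.
oracle_ancova_f <- function(values, groups, covs = NULL) {
  g <- factor(groups)
  D <- stats::model.matrix(~ g)[, -1, drop = FALSE]  # group dummies
  X0 <- matrix(1, length(values), 1L)
  if (!is.null(covs)) X0 <- cbind(X0, as.matrix(covs))
  X1 <- cbind(X0, D)
  rss <- function(X, y) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  r0 <- rss(X0, values); r1 <- rss(X1, values)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(values) - ncol(X1)
  F <- ((r0 - r1) / df1) / (r1 / df2)
  list(F = F, df = c(df1, df2),
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Tukey HSD adjusted p values via ptukey on the studentized range.
oracle_tukey <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  ns <- tapply(values, g, length)
  ms <- tapply(values, g, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / df
  pairs <- utils::combn(levels(g), 2)
  data.frame(
    pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
    diff = ms[pairs[2, ]] - ms[pairs[1, ]],
    p_adj = apply(pairs, 2, function(pr) {
      se <- sqrt(mse / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
      q <- abs(ms[pr[1]] - ms[pr[2]]) / se
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Benjamini-Hochberg by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Small random chain-adjacency segment table for track-growing tests.
make_chain_segments <- function(n, length_mm = 2) {
  neighbors <- lapply(seq_len(n), function(i)
    setdiff(c(i - 1L, i + 1L), c(0L, n + 1L)))
  data.frame(id = sprintf("seg%04d", seq_len(n)),
             x = seq_len(n) * length_mm, y = 0, z = 0,
             ox = 1, oy = 0, oz = 0, length_mm = length_mm,
             neighbors = I(neighbors), stringsAsFactors = FALSE)
}
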