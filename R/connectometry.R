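# Correlational connectometry: covariate-adjusted Spearman correlation of
# per-segment quantitative anisotropy (QA) with a study variable, contiguous
# track growing over the segment adjacency graph, a permutation null over
# track length, and FDR control over track length.

#' Construct a local connectome matrix
#'
#' @param qa numeric subjects x segments matrix of quantitative anisotropy
#'   (nonnegative, no missing values); row names identify subjects, column
#'   names the segments.
#' @param segments data frame with one row per segment: `id`, position
#'   `x`,`y`,`z` (mm), orientation `ox`,`oy`,`oz`, `length_mm` (> 0), and a
#'   `neighbors` list-column of integer indices (adjacency must be symmetric).
#' @return an object of class `local_connectome`.
#' @export
local_connectome <- function(qa, segments) {
  qa <- as.matrix(qa)
  if (any(!is.finite(qa))) stop("QA matrix contains missing/non-finite values")
  if (any(qa < 0)) stop("QA values must be nonnegative")
  need <- c("id", "x", "y", "z", "ox", "oy", "oz", "length_mm", "neighbors")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(segments) != ncol(qa))
    stop("segments rows (", nrow(segments), ") != QA columns (", ncol(qa), ")")
  if (any(segments$length_mm <= 0)) stop("segment length_mm must be > 0")
  nb <- segments$neighbors
  for (i in seq_along(nb)) {
    for (j in nb[[i]]) {
      if (j < 1L || j > length(nb) || !(i %in% nb[[j]]))
        stop("segment adjacency is not symmetric at segment ", i)
    }
  }
  structure(list(qa = qa, segments = segments), class = "local_connectome")
}

# Column-wise average ranks (ties -> average), as a matrix.
rank_columns <- function(m) apply(m, 2L, rank, ties.method = "average")

#' Covariate-adjusted Spearman partial correlation
#'
#' Rank-transforms `x` and `y` (average ranks for ties), residualizes both on
#' an intercept plus the covariate columns by least squares, and returns the
#' Pearson correlation of the residuals. With no covariates this equals the
#' plain Spearman rank correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix/data frame (n x k) of nuisance
#'   variables (e.g. handedness, sex, age).
#' @return the partial rank correlation; `NA` if either variable is constant
#'   after ranking and residualization.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("x and y must be finite")
  k <- 0L
  X <- matrix(1, length(x), 1L)
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    cm <- as.matrix(covariates)
    storage.mode(cm) <- "double"
    k <- ncol(cm)
    X <- cbind(X, cm)
  }
  if (length(x) < k + 3L) stop("need at least k + 3 observations")
  qrX <- qr(X)
  ex <- qr.resid(qrX, rank(x, ties.method = "average"))
  ey <- qr.resid(qrX, rank(y, ties.method = "average"))
  sx <- sum(ex^2); sy <- sum(ey^2)
  if (sx < 1e-12 || sy < 1e-12) return(NA_real_)
  sum(ex * ey) / sqrt(sx * sy)
}

#' Convert a correlation to a T score
#'
#' `t = rho * sqrt((n - k - 2) / (1 - rho^2))`, the t statistic of a partial
#' correlation with `k` covariates. `|rho|` at 1 returns a signed infinity.
#'
#' @param rho correlation(s).
#' @param n number of subjects.
#' @param k number of covariates.
#' @return T score(s), same length as `rho`.
#' @export
t_from_r <- function(rho, n, k = 0L) {
  if (any(abs(rho) > 1, na.rm = TRUE)) stop("|rho| must be <= 1")
  df <- n - k - 2
  if (df <= 0) stop("nonpositive degrees of freedom")
  out <- rho * sqrt(df / (1 - rho^2))
  out[!is.na(rho) & abs(rho) == 1] <- sign(rho[!is.na(rho) & abs(rho) == 1]) * Inf
  out
}

# Residualized column ranks of the QA matrix plus the pieces needed to score
# any (permuted) study variable quickly.
prepare_qa <- function(qa, covariates_mat) {
  n <- nrow(qa)
  X <- cbind(1, covariates_mat)
  qrX <- qr(X)
  Eqa <- qr.resid(qrX, rank_columns(qa))
  css <- colSums(Eqa^2)
  list(qrX = qrX, Eqa = Eqa, css = css, n = n,
       k = ncol(X) - 1L)
}

# rho for every segment given a study-variable vector (uses precomputed prep).
score_variable <- function(prep, y) {
  ey <- qr.resid(prep$qrX, rank(y, ties.method = "average"))
  sy <- sum(ey^2)
  if (sy < 1e-12) return(rep(NA_real_, ncol(prep$Eqa)))
  rho <- as.numeric(crossprod(prep$Eqa, ey)) / sqrt(prep$css * sy)
  rho[prep$css < 1e-12] <- NA_real_
  rho
}

#' Per-segment correlation statistics
#'
#' Computes the covariate-adjusted Spearman partial correlation and its T
#' score for every segment of a local connectome matrix. Segments that are
#' constant across subjects are flagged `NA` and never selected.
#'
#' @param matrix a [local_connectome()].
#' @param covariates data frame including the study variable column.
#' @param variable name of the study variable column (default `"lq"`).
#' @param covariate_names columns to adjust for (default the intersection of
#'   `c("handedness", "sex", "age")` with the covariate table).
#' @return data frame: `id`, `rho`, `t`.
#' @export
segment_stats <- function(matrix, covariates, variable = "lq",
                          covariate_names = NULL) {
  stopifnot(inherits(matrix, "local_connectome"))
  if (!variable %in% names(covariates))
    stop("study variable '", variable, "' not in covariates")
  if (is.null(covariate_names))
    covariate_names <- intersect(c("handedness", "sex", "age"), names(covariates))
  cm <- as.matrix(covariates[, covariate_names, drop = FALSE])
  storage.mode(cm) <- "double"
  prep <- prepare_qa(matrix$qa, cm)
  rho <- score_variable(prep, covariates[[variable]])
  data.frame(id = matrix$segments$id, rho = rho,
             t = t_from_r(rho, n = prep$n, k = prep$k),
             stringsAsFactors = FALSE)
}

# Connected components of `marked` segment indices under the neighbor graph
# (BFS). Returns a list of integer vectors (sorted within a component).
grow_components <- function(marked, neighbors) {
  marked <- sort(marked)
  in_set <- logical(length(neighbors))
  in_set[marked] <- TRUE
  seen <- logical(length(neighbors))
  comps <- list()
  for (s in marked) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, v)
      for (w in neighbors[[v]]) {
        if (in_set[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Threshold segments and grow contiguous tracks
#'
#' Marks segments whose T score is at or beyond `+t_threshold` (positive
#' correlation) or `-t_threshold` (negative), then grows maximal connected
#' chains of same-sign marked segments over the adjacency graph. Track length
#' is the sum of member segment lengths in mm.
#'
#' @param stats data frame from [segment_stats()] (column `t`).
#' @param segments segment table of the connectome (with `neighbors`,
#'   `length_mm`).
#' @param t_threshold selection threshold on the T score (default 3,
#'   conservative against false positives).
#' @return list with `pos` and `neg`, each a list of tracks; a track is a
#'   list with `segments` (integer indices), `length_mm`, `sign`.
#' @export
select_and_grow <- function(stats, segments, t_threshold = 3) {
  nb <- segments$neighbors
  len <- segments$length_mm
  mk <- function(idx, sgn) {
    comps <- grow_components(idx, nb)
    lapply(comps, function(cp)
      list(segments = cp, length_mm = sum(len[cp]), sign = sgn))
  }
  pos_idx <- which(!is.na(stats$t) & stats$t >= t_threshold)
  neg_idx <- which(!is.na(stats$t) & stats$t <= -t_threshold)
  list(pos = mk(pos_idx, 1L), neg = mk(neg_idx, -1L))
}

#' Remove poorly supported tracks (simplified topology-informed pruning)
#'
#' Iteratively removes tracks that contain any segment supported by only a
#' single track, recomputing segment support after each pass, until a fixed
#' point or the iteration cap. This is a simplified surrogate of
#' topology-informed pruning of spurious streamlines: singly supported spurs
#' are discarded, mutually supporting tracks survive.
#'
#' @param tracks list of tracks (each with a `segments` integer vector).
#' @param iterations maximum number of passes (default 16).
#' @return the surviving tracks, in input order.
#' @export
prune_tracks <- function(tracks, iterations = 16L) {
  if (iterations < 0) stop("`iterations` must be >= 0")
  for (it in seq_len(iterations)) {
    if (!length(tracks)) break
    segs <- unlist(lapply(tracks, `[[`, "segments"))
    support <- table(segs)
    weak <- as.integer(names(support)[support == 1L])
    drop <- vapply(tracks, function(tr) any(tr$segments %in% weak), FALSE)
    if (!any(drop)) break
    tracks <- tracks[!drop]
  }
  tracks
}

#' Drop short tracks
#'
#' Removes tracks strictly shorter than `min_length_mm` (default 20 mm),
#' the conventional cutoff for interpretability.
#'
#' @param tracks list of tracks (each with `length_mm`).
#' @param min_length_mm minimum length in mm (strict `<` is removed).
#' @return filtered track list; warns when everything was removed from a
#'   non-empty input.
#' @export
filter_short <- function(tracks, min_length_mm = 20) {
  if (!length(tracks)) return(tracks)
  keep <- vapply(tracks, function(tr) tr$length_mm >= min_length_mm, FALSE)
  if (!any(keep)) warning("all tracks shorter than ", min_length_mm, " mm")
  tracks[keep]
}

# Observed candidate tracks for one sign after the seed-per-segment pruning
# step: every selected segment seeds a candidate track equal to its maximal
# chain, so an isolated single-segment spur has support 1 and is pruned while
# any multi-segment chain supports itself. Returns unique surviving chains.
grown_pruned_tracks <- function(comps, len, sgn, prune_iterations) {
  if (!length(comps)) return(list())
  seeded <- list()
  for (cp in comps) for (s in cp)
    seeded[[length(seeded) + 1L]] <- list(segments = cp, length_mm = sum(len[cp]),
                                          sign = sgn)
  kept <- prune_tracks(seeded, iterations = prune_iterations)
  if (!length(kept)) return(list())
  keys <- vapply(kept, function(tr) paste(tr$segments, collapse = ","), "")
  kept[!duplicated(keys)]
}

# One full selection pass: rho -> t -> select -> grow -> prune. Returns the
# unique pruned track lists per sign.
selection_pass <- function(prep, y, neighbors, len, t_threshold, prune_iterations) {
  rho <- score_variable(prep, y)
  t <- t_from_r(rho, n = prep$n, k = prep$k)
  pos <- grow_components(which(!is.na(t) & t >= t_threshold), neighbors)
  neg <- grow_components(which(!is.na(t) & t <= -t_threshold), neighbors)
  list(pos = grown_pruned_tracks(pos, len, 1L, prune_iterations),
       neg = grown_pruned_tracks(neg, len, -1L, prune_iterations),
       rho = rho, t = t)
}

#' Permutation null distribution of track length
#'
#' Shuffles the study variable across subjects (covariate rows stay aligned
#' with the QA rows, preserving the QA-covariate structure), re-runs the
#' full correlation/threshold/grow/prune pipeline for each permutation, and
#' records all resulting track lengths per sign.
#'
#' @param matrix a [local_connectome()].
#' @param covariates covariate data frame including the study variable.
#' @param variable study variable column name.
#' @param covariate_names nuisance columns (see [segment_stats()]).
#' @param n_permutations number of permutations (default 5000).
#' @param t_threshold,prune_iterations selection parameters.
#' @param seed RNG seed for the permutations.
#' @return list with `pos` and `neg` numeric vectors of null track lengths
#'   (mm), and `n_permutations`.
#' @export
permutation_null <- function(matrix, covariates, variable = "lq",
                             covariate_names = NULL, n_permutations = 5000L,
                             t_threshold = 3, prune_iterations = 16L,
                             seed = 1L) {
  stopifnot(inherits(matrix, "local_connectome"))
  n_permutations <- stopifnot_count(n_permutations, "n_permutations")
  if (is.null(covariate_names))
    covariate_names <- intersect(c("handedness", "sex", "age"), names(covariates))
  cm <- as.matrix(covariates[, covariate_names, drop = FALSE])
  storage.mode(cm) <- "double"
  prep <- prepare_qa(matrix$qa, cm)
  y <- covariates[[variable]]
  nb <- matrix$segments$neighbors
  len <- matrix$segments$length_mm
  with_seed(seed, {
    pos <- vector("list", n_permutations)
    neg <- vector("list", n_permutations)
    for (p in seq_len(n_permutations)) {
      yp <- y[sample.int(length(y))]
      pass <- selection_pass(prep, yp, nb, len, t_threshold, prune_iterations)
      pos[[p]] <- vapply(pass$pos, `[[`, 0.0, "length_mm")
      neg[[p]] <- vapply(pass$neg, `[[`, 0.0, "length_mm")
    }
    list(pos = unlist(pos), neg = unlist(neg), n_permutations = n_permutations)
  })
}

#' FDR over track length from a permutation null
#'
#' For each observed track length `l`, the raw FDR is the mean per-permutation
#' count of null tracks of length `>= l` divided by the number of observed
#' tracks of length `>= l`, clipped to `[0, 1]`. A monotone (step-down) curve
#' is obtained by taking the running minimum from short to long tracks;
#' significance is assessed on the monotone curve.
#'
#' @param observed_lengths numeric vector of observed track lengths (mm).
#' @param null_lengths numeric vector of all null track lengths (mm), pooled
#'   over permutations.
#' @param n_permutations number of permutations behind `null_lengths`.
#' @param fdr_threshold significance threshold (default 0.01).
#' @return list with `table` (data frame: length_mm, fdr_raw, fdr,
#'   significant) and `significant` (logical per observed track). Empty
#'   observed input yields an empty table.
#' @export
estimate_fdr <- function(observed_lengths, null_lengths, n_permutations,
                         fdr_threshold = 0.01) {
  if (!length(observed_lengths)) {
    return(list(table = data.frame(length_mm = numeric(0), fdr_raw = numeric(0),
                                   fdr = numeric(0), significant = logical(0)),
                significant = logical(0)))
  }
  ls <- sort(unique(observed_lengths))
  raw <- vapply(ls, function(l) {
    null_ge <- sum(null_lengths >= l) / n_permutations
    obs_ge <- sum(observed_lengths >= l)
    min(1, max(0, null_ge / obs_ge))
  }, 0.0)
  mono <- cummin(raw)  # lengths ascend, so this is nonincreasing in length
  tab <- data.frame(length_mm = ls, fdr_raw = raw, fdr = mono,
                    significant = mono <= fdr_threshold)
  sig <- tab$significant[match(observed_lengths, tab$length_mm)]
  list(table = tab, significant = sig)
}

#' Run the full connectometry analysis
#'
#' Correlates segment QA with the study variable (covariate-adjusted Spearman
#' partial correlation), selects segments at the T-score threshold, grows
#' contiguous tracks per sign, prunes poorly supported spurs, estimates the
#' FDR of each track length against a permutation null, and drops short
#' tracks. Group contrasts (e.g. LLD vs BLR) are run by passing a 0/1 group
#' indicator as the study variable on the subject subset.
#'
#' @param matrix a [local_connectome()].
#' @param covariates covariate data frame including the study variable.
#' @param variable study variable column (default `"lq"`).
#' @param covariate_names nuisance columns (see [segment_stats()]).
#' @param t_threshold T-score selection threshold (default 3).
#' @param n_permutations permutations for the null (default 5000).
#' @param fdr_threshold FDR significance level (default 0.01).
#' @param min_length_mm minimum reported track length (default 20 mm).
#' @param prune_iterations pruning passes (default 16).
#' @param seed RNG seed (permutations).
#' @return an object of class `connectometry_result`: per-segment `stats`,
#'   per-sign `tracks` (all pruned tracks with `significant` flags),
#'   `significant_tracks` (length-filtered), `fdr` tables, the null summary,
#'   and the echoed `config`.
#' @export
run_connectometry <- function(matrix, covariates, variable = "lq",
                              covariate_names = NULL, t_threshold = 3,
                              n_permutations = 5000L, fdr_threshold = 0.01,
                              min_length_mm = 20, prune_iterations = 16L,
                              seed = 1L) {
  stopifnot(inherits(matrix, "local_connectome"))
  if (nrow(covariates) != nrow(matrix$qa))
    stop("covariate rows must match QA matrix rows")
  if (is.null(covariate_names))
    covariate_names <- intersect(c("handedness", "sex", "age"), names(covariates))
  cm <- as.matrix(covariates[, covariate_names, drop = FALSE])
  storage.mode(cm) <- "double"
  prep <- prepare_qa(matrix$qa, cm)
  nb <- matrix$segments$neighbors
  len <- matrix$segments$length_mm
  obs <- selection_pass(prep, covariates[[variable]], nb, len,
                        t_threshold, prune_iterations)
  null <- permutation_null(matrix, covariates, variable = variable,
                           covariate_names = covariate_names,
                           n_permutations = n_permutations,
                           t_threshold = t_threshold,
                           prune_iterations = prune_iterations, seed = seed)
  finish_sign <- function(tracks, null_lengths) {
    lengths <- vapply(tracks, `[[`, 0.0, "length_mm")
    fdr <- estimate_fdr(lengths, null_lengths, n_permutations, fdr_threshold)
    tracks <- Map(function(tr, sig) { tr$significant <- sig; tr },
                  tracks, as.list(fdr$significant %||% logical(0)))
    sig_tracks <- Filter(function(tr) isTRUE(tr$significant), tracks)
    sig_tracks <- suppressWarnings(filter_short(sig_tracks, min_length_mm))
    list(tracks = tracks, significant = sig_tracks, fdr = fdr$table)
  }
  pos <- finish_sign(obs$pos, null$pos)
  neg <- finish_sign(obs$neg, null$neg)
  structure(list(
    stats = data.frame(id = matrix$segments$id, rho = obs$rho, t = obs$t,
                       stringsAsFactors = FALSE),
    tracks = list(pos = pos$tracks, neg = neg$tracks),
    significant_tracks = list(pos = pos$significant, neg = neg$significant),
    fdr = list(pos = pos$fdr, neg = neg$fdr),
    null = null,
    config = list(variable = variable, covariate_names = covariate_names,
                  t_threshold = t_threshold, n_permutations = n_permutations,
                  fdr_threshold = fdr_threshold, min_length_mm = min_length_mm,
                  prune_iterations = prune_iterations, seed = seed,
                  n_subjects = nrow(matrix$qa),
                  n_segments = ncol(matrix$qa))),
    class = "connectometry_result")
}

#' @export
print.connectometry_result <- function(x, ...) {
  cat("Connectometry result:", x$config$n_subjects, "subjects,",
      x$config$n_segments, "segments\n")
  cat("  variable:", x$config$variable,
      "| T threshold:", x$config$t_threshold,
      "| permutations:", x$config$n_permutations,
      "| FDR:", x$config$fdr_threshold, "\n")
  for (s in c("pos", "neg")) {
    tr <- x$significant_tracks[[s]]
    cat(sprintf("  %s tracks (significant, >= %g mm): %d",
                if (s == "pos") "positively correlated" else "negatively correlated",
                x$config$min_length_mm, length(tr)))
    if (length(tr))
      cat(" | lengths mm:", paste(vapply(tr, `[[`, 0.0, "length_mm"),
                                  collapse = ", "))
    cat("\n")
  }
  invisible(x)
}
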