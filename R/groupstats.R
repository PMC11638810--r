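# Group-level statistics: covariate-adjusted ANOVA across laterality groups,
# Tukey HSD post hoc tests, Benjamini-Hochberg FDR, and linear regression of
# LQ on structural features.

#' Covariate-adjusted one-way ANOVA across laterality groups
#'
#' Tests the group factor after adjusting for covariates (type-II sums of
#' squares: the group term is assessed on top of the covariate-only model).
#' With no covariates this is the classical one-way ANOVA. Groups with fewer
#' than 2 members are excluded with a warning (right-dominant groups are
#' often tiny).
#'
#' @param values numeric response (one shape metric).
#' @param groups factor or character of group labels (e.g. LLD/BLR/RLD).
#' @param covariates optional data frame / matrix of covariates entering
#'   linearly (e.g. age, sex, handedness).
#' @param metric optional metric name echoed in the result.
#' @return list of class `group_test`: `metric`, `F`, `df` (c(df1, df2)),
#'   `p_raw`, `groups_used`, `n`.
#' @export
anova_by_group <- function(values, groups, covariates = NULL, metric = "metric") {
  groups <- as.character(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }
  if (length(unique(groups)) < 2L)
    stop("need at least 2 groups with >= 2 members")
  g <- factor(groups)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    fit0 <- lm(values ~ 1)
    fit1 <- lm(values ~ g)
  } else {
    cv <- as.data.frame(covariates)
    dat <- cbind(data.frame(.y = values, .g = g), cv)
    f0 <- stats::as.formula(paste(".y ~", paste(names(cv), collapse = " + ")))
    f1 <- stats::as.formula(paste(".y ~", paste(names(cv), collapse = " + "), "+ .g"))
    fit0 <- lm(f0, data = dat)
    fit1 <- lm(f1, data = dat)
  }
  cmp <- anova(fit0, fit1)
  structure(list(metric = metric,
                 F = cmp$F[2L],
                 df = c(cmp$Df[2L], cmp$Res.Df[2L]),
                 p_raw = cmp$`Pr(>F)`[2L],
                 groups_used = levels(g),
                 n = length(values)),
            class = "group_test")
}

#' Tukey HSD post hoc comparisons
#'
#' Pairwise group-mean differences with studentized-range adjusted p values.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return data frame: `pair`, `diff` (mean difference), `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_posthoc <- function(values, groups) {
  g <- factor(as.character(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  fit <- aov(values ~ g)
  tk <- TukeyHSD(fit)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment over the declared test family (typically the shape
#' metrics x tracts tested in one run). Order-preserving; adjusted values are
#' never below the raw ones.
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values, same order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Regress the laterality quotient on a structural feature
#'
#' Ordinary least squares of LQ on the feature plus covariates; reports the
#' feature coefficient (the structural-asymmetry effect on functional
#' lateralization).
#'
#' @param lq numeric response.
#' @param feature numeric structural feature (e.g. a shape-metric asymmetry).
#' @param covariates optional covariate data frame / matrix.
#' @return list: `slope`, `se`, `t`, `p`, `n`, plus the full `fit`.
#' @export
regress_lq_on_feature <- function(lq, feature, covariates = NULL) {
  if (length(lq) != length(feature)) stop("lq and feature lengths differ")
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    dat <- data.frame(.lq = lq, .feature = feature)
    fit <- lm(.lq ~ .feature, data = dat)
  } else {
    cv <- as.data.frame(covariates)
    dat <- cbind(data.frame(.lq = lq, .feature = feature), cv)
    fml <- stats::as.formula(paste(".lq ~ .feature +",
                                   paste(names(cv), collapse = " + ")))
    fit <- lm(fml, data = dat)
  }
  sm <- summary(fit)$coefficients
  list(slope = sm[".feature", "Estimate"], se = sm[".feature", "Std. Error"],
       t = sm[".feature", "t value"], p = sm[".feature", "Pr(>|t|)"],
       n = length(lq), fit = fit)
}

#' Group comparison of shape metrics across laterality classes
#'
#' Runs the covariate-adjusted ANOVA and Tukey post hoc for each metric
#' column, then applies Benjamini-Hochberg FDR over the family of metrics
#' tested in this call.
#'
#' @param shapes data frame of shape metrics (subjects x metrics, numeric
#'   columns only are tested).
#' @param groups laterality class per subject (LLD/BLR/RLD).
#' @param covariates optional covariate data frame.
#' @return list with `tests` (data frame: metric, F, df1, df2, p_raw, p_fdr)
#'   and `tukey` (named list of post hoc tables per metric).
#' @export
compare_shape_by_laterality <- function(shapes, groups, covariates = NULL) {
  metrics <- names(shapes)[vapply(shapes, is.numeric, FALSE)]
  if (!length(metrics)) stop("no numeric metric columns in `shapes`")
  tests <- lapply(metrics, function(mname)
    anova_by_group(shapes[[mname]], groups, covariates, metric = mname))
  tukey <- lapply(metrics, function(mname) tukey_posthoc(shapes[[mname]], groups))
  names(tukey) <- metrics
  tab <- data.frame(
    metric = metrics,
    F = vapply(tests, `[[`, 0.0, "F"),
    df1 = vapply(tests, function(t) t$df[1L], 0.0),
    df2 = vapply(tests, function(t) t$df[2L], 0.0),
    p_raw = vapply(tests, `[[`, 0.0, "p_raw"),
    stringsAsFactors = FALSE)
  tab$p_fdr <- fdr_adjust(tab$p_raw)
  list(tests = tab, tukey = tukey)
}
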