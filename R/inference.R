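#' One-way ANOVA from printed group summaries
#'
#' Reconstructs the fixed-effects F test from per-group means, SDs and
#' sample sizes alone — the form needed to check demographic tables that
#' print only summaries. Between-group SS comes from the group means about
#' the size-weighted grand mean; within-group SS is `sum((n_i - 1) s_i^2)`.
#'
#' @param means,sds,ns Numeric vectors of per-group mean, SD and size
#'   (all `n >= 2`).
#' @return List with `F`, `p`, `df` (numerator, denominator).
#' @export
#' @examples
#' anova_from_summary(c(48.57, 44.54, 53.11), c(8.7, 12.8, 12.9), c(14, 13, 18))
anova_from_summary <- function(means, sds, ns) {
  g <- length(means)
  if (g < 2 || length(sds) != g || length(ns) != g)
    stop("need equal-length means/sds/ns for >= 2 groups")
  if (any(ns < 2)) stop("every group must have n >= 2")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- g - 1
  df2 <- N - g
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE), df = c(df1, df2))
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square on a 2-D count table, without continuity
#' correction, as used for sex-by-group comparisons.
#'
#' @param counts Matrix of non-negative counts with positive row and column
#'   totals.
#' @return List with `chi2`, `p`, `df`.
#' @export
#' @examples
#' chisq_independence(rbind(male = c(6, 5, 10), female = c(8, 8, 8)))
chisq_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (length(dim(counts)) != 2 || nrow(counts) < 2 || ncol(counts) < 2)
    stop("counts must be a 2-D table with >= 2 rows and columns")
  if (any(rowSums(counts) <= 0) || any(colSums(counts) <= 0))
    stop("all row and column totals must be positive")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter))
}

# Shared linear-model workhorse: outcome ~ group + covariates, complete
# cases only. Returns the fit plus the pieces contrasts need.
fit_group_model <- function(outcome, group, covariates) {
  group <- factor(group)
  df <- data.frame(.y = outcome, .group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  cc <- stats::complete.cases(df)
  if (sum(!cc) > 0)
    message("listwise deletion: dropped ", sum(!cc), " incomplete case(s)")
  df <- df[cc, , drop = FALSE]
  if (any(table(droplevels(df$.group)) < 3))
    stop("need >= 3 complete cases per group")
  full <- lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("collinear model columns: ", paste(bad, collapse = ", "))
  }
  list(fit = full, data = df)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits `outcome ~ group + covariates` and tests the group block with a
#' partial F test; reports group means adjusted to the covariate means.
#' This is the standard reading of "ANOVA after controlling for age, sex
#' and education".
#'
#' @param outcome Numeric vector, one value per subject.
#' @param group Factor or character group labels.
#' @param covariates Data frame of covariates (e.g. age, sex, education);
#'   `NULL` for an unadjusted comparison. Incomplete cases are dropped
#'   listwise with a message.
#' @return List: `F`, `p`, `df`, `adjusted_means` (named by group), `fit`.
#' @export
adjusted_group_test <- function(outcome, group, covariates = NULL) {
  m <- fit_group_model(outcome, group, covariates)
  reduced <- lm(.y ~ . - .group, data = m$data)
  an <- stats::anova(reduced, m$fit)
  mm <- stats::model.matrix(m$fit)
  beta <- stats::coef(m$fit)
  grp_cols <- grepl("^\\.group", colnames(mm))
  x_base <- colMeans(mm)
  lev <- levels(droplevels(m$data$.group))
  adj <- vapply(lev, function(g) {
    x <- x_base
    x[grp_cols] <- 0
    gc <- paste0(".group", g)
    if (gc %in% colnames(mm)) x[gc] <- 1
    sum(x * beta)
  }, numeric(1))
  list(F = an$F[2], p = an$`Pr(>F)`[2],
       df = c(an$Df[2], an$Res.Df[2]),
       adjusted_means = adj, fit = m$fit)
}

#' Post hoc pairwise contrasts from the adjusted model
#'
#' Covariate-adjusted two-group contrasts computed from the same linear
#' model as [adjusted_group_test()]: for each pair of groups, the
#' difference of adjusted means, its t statistic on the residual degrees of
#' freedom, and a two-sided p value.
#'
#' @inheritParams adjusted_group_test
#' @return Data frame: `group1`, `group2`, `diff` (group1 - group2), `t`,
#'   `p`.
#' @export
posthoc_pairwise <- function(outcome, group, covariates = NULL) {
  m <- fit_group_model(outcome, group, covariates)
  beta <- stats::coef(m$fit)
  V <- stats::vcov(m$fit)
  mm <- stats::model.matrix(m$fit)
  lev <- levels(droplevels(m$data$.group))
  grp_vec <- function(g) {
    x <- setNames(numeric(length(beta)), names(beta))
    gc <- paste0(".group", g)
    if (gc %in% names(x)) x[gc] <- 1
    x
  }
  df_res <- stats::df.residual(m$fit)
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    cvec <- grp_vec(pr[1]) - grp_vec(pr[2])
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    c(diff = est, t = tval, p = 2 * pt(-abs(tval), df_res))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             diff = out["diff", ], t = out["t", ], p = out["p", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values; thresholding the result at `alpha` is
#' equivalent to the classical BH selection rule. Applied within one family
#' of tests (e.g. all nodes for one nodal metric).
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Brain-behavior partial correlation
#'
#' Partial correlation between a network metric (typically an AUC) and a
#' cognitive score controlling for covariates, computed as the correlation
#' of the two covariate-residualized variables, with a two-sided p value on
#' `n - 2 - k` degrees of freedom (`k` covariate model columns). Incomplete
#' cases are dropped listwise.
#'
#' @param metric Numeric vector (e.g. local-efficiency AUC per subject).
#' @param score Numeric vector of cognitive scores.
#' @param covariates Data frame of covariates or `NULL` (then the plain
#'   Pearson correlation).
#' @param min_n Minimum complete cases required (default 10).
#' @return List: `r` (partial correlation), `p`, `n` (complete cases).
#' @export
behavior_regression <- function(metric, score, covariates = NULL,
                                min_n = 10L) {
  df <- data.frame(.m = metric, .s = score)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)
  if (n < min_n)
    stop("only ", n, " complete cases; need at least ", min_n)
  if (!is.null(covariates)) {
    rm_ <- stats::resid(lm(.m ~ . - .s, data = df))
    rs_ <- stats::resid(lm(.s ~ . - .m, data = df))
    k <- ncol(stats::model.matrix(lm(.m ~ . - .s, data = df))) - 1L
  } else {
    rm_ <- df$.m
    rs_ <- df$.s
  }
  r <- cor(rm_, rs_)
  df_t <- n - 2L - k
  tval <- r * sqrt(df_t / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df_t), n = n)
}
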