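#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided test for categorical comparisons (protracted vs.
#' non-protracted, potent vs. non-potent): the p-value sums hypergeometric
#' probabilities, over all tables with the observed margins, of tables no
#' more probable than the observed one (the probability-mass two-sided
#' convention). A table with a zero margin carries no information; its p is
#' defined as 1 and flagged.
#'
#' @param table 2x2 matrix of non-negative counts (rows = groups,
#'   columns = outcome yes/no), or the count `a` with `b`, `c`, `d`.
#' @param b,c,d remaining cell counts when `table` is scalar `a`.
#' @return A list: `p_value`, `odds_ratio` (conditional MLE, `NA` when
#'   flagged), `flagged` (zero margin), `method`.
#' @export
fisher_exact <- function(table, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(table)) table else matrix(c(table, c, b, d), 2, 2)
  if (!all(dim(m) == 2L)) stopf("`table` must be 2x2")
  if (any(m < 0) || any(m != round(m))) stopf("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_, flagged = TRUE,
                method = "Fisher's exact test (degenerate margin)"))
  ft <- stats::fisher.test(m)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       flagged = FALSE, method = "Fisher's exact test (two-sided)")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups used when a metric is not Gaussian.
#' U is computed with midrank tie handling. The p-value is exact (full
#' enumeration of rank assignments) when the combined sample size is at most
#' 20 and there are no ties, and otherwise uses the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @return A list: `U`, `p_value`, `exact`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact,
       n_x = length(x), n_y = length(y),
       method = if (exact) "Mann-Whitney U (exact)"
       else "Mann-Whitney U (normal approximation, tie-corrected)")
}

#' One-way ANOVA with Tukey's post-test
#'
#' Compares the means of two or more groups when a metric is Gaussian;
#' pairwise differences are adjusted with Tukey's honestly-significant-
#' difference procedure (studentized-range quantiles). No correction is
#' applied beyond Tukey within the family.
#'
#' @param groups named list of numeric vectors, or a data frame with columns
#'   `group` and `value`.
#' @param alpha family-wise significance level for the Tukey decisions.
#' @return A list: `F`, `df`, `p_value`, `tukey` (data frame with `pair`,
#'   `diff`, `lwr`, `upr`, `p_adj`, `significant`), `flagged` (TRUE when the
#'   residual variance is zero and F is undefined).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups)))
      stopf("data frame input needs columns `group` and `value`")
    df <- data.frame(group = factor(groups$group), value = groups$value)
  } else {
    if (is.null(names(groups)) || any(names(groups) == ""))
      stopf("list input must be named by group")
    df <- data.frame(
      group = factor(rep(names(groups), lengths(groups)),
                     levels = names(groups)),
      value = unlist(groups, use.names = FALSE))
  }
  if (nlevels(df$group) < 2L) stopf("need at least 2 groups")
  if (nrow(df) <= nlevels(df$group))
    stopf("need more observations than groups")

  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  if (!is.finite(mse) || mse <= 1e-10 * max(1, mean(df$value)^2))
    return(list(F = NA_real_, df = unname(tab[, "Df"]), p_value = NA_real_,
                tukey = NULL, flagged = TRUE))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(F = tab["group", "F value"], df = unname(tab[, "Df"]),
       p_value = tab["group", "Pr(>F)"], tukey = tukey, flagged = FALSE)
}
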