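#' Levene's test for homogeneity of variance
#'
#' Classic Levene test: one-way ANOVA on the absolute deviations of each
#' observation from its group centre. The centre defaults to the group
#' mean (the original Levene statistic); `center = "median"` gives the
#' Brown-Forsythe variant, more robust to heavy tails. Used here to ask
#' whether short-minus-long copy differences are more variable across
#' samples in open-chromatin regions than in the closed pericentromeric
#' region.
#'
#' @param data Data frame in long format.
#' @param value,group Column names (tidy-eval) holding the values and the
#'   group labels; at least two groups, each non-empty.
#' @param center `"mean"` (classic Levene) or `"median"` (Brown-Forsythe).
#' @return A one-row tibble: `method`, `center`, `statistic` (F), `df1`,
#'   `df2`, `p_value`, and a `groups` list-column of per-group summaries
#'   (`n`, `mean`, `median`, `sd`).
#' @examples
#' df <- data.frame(v = c(rnorm(20), rnorm(20, sd = 3)),
#'                  g = rep(c("a", "b"), each = 20))
#' levene_test(df, v, g)
#' @export
levene_test <- function(data, value, group, center = c("mean", "median")) {
  center <- match.arg(center)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("Levene's test needs at least two groups.")
  if (any(tabulate(g) == 0)) abort("Every group must be non-empty.")

  centre_fun <- if (center == "mean") mean else median
  centres <- tapply(v, g, centre_fun)
  dev <- abs(v - centres[g])
  fit <- anova(lm(dev ~ g))
  summaries <- tibble(
    group = levels(g),
    n = as.integer(tabulate(g)),
    mean = as.numeric(tapply(v, g, mean)),
    median = as.numeric(tapply(v, g, median)),
    sd = as.numeric(tapply(v, g, sd))
  )
  tibble(
    method = "Levene's test (abs deviations, one-way ANOVA)",
    center = center,
    statistic = fit$`F value`[1],
    df1 = fit$Df[1],
    df2 = fit$Df[2],
    p_value = fit$`Pr(>F)`[1],
    groups = list(summaries)
  )
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum comparison of two samples, as used for
#' the short/long copy-ratio shift between cancer and healthy cohorts.
#' The exact null distribution is used for small samples
#' (both arms <= `exact_max_n`, no ties); otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y Numeric vectors.
#' @param exact_max_n Largest per-arm size for which the exact null is
#'   enumerated.
#' @return A one-row tibble: `statistic` (the Mann-Whitney U of `x`),
#'   `p_value`, `method`, `exact`, `n_x`, `n_y`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
rank_sum_test <- function(x, y, exact_max_n = 8) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && length(x) <= exact_max_n &&
    length(y) <= exact_max_n
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    method = "Wilcoxon rank-sum (two-sided)",
    exact = use_exact,
    n_x = length(x),
    n_y = length(y)
  )
}

#' Pearson correlation with confidence intervals
#'
#' Product-moment correlation `r` with a Fisher-z confidence interval, plus
#' the derived coefficient of determination `R^2` with an interval obtained
#' by squaring the `r` interval endpoints: when the `r` interval spans 0
#' the `R^2` lower bound is 0, otherwise the squared endpoints are sorted.
#' This is the statistic used to compare qPCR contamination scores with
#' electrophoresis molarity ratios.
#'
#' @param x,y Numeric vectors of equal length (n >= 3; n >= 4 for a CI).
#' @param level Confidence level.
#' @return A one-row tibble: `r`, `r_ci_low`, `r_ci_high`, `r_squared`,
#'   `r2_ci_low`, `r2_ci_high`, `p_value`, `n`.
#' @examples
#' pearson_with_ci(1:10, 2 * (1:10) + 1)
#' @export
pearson_with_ci <- function(x, y, level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  ht <- cor.test(x, y, method = "pearson", conf.level = level)
  r <- unname(ht$estimate)
  ci <- if (!is.null(ht$conf.int)) as.numeric(ht$conf.int) else c(NA, NA)
  if (abs(r) == 1) ci <- c(r, r)
  r2_ci <- if (anyNA(ci)) {
    c(NA_real_, NA_real_)
  } else if (ci[1] <= 0 && ci[2] >= 0) {
    c(0, max(ci^2))
  } else {
    sort(ci^2)
  }
  tibble(
    r = r,
    r_ci_low = ci[1],
    r_ci_high = ci[2],
    r_squared = r^2,
    r2_ci_low = r2_ci[1],
    r2_ci_high = r2_ci[2],
    p_value = ht$p.value,
    n = length(x)
  )
}
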