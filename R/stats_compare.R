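#' Compare a statistic across groups (one-way ANOVA or t-test)
#'
#' Thin, uniform wrapper over `stats::aov` / `stats::t.test` that returns
#' the fields the comparison report tabulates.  The t-test is the
#' two-sample pooled-variance (Student) test; for two groups the ANOVA F
#' equals its squared t.
#'
#' @param values numeric vector of observations.
#' @param groups vector of group labels, same length.
#' @param test `"anova"` or `"t_test"` (t-test requires exactly 2 groups).
#' @return Data frame (class `group_comparison`) with `test`, `statistic`,
#'   `df1`, `df2`, `p_value` and `n_groups`.
#' @export
compare_groups <- function(values, groups, test = c("anova", "t_test")) {
  test <- match.arg(test)
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  if (test == "anova") {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    out <- data.frame(test = "anova",
                      statistic = s[["F value"]][1],
                      df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                      p_value = s[["Pr(>F)"]][1],
                      n_groups = nlevels(groups))
  } else {
    if (nlevels(groups) != 2) stop("t_test requires exactly 2 groups")
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    out <- data.frame(test = "t_test",
                      statistic = unname(tt$statistic),
                      df1 = 1, df2 = unname(tt$parameter),
                      p_value = tt$p.value, n_groups = 2)
  }
  class(out) <- c("group_comparison", class(out))
  out
}

#' Kolmogorov-Smirnov check of normality
#'
#' KS test of the sample against a normal with the sample's mean and
#' standard deviation (parameters estimated from the data, so p-values are
#' conservative in the Lilliefors sense; used as a screening check before
#' ANOVA/t comparisons).
#'
#' @param values numeric vector, n >= 5, non-constant.
#' @return Data frame with `test = "ks_normality"`, `statistic` (D),
#'   `p_value`, `n`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stop("need at least 5 values")
  s <- stats::sd(values)
  if (s == 0) stop("constant vector: normality is undefined")
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s))
  data.frame(test = "ks_normality", statistic = unname(ks$statistic),
             p_value = ks$p.value, n = length(values))
}

#' Ordinary least-squares regression summary
#'
#' @param x,y numeric vectors (n >= 3); `x` must not be constant.
#' @return Data frame with `slope`, `intercept`, `r2`, `p_value` (slope
#'   test) and `n`.
#' @export
regress <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r2 = s$r.squared,
             p_value = s$coefficients[2, 4],
             n = length(x))
}

#' Paired z-test for observed versus expected index values
#'
#' Used for the observed-vs-expected RCDI comparison: a z statistic on the
#' per-family differences `observed - expected`, with a normal reference
#' (appropriate for the family counts involved).
#'
#' @param observed,expected paired numeric vectors.
#' @return Data frame with `test = "paired_z"`, `statistic` (z),
#'   `p_value` (two-sided), `mean_difference`, `n`.
#' @export
paired_z_test <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  d <- observed - expected
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0) stop("all differences identical")
  z <- mean(d) / (stats::sd(d) / sqrt(n))
  data.frame(test = "paired_z", statistic = z,
             p_value = 2 * stats::pnorm(-abs(z)),
             mean_difference = mean(d), n = n)
}
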