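# Cohort statistics: distribution-aware two-/multi-group comparisons,
# categorical tests, multivariable linear regression with a pairwise
# collinearity screen, and Bland-Altman method agreement. All tests are
# two-tailed. Test engines are the base stats functions; what this module
# adds is the selection logic and the reporting containers.

#' Choose the comparison test from distributional checks
#'
#' Each group is checked for normality with a Shapiro-Wilk test at
#' `alpha_norm` (0.05 by default). If every group passes: Welch t test for
#' two groups, one-way ANOVA for more; otherwise the rank-based
#' Mann-Whitney U (two groups) or Kruskal-Wallis test. A zero-variance
#' group is treated as failing the normality check (the Shapiro-Wilk
#' statistic is undefined there); groups larger than 5000 are subsampled
#' to 5000 for the check only.
#'
#' @param samples list of >= 2 numeric vectors, each of length >= 3.
#' @param alpha_norm significance level of the normality check.
#' @return One of `"t"`, `"anova"`, `"mann-whitney"`, `"kruskal"`.
#' @export
choose_test <- function(samples, alpha_norm = 0.05) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("'samples' must be a list of at least two groups")
  n <- vapply(samples, length, 1L)
  if (any(n < 3L)) stop("every group needs n >= 3")
  normal <- vapply(samples, function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
    stats::shapiro.test(x)$p.value >= alpha_norm
  }, TRUE)
  if (all(normal)) {
    if (length(samples) == 2L) "t" else "anova"
  } else {
    if (length(samples) == 2L) "mann-whitney" else "kruskal"
  }
}

#' Compare a continuous variable between groups
#'
#' Splits `variable` by `grouping`, selects the test with [choose_test()]
#' (or uses the one forced via `test`), runs it two-tailed and reports
#' per-group summaries in the test family's idiom: mean +/- SD for the
#' parametric tests, median (range) for the rank tests. When every group
#' is a constant and all constants are equal the comparison is degenerate
#' (no variance anywhere) and is reported as such with `p_value = NA`.
#'
#' @param cohort data frame (e.g. from [simulate_cohort()]).
#' @param variable name of the numeric column to compare.
#' @param grouping name of the grouping column (default `"group"`).
#' @param test `"auto"` or one of the four test names to force.
#' @param alpha_norm normality-check level for `"auto"`.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return An object of class `group_comparison`.
#' @export
compare_groups <- function(cohort, variable, grouping = "group",
                           test = c("auto", "t", "anova", "mann-whitney", "kruskal"),
                           alpha_norm = 0.05, var_equal = FALSE) {
  test <- match.arg(test)
  if (!variable %in% names(cohort)) stop("variable not found: ", variable)
  if (!grouping %in% names(cohort)) stop("grouping not found: ", grouping)
  keep <- !is.na(cohort[[variable]]) & !is.na(cohort[[grouping]])
  g <- droplevels(factor(cohort[[grouping]][keep]))
  x <- cohort[[variable]][keep]
  samples <- split(x, g)
  normal <- vapply(samples, function(v)
    stats::sd(v) > 0 && length(v) >= 3L &&
      stats::shapiro.test(if (length(v) > 5000L) v[seq(1L, length(v), length.out = 5000L)] else v)$p.value >= alpha_norm,
    TRUE)
  if (test == "auto") test <- choose_test(samples, alpha_norm)

  degenerate <- all(vapply(samples, stats::sd, 1.0) == 0) &&
    length(unique(unlist(samples))) == 1L
  if (degenerate && test %in% c("anova", "t")) {
    res <- list(statistic = NA_real_, p.value = NA_real_)
    note <- "degenerate: zero variance in every group"
  } else {
    note <- NA_character_
    res <- switch(test,
      "t" = stats::t.test(samples[[1]], samples[[2]], var.equal = var_equal),
      "mann-whitney" = suppressWarnings(
        stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE, correct = TRUE)),
      "anova" = {
        fit <- stats::aov(x ~ g)
        s <- summary(fit)[[1]]
        list(statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1])
      },
      "kruskal" = stats::kruskal.test(samples))
  }
  summaries <- data.frame(
    group = names(samples),
    n = vapply(samples, length, 1L),
    mean = vapply(samples, mean, 1.0),
    sd = vapply(samples, stats::sd, 1.0),
    median = vapply(samples, stats::median, 1.0),
    min = vapply(samples, min, 1.0),
    max = vapply(samples, max, 1.0),
    normal = normal,
    row.names = NULL)
  stat <- if (is.list(res) && !is.null(res$statistic)) unname(res$statistic) else NA_real_
  structure(
    list(test_name = test, statistic = stat,
         p_value = if (is.null(res$p.value)) NA_real_ else unname(res$p.value),
         variable = variable, summaries = summaries, note = note),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s: statistic %.4g, p = %.4g\n",
              x$variable, x$test_name, x$statistic, x$p_value))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  parametric <- x$test_name %in% c("t", "anova")
  for (i in seq_len(nrow(x$summaries))) {
    s <- x$summaries[i, ]
    if (parametric)
      cat(sprintf("  %-12s n=%3d  %.2f +/- %.2f\n", s$group, s$n, s$mean, s$sd))
    else
      cat(sprintf("  %-12s n=%3d  %.2f (%.2f - %.2f)\n", s$group, s$n,
                  s$median, s$min, s$max))
  }
  invisible(x)
}

#' Chi-square or Fisher exact test for a contingency table
#'
#' Fisher's exact test is used for a 2x2 table with any expected cell
#' count below 5; the (uncorrected) chi-square test otherwise.
#'
#' @param table matrix of non-negative integer counts.
#' @param correct apply the Yates continuity correction to chi-square 2x2.
#' @return List with `test`, `statistic`, `p_value`, `expected`.
#' @export
categorical_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (length(table) == 0 || sum(table) == 0) stop("empty table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  use_fisher <- all(dim(table) == 2L) && any(expected < 5)
  if (use_fisher) {
    res <- stats::fisher.test(table)
    list(test = "fisher", statistic = NA_real_, p_value = res$p.value,
         expected = expected)
  } else {
    res <- suppressWarnings(stats::chisq.test(table, correct = correct))
    list(test = "chi-square", statistic = unname(res$statistic),
         p_value = res$p.value, expected = expected)
  }
}

# numeric encoding for the collinearity screen: binary factors/logicals
# become 0/1, multi-level factors their integer codes
.screen_numeric <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  as.numeric(as.integer(factor(x)))
}

#' Multivariable linear regression with a collinearity screen
#'
#' Ordinary least squares of `outcome` on `predictors`, after a sequential
#' pairwise screen: predictors are considered in the order given; a
#' candidate whose absolute correlation with an already-included predictor
#' exceeds `collinearity_r` (Pearson for continuous pairs, point-biserial
#' via 0/1 coding for binary ones) is excluded and reported with the
#' offending pair. Constant predictors are excluded as degenerate. Rows
#' with missing values in the outcome or any candidate predictor are
#' dropped.
#'
#' @param cohort data frame.
#' @param outcome outcome column name (default `"scar_pct"`).
#' @param predictors character vector of candidate predictor columns.
#' @param collinearity_r exclusion threshold on |r| (default 0.7).
#' @return An object of class `regression_result`: `coefficients` table,
#'   `included`, `excluded` (with reasons), `n`, `r_squared`, `model`.
#' @export
fit_infarct_regression <- function(cohort, outcome = "scar_pct",
                                   predictors = c("indexed_itfv", "age", "sex",
                                                  "race", "bmi", "diabetes", "gfr"),
                                   collinearity_r = 0.7) {
  missing_cols <- setdiff(c(outcome, predictors), names(cohort))
  if (length(missing_cols)) stop("columns not found: ",
                                 paste(missing_cols, collapse = ", "))
  dat <- cohort[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  included <- character(0)
  excluded <- data.frame(predictor = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (p in predictors) {
    v <- .screen_numeric(dat[[p]])
    if (stats::sd(v) == 0) {
      excluded <- rbind(excluded, data.frame(predictor = p, reason = "constant"))
      next
    }
    clash <- NULL
    for (q in included) {
      r <- stats::cor(v, .screen_numeric(dat[[q]]))
      if (is.finite(r) && abs(r) > collinearity_r) { clash <- c(q, r); break }
    }
    if (is.null(clash)) included <- c(included, p)
    else excluded <- rbind(excluded, data.frame(
      predictor = p,
      reason = sprintf("collinear with %s (r = %.3f)", clash[1],
                       as.numeric(clash[2]))))
  }
  if (!length(included)) stop("no predictors left after the collinearity screen")
  if (nrow(dat) <= length(included) + 1L)
    stop("need n > number of predictors + 1")
  fml <- stats::reformulate(included, response = outcome)
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design after exclusions")
  ct <- summary(fit)$coefficients
  structure(
    list(outcome = outcome, included = included, excluded = excluded,
         coefficients = data.frame(term = rownames(ct),
                                   estimate = ct[, 1], std_error = ct[, 2],
                                   t_value = ct[, 3], p_value = ct[, 4],
                                   row.names = NULL),
         n = nrow(dat), r_squared = summary(fit)$r.squared, model = fit),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s ~ %s (n = %d, R^2 = %.3f)\n",
              x$outcome, paste(x$included, collapse = " + "), x$n, x$r_squared))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), std_error = signif(std_error, 3),
                  t_value = signif(t_value, 3), p_value = signif(p_value, 3)),
        row.names = FALSE)
  if (nrow(x$excluded)) {
    cat("  excluded:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("    %s  (%s)\n", x$excluded$predictor[i], x$excluded$reason[i]))
  }
  invisible(x)
}

#' Bland-Altman agreement between paired measurements
#'
#' Differences are `a - b` (first-listed measurement minus second). Bias
#' is their mean, `sd_diff` their SD (n-1 denominator), and the limits of
#' agreement are `bias +/- 1.96 * sd_diff`. The Pearson correlation of the
#' paired measurements is reported alongside.
#'
#' @param a,b numeric vectors of equal length >= 2 (pairs with missing
#'   values are dropped).
#' @return An object of class `agreement_result`: `bias`, `sd_diff`,
#'   `lower_limit`, `upper_limit`, `pearson_r`, `n_pairs`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  r <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b)
       else if (all(a == b)) 1.0 else NA_real_
  structure(
    list(bias = bias, sd_diff = sd_diff,
         lower_limit = bias - 1.96 * sd_diff,
         upper_limit = bias + 1.96 * sd_diff,
         pearson_r = r, n_pairs = length(a)),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> bias %.4g, limits of agreement (%.4g, %.4g), r = %.3f, n = %d\n",
              x$bias, x$lower_limit, x$upper_limit, x$pearson_r, x$n_pairs))
  invisible(x)
}
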