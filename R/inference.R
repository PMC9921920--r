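#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA: F = MS_between / MS_within with
#' (k - 1, N - k) degrees of freedom and an exact p-value from the F
#' distribution.
#'
#' @param values Numeric outcome vector.
#' @param group_labels Grouping vector (coerced to factor), at least two
#'   groups with at least two observations each.
#' @return Object of class \code{anova_report}: list with \code{F},
#'   \code{p}, \code{df}, \code{group_means}, \code{group_sds},
#'   \code{group_n} and the underlying \code{aov} fit.
#' @export
one_way_anova <- function(values, group_labels) {
  g <- factor(group_labels)
  ok <- !is.na(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (any(table(g) < 2)) stop("every group needs at least two observations")
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  structure(list(
    F = tab[["F value"]][1],
    p = tab[["Pr(>F)"]][1],
    df = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
    group_means = tapply(values, g, mean),
    group_sds = tapply(values, g, stats::sd),
    group_n = as.vector(table(g)),
    fit = fit
  ), class = "anova_report")
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' Studentized-range pairwise comparisons with family-wise adjustment;
#' unequal group sizes are handled by the Tukey-Kramer form.
#'
#' @param report An \code{anova_report} from \code{one_way_anova()} with
#'   at least three groups.
#' @return Data.frame with one row per pair: \code{pair}, \code{diff},
#'   \code{lwr}, \code{upr}, \code{p_adj}.
#' @export
tukey_hsd <- function(report) {
  stopifnot(inherits(report, "anova_report"))
  k <- length(report$group_means)
  if (k < 3) {
    stop("Tukey HSD needs at least 3 groups; with 2 groups use a t-test")
  }
  tk <- stats::TukeyHSD(report$fit)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL)
}

#' Distribution-free confidence interval for a median
#'
#' Order-statistic interval from the binomial distribution: the largest
#' rank r with P(X < r) <= alpha/2 for X ~ Binomial(n, 1/2) gives the
#' interval (x_(r), x_(n+1-r)) with coverage at least the requested
#' level.
#'
#' @param x Numeric vector, n >= 6.
#' @param level Confidence level (default 0.95).
#' @return List with \code{lower}, \code{upper}, \code{median} and the
#'   achieved \code{coverage}.
#' @export
median_ci <- function(x, level = 0.95) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 6) stop("at least 6 observations are required")
  alpha <- 1 - level
  r <- stats::qbinom(alpha / 2, n, 0.5)
  # qbinom gives smallest q with P(X <= q) >= alpha/2; step down until
  # P(X <= r - 1) <= alpha/2 holds
  while (r > 0 && stats::pbinom(r - 1, n, 0.5) > alpha / 2) r <- r - 1
  if (r < 1) {
    achievable <- 1 - 2 * stats::pbinom(0, n, 0.5)
    stop(sprintf(
      "n = %d cannot support level %.3f; achievable coverage %.4f",
      n, level, achievable))
  }
  coverage <- 1 - 2 * stats::pbinom(r - 1, n, 0.5)
  list(lower = x[r], upper = x[n + 1 - r], median = stats::median(x),
       coverage = coverage)
}

#' Self-report agreement regression
#'
#' Tests whether self-reported and measured records follow the same
#' body-fat-on-weight regression line, with a single dummy-coded model
#' bfp = b0 + b1 weight + b2 source + b3 (weight x source):
#' \code{intercept_diff_p} tests b2 = 0 (no vertical shift between the
#' lines) and \code{slope_diff_p} tests b3 = 0 (the recording method does
#' not change the weight-fat relationship). Apply per sex by calling once
#' per group.
#'
#' @param bfp Body-fat percentages (both sources stacked).
#' @param weight Body weights (kg), same length.
#' @param source_labels Vector with values \code{"self_report"} and
#'   \code{"measured"}; at least 3 points per source.
#' @return Object of class \code{agreement_report}: list with
#'   \code{intercept_diff_p}, \code{slope_diff_p} and \code{coefficients}
#'   per source.
#' @export
agreement_regression <- function(bfp, weight, source_labels) {
  src <- factor(source_labels, levels = c("self_report", "measured"))
  if (anyNA(src)) {
    stop("source labels must be 'self_report' or 'measured'")
  }
  if (any(table(src) < 3)) stop("at least 3 points per source are required")
  if (stats::sd(weight) == 0) stop("constant weight: singular design")
  # center the covariate so the source contrast measures the vertical
  # shift at the mean weight rather than an extrapolation to weight 0
  wc <- weight - mean(weight)
  fit <- stats::lm(bfp ~ wc * src)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 4 || anyNA(stats::coef(fit))) {
    stop("singular design: could not estimate all terms")
  }
  co <- stats::coef(fit)
  b0 <- unname(co[1] - co[2] * mean(weight))          # original scale
  b0m <- unname(co[1] + co[3] - (co[2] + co[4]) * mean(weight))
  structure(list(
    intercept_diff_p = cf["srcmeasured", "Pr(>|t|)"],
    slope_diff_p = cf["wc:srcmeasured", "Pr(>|t|)"],
    coefficients = list(
      self_report = c(intercept = b0, slope = unname(co[2])),
      measured = c(intercept = b0m, slope = unname(co[2] + co[4]))
    ),
    fit = fit
  ), class = "agreement_report")
}

#' Two-group descriptive comparison with automatic test dispatch
#'
#' Dispatches to the Student t-test (equal variances by default), the
#' Mann-Whitney U test, or the chi-square test according to
#' \code{variable_kind}. When the kind is unspecified, normality of each
#' group is pre-assessed with the Shapiro-Wilk test (alpha = 0.05) and
#' the t-test is used only if neither group rejects.
#'
#' @param x,y The two groups: numeric vectors for continuous kinds, or
#'   for \code{"categorical"} a contingency table/matrix passed as
#'   \code{x} (with \code{y} omitted).
#' @param variable_kind \code{"normal"}, \code{"nonnormal"},
#'   \code{"categorical"}, or \code{NULL} to decide by Shapiro-Wilk.
#' @param welch Use the Welch correction in the t-test branch (default
#'   FALSE).
#' @param correct Continuity correction in the chi-square branch
#'   (default FALSE).
#' @return List with \code{test} (name), \code{statistic} and \code{p}.
#' @export
descriptive_compare <- function(x, y = NULL, variable_kind = NULL,
                                welch = FALSE, correct = FALSE) {
  if (!is.null(variable_kind) && variable_kind == "categorical") {
    ct <- stats::chisq.test(as.matrix(x), correct = correct)
    return(list(test = "chi-square", statistic = unname(ct$statistic),
                p = ct$p.value))
  }
  if (is.null(x) || is.null(y) || length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty")
  }
  if (is.null(variable_kind)) {
    norm <- function(v) length(unique(v)) > 2 &&
      stats::shapiro.test(v)$p.value > 0.05
    variable_kind <- if (norm(x) && norm(y)) "normal" else "nonnormal"
  }
  if (variable_kind == "normal") {
    tt <- stats::t.test(x, y, var.equal = !welch)
    list(test = if (welch) "Welch t" else "Student t",
         statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    list(test = "Mann-Whitney U", statistic = unname(wt$statistic),
         p = wt$p.value)
  }
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p))
  means <- sprintf("%s: %.2f (sd %.2f, n %d)", names(x$group_means),
                   x$group_means, x$group_sds, x$group_n)
  cat("  groups:", paste(means, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Self-report agreement regression\n")
  cat(sprintf("  intercept shift: p = %.4g\n", x$intercept_diff_p))
  cat(sprintf("  slope change:    p = %.4g\n", x$slope_diff_p))
  invisible(x)
}
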