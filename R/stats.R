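#' Two-sample t test (Welch by default)
#'
#' Compares two groups of per-sample measurements (e.g. crescent
#' incidences per participant). Defaults to the unequal-variance Welch
#' test with Satterthwaite degrees of freedom; `pooled = TRUE` gives the
#' classical equal-variance test for sensitivity checks. Significance is
#' declared at `p <= 0.05`. When both groups have zero variance and equal
#' means the test is degenerate and `t = 0, p = 1` by convention.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @param labels length-2 character vector of group labels.
#' @param pooled use the pooled-variance test instead of Welch.
#' @return list of class `GroupComparison`: `labels`, `n`, `means`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `significant`.
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 3, 4))$t_statistic  # -1.2247
#' @export
welchTTest <- function(a, b, labels = c("a", "b"), pooled = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = length(a) + length(b) - 2, p = 1)
    } else stop("zero variance in both groups with unequal means")
  } else {
    ht <- stats::t.test(a, b, var.equal = pooled)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(list(
    labels = labels,
    n = c(length(a), length(b)),
    means = c(mean(a), mean(b)),
    t_statistic = res$t,
    degrees_of_freedom = res$df,
    p_value = res$p,
    significant = res$p <= 0.05
  ), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g)\n",
              x$labels[1], x$n[1], x$means[1],
              x$labels[2], x$n[2], x$means[2]))
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g%s\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Five-number boxplot summaries with sqrt-n widths
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile(type = 7)`; the convention is fixed and documented),
#' whiskers extend to the minimum and maximum, and box widths are
#' proportional to the square root of the group size, normalized to the
#' largest group.
#'
#' @param groups named list of non-empty numeric vectors.
#' @return data.frame with one row per group: `group, n, min, q1, median,
#'   q3, max, box_width`.
#' @examples
#' boxplotSummary(list(a = 1:5))
#' @export
boxplotSummary <- function(groups) {
  if (!length(groups)) stop("no groups given")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns == 0)) stop("empty group: ",
                         paste(names(groups)[ns == 0], collapse = ", "))
  q <- t(vapply(groups, function(v)
    stats::quantile(as.numeric(v), c(0, 0.25, 0.5, 0.75, 1), type = 7,
                    names = FALSE), numeric(5)))
  data.frame(group = names(groups), n = as.integer(ns),
             min = q[, 1], q1 = q[, 2], median = q[, 3], q3 = q[, 4],
             max = q[, 5],
             box_width = sqrt(ns) / sqrt(max(ns)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression with `r_squared` equal to the squared Pearson
#' correlation and a two-sided p value from the slope's t statistic on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @return list of class `RegressionFit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @examples
#' linearFit(0:2, c(0, 1, 4))$slope  # 2
#' @export
linearFit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  n <- length(x)
  slope <- unname(stats::coef(fit)[2])
  # slope t test computed directly: summary.lm warns on perfect fits
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2) / sxx)
  p <- if (se == 0) {
    if (slope == 0) NA_real_ else 0
  } else 2 * stats::pt(-abs(slope / se), n - 2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (stats::var(y) == 0) NA_real_
                else stats::cor(x, y)^2,
    p_value = p,
    n = n
  ), class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g  (R2 = %.3f, p = %.4g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Pairwise group comparisons of summary measures
#'
#' Runs [welchTTest()] on every pair of group levels for each measure
#' column, as applied to a batch summary table.
#'
#' @param data data.frame (e.g. the `summaries` from [batchProcess()]).
#' @param group name of the grouping column.
#' @param measures character vector of numeric measure columns.
#' @param pooled use pooled-variance tests.
#' @return data.frame with one row per measure and group pair.
#' @export
compareGroups <- function(data, group,
                          measures = c("pct_globules_with_crescents",
                                       "cellular_rna_pct"),
                          pooled = FALSE) {
  if (!group %in% names(data)) stop("no such grouping column: ", group)
  measures <- intersect(measures, names(data))
  if (!length(measures)) stop("none of the measure columns are present")
  lev <- unique(as.character(data[[group]]))
  if (length(lev) < 2) stop("need at least two group levels")
  rows <- list()
  for (m in measures) {
    for (i in seq_len(length(lev) - 1)) {
      for (j in seq(i + 1, length(lev))) {
        va <- data[[m]][data[[group]] == lev[i]]
        vb <- data[[m]][data[[group]] == lev[j]]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (length(va) < 2 || length(vb) < 2) next
        ht <- welchTTest(va, vb, labels = c(lev[i], lev[j]),
                         pooled = pooled)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, group_a = lev[i], group_b = lev[j],
          n_a = ht$n[1], n_b = ht$n[2],
          mean_a = ht$means[1], mean_b = ht$means[2],
          t_statistic = ht$t_statistic,
          degrees_of_freedom = ht$degrees_of_freedom,
          p_value = ht$p_value, significant = ht$significant,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no comparable group pairs (need n >= 2 per group)")
  do.call(rbind, c(rows, make.row.names = FALSE))
}
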