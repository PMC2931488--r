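#' Pooled two-sample t test from summary statistics
#'
#' Classic equal-variance Student's t computed from group sizes, means and
#' SDs, so that comparisons can be run directly on published summary tables:
#' pooled variance `((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / (s_p sqrt(1/n1 + 1/n2))`, two-sided p from the t
#' distribution with `n1 + n2 - 2` degrees of freedom.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group SDs (>= 0).
#' @param metric Label carried into the result.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `group_comparison`: list with `metric`,
#'   `groups` (data.frame n/mean/sd), `t_statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
#' @examples
#' pooled_t_summary(10, 9.8, 2.5, 9, 2.7, 1.7, metric = "gpc")
pooled_t_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                             metric = "metric", alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean1 - mean2
  if (se == 0) {
    tt <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    tt <- diff / se
    p <- 2 * stats::pt(-abs(tt), df)
  }
  structure(
    list(metric = metric,
         groups = data.frame(n = c(n1, n2), mean = c(mean1, mean2),
                             sd = c(sd1, sd2)),
         t_statistic = tt, df = df, p_value = p,
         significant = is.finite(p) && p < alpha, alpha = alpha),
    class = "group_comparison"
  )
}

#' Pooled two-sample t test on raw values
#'
#' @param group_a,group_b Numeric vectors of per-sample values (each
#'   n >= 2).
#' @inheritParams pooled_t_summary
#' @return A `group_comparison`; see [pooled_t_summary()].
#' @export
pooled_t_test <- function(group_a, group_b, metric = "metric",
                          alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  pooled_t_summary(length(group_a), mean(group_a), stats::sd(group_a),
                   length(group_b), mean(group_b), stats::sd(group_b),
                   metric = metric, alpha = alpha)
}

#' @export
print.group_comparison <- function(x, ...) {
  g <- x$groups
  cat(sprintf("%s: %.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d)\n",
              x$metric, g$mean[1], g$sd[1], g$n[1], g$mean[2], g$sd[2],
              g$n[2]))
  cat(sprintf("  t = %.3f, df = %d, p = %.4g%s\n", x$t_statistic, x$df,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Compare all metabolites between two groups of a quantification table
#'
#' Runs [pooled_t_test()] per metabolite column on a long-format
#' quantification table (one row per sample), as produced by
#' [run_metabolite_pipeline()].  No multiple-testing correction is applied
#' across the metabolites.
#'
#' @param quant data.frame with a `group` column and one numeric column per
#'   metabolite.
#' @param metabolites Column names to compare; defaults to the numeric
#'   columns other than `mass`.
#' @param alpha Significance level.
#' @return data.frame with one row per metabolite: group means/SDs, t, df,
#'   p, significance flag.
#' @export
compare_metabolites <- function(quant, metabolites = NULL, alpha = 0.05) {
  if (is.null(quant$group)) stop("'quant' needs a 'group' column", call. = FALSE)
  groups <- unique(quant$group)
  if (length(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  if (is.null(metabolites)) {
    num <- vapply(quant, is.numeric, logical(1))
    metabolites <- setdiff(names(quant)[num], c("mass", "r_squared"))
  }
  rows <- lapply(metabolites, function(m) {
    a <- quant[[m]][quant$group == groups[1]]
    b <- quant[[m]][quant$group == groups[2]]
    cmp <- pooled_t_test(a[!is.na(a)], b[!is.na(b)], metric = m,
                         alpha = alpha)
    data.frame(metric = m,
               n1 = cmp$groups$n[1], mean1 = cmp$groups$mean[1],
               sd1 = cmp$groups$sd[1],
               n2 = cmp$groups$n[2], mean2 = cmp$groups$mean[2],
               sd2 = cmp$groups$sd[2],
               t = cmp$t_statistic, df = cmp$df, p = cmp$p_value,
               significant = cmp$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}
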