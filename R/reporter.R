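# Reporter-assay analytics: RFP-normalized GFP intensities, one-way ANOVA
# with Dunnett many-to-one comparisons against a control construct (the
# family-wise procedure used to compare CRM variants), and the pooled
# two-sample t-test used for single wild-type-versus-mutant contrasts.

#' Normalize reporter fluorescence
#'
#' Adds `normalized = gfp_mean / rfp_mean` per record (the transfection
#' control channel divides out electroporation efficiency).
#'
#' @param records Tibble with `gfp_mean` (>= 0) and `rfp_mean` (> 0).
#' @return `records` with a `normalized` column.
#' @export
normalize_fluorescence <- function(records) {
  if (any(records$rfp_mean <= 0)) abort("rfp_mean must be > 0 for every record")
  if (any(records$gfp_mean < 0)) abort("gfp_mean must be >= 0")
  dplyr::mutate(records, normalized = .data$gfp_mean / .data$rfp_mean)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits the omnibus one-way ANOVA and compares every non-control group
#' against the control with single-step Dunnett adjustment: the adjusted
#' p-value of comparison i is `P(max_j |T_j| >= |t_i|)` under the
#' equicorrelated multivariate-t null with `N - k` degrees of freedom and
#' correlations `sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))`, evaluated
#' analytically with [mvtnorm::pmvt()] (or by Monte-Carlo when
#' `n_mc > 0`).
#'
#' @param data Tibble with a grouping column and a response column.
#' @param control Control group label.
#' @param alpha Family-wise significance level (default 0.05).
#' @param value,group Column names of response and group.
#' @param n_mc If > 0, draw this many Monte-Carlo samples of
#'   `max_j |T_j|` instead of the analytic integral (useful cross-check;
#'   seed-dependent).
#' @return An object of class `dunnett_fit`; see [tidy.dunnett_fit()] and
#'   [glance.dunnett_fit()].
#' @export
anova_dunnett <- function(data, control, alpha = 0.05,
                          value = "normalized", group = "group", n_mc = 0L) {
  vals <- data[[value]]
  grp <- as.character(data[[group]])
  if (is.null(vals) || is.null(grp)) abort("value/group column not found")
  if (!control %in% grp) abort(sprintf("control group '%s' not present", control))
  g <- split(vals, grp)
  if (length(g) < 2L) abort("need at least two groups")
  ns <- lengths(g)
  if (any(ns < 2L)) {
    abort(sprintf("group '%s' has fewer than 2 observations", names(g)[ns < 2][1]))
  }
  others <- setdiff(names(g), control)
  N <- sum(ns)
  k <- length(g)
  means <- vapply(g, mean, double(1))
  ss_within <- sum(vapply(g, function(x) sum((x - mean(x))^2), double(1)))
  df2 <- N - k
  mse <- ss_within / df2

  if (mse == 0) {
    if (max(means) - min(means) > 0) {
      abort("zero within-group variance with differing means: degenerate input")
    }
    comparisons <- tibble(
      group = others, estimate = 0, t = 0, p_unadjusted = 1, p_adjusted = 1,
      significant = FALSE
    )
    fit <- list(
      comparisons = comparisons,
      anova = list(statistic = 0, df1 = k - 1L, df2 = df2, p_value = 1),
      control = control, alpha = alpha, n = ns, method = "degenerate"
    )
    return(structure(fit, class = "dunnett_fit"))
  }

  grand <- mean(vals)
  ss_between <- sum(ns * (means - grand)^2)
  f_stat <- (ss_between / (k - 1)) / mse
  f_p <- stats::pf(f_stat, k - 1, df2, lower.tail = FALSE)

  n0 <- ns[[control]]
  ni <- ns[others]
  t_i <- (means[others] - means[[control]]) / sqrt(mse * (1 / ni + 1 / n0))
  lam <- sqrt(ni / (ni + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  p_unadj <- 2 * pt(-abs(t_i), df2)
  if (n_mc > 0L) {
    Z <- mvtnorm::rmvnorm(n_mc, sigma = R)
    S <- sqrt(stats::rchisq(n_mc, df2) / df2)
    maxT <- apply(abs(Z / S), 1, max)
    p_adj <- vapply(abs(t_i), function(tt) mean(maxT >= tt), double(1))
    method <- sprintf("monte-carlo (%d draws)", n_mc)
  } else {
    p_adj <- vapply(abs(t_i), function(tt) {
      1 - mvtnorm::pmvt(
        lower = rep(-tt, length(others)), upper = rep(tt, length(others)),
        df = df2, corr = R
      )[1]
    }, double(1))
    method <- "multivariate-t"
  }
  p_adj <- pmin(1, pmax(p_adj, p_unadj))
  comparisons <- tibble(
    group = others,
    estimate = unname(means[others] - means[[control]]),
    t = unname(t_i),
    p_unadjusted = unname(p_unadj),
    p_adjusted = unname(p_adj),
    significant = unname(p_adj < alpha)
  )
  structure(
    list(
      comparisons = comparisons,
      anova = list(statistic = f_stat, df1 = k - 1L, df2 = df2, p_value = f_p),
      control = control, alpha = alpha, n = ns, method = method,
      data = tibble(group = grp, value = vals)
    ),
    class = "dunnett_fit"
  )
}

#' @export
print.dunnett_fit <- function(x, ...) {
  cat(sprintf(
    "<dunnett_fit> F(%d, %d) = %.3f, p = %.3g; control '%s', alpha %.2f (%s)\n",
    x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p_value,
    x$control, x$alpha, x$method
  ))
  print(x$comparisons)
  invisible(x)
}

#' Tidy a Dunnett fit: one row per comparison
#'
#' @param x A `dunnett_fit`.
#' @param ... Unused.
#' @return Tibble with `group`, `estimate` (mean difference vs control),
#'   `t`, `p_unadjusted`, `p_adjusted`, `significant`.
#' @export
tidy.dunnett_fit <- function(x, ...) x$comparisons

#' Glance at a Dunnett fit: the omnibus ANOVA
#'
#' @param x A `dunnett_fit`.
#' @param ... Unused.
#' @return One-row tibble with `statistic` (F), `df1`, `df2`, `p_value`,
#'   `alpha`, `control`.
#' @export
glance.dunnett_fit <- function(x, ...) {
  tibble(
    statistic = x$anova$statistic, df1 = x$anova$df1, df2 = x$anova$df2,
    p_value = x$anova$p_value, alpha = x$alpha, control = x$control
  )
}

#' Pooled-variance two-sample t-test
#'
#' The two-tailed Student's t used for single wild-type-versus-mutant
#' reporter contrasts.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param two_tailed Two-tailed p (default) or one-tailed.
#' @return One-row tibble with `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(a, b, two_tailed = TRUE) {
  if (length(a) < 2L || length(b) < 2L) abort("each sample needs n >= 2")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2L, p_value = 1))
    }
    abort("zero pooled variance: degenerate input")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE,
                      alternative = if (two_tailed) "two.sided" else "greater")
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Per-group box-plot summary of normalized intensities
#'
#' Median, interquartile range and range per construct — the numbers behind
#' the box-and-whisker presentation of reporter data.
#'
#' @param records Normalized records (see [normalize_fluorescence()]).
#' @param value,group Column names.
#' @return Tibble with one row per group.
#' @export
summarize_groups <- function(records, value = "normalized", group = "group") {
  records |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data[[value]]),
      q1 = stats::quantile(.data[[value]], 0.25)[[1]],
      q3 = stats::quantile(.data[[value]], 0.75)[[1]],
      min = min(.data[[value]]),
      max = max(.data[[value]]),
      .groups = "drop"
    )
}
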