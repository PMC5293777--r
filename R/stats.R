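# The statistical battery: baseline IOP averaging, percent change, one-sided
# t test against a hypothesized value (a unity ratio), normality-gated
# two-group comparison with Mann-Whitney fallback, one-way ANOVA with
# Holm-Sidak pairwise comparisons, and the IOP elevation summary table.
# All group summaries are mean +/- SEM.

#' @keywords internal
#' @noRd
test_result <- function(test_name, statistic, p_value, n, normality_pass = NA,
                        route = test_name, ...) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_value = unname(p_value), n = n, normality_pass = normality_pass,
         route = route, ...),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p = %.4g (n = %s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Baseline IOP from pre-injection readings
#'
#' Pre-injection readings (days <= 0, day 0 being the injection day) are
#' averaged per animal and eye. A warning is raised when the number of
#' pre-injection days falls outside the conventional 2-3.
#'
#' @param records Data.frame with columns `animal_id`, `eye`, `day`,
#'   `iop_mmHg` (as from [generate_iop_series()]).
#' @return Data.frame `animal_id`, `eye`, `baseline_iop_mmHg`, `n_days`.
#' @examples
#' rec <- data.frame(animal_id = "A1", eye = "SALINE", day = -2:0,
#'                   iop_mmHg = c(19, 20, 21))
#' baseline_iop(rec)$baseline_iop_mmHg # 20
#' @export
baseline_iop <- function(records) {
  pre <- records[records$day <= 0, , drop = FALSE]
  if (nrow(pre) == 0) stopf("no pre-injection (day <= 0) records")
  out <- stats::aggregate(iop_mmHg ~ animal_id + eye, pre, mean)
  names(out)[names(out) == "iop_mmHg"] <- "baseline_iop_mmHg"
  nd <- stats::aggregate(day ~ animal_id + eye, pre,
                         function(d) length(unique(d)))
  out$n_days <- nd$day[match(paste(out$animal_id, out$eye),
                             paste(nd$animal_id, nd$eye))]
  if (any(out$n_days < 2 | out$n_days > 3)) {
    warnf("pre-injection day count outside the expected 2-3 for %d eye(s)",
          sum(out$n_days < 2 | out$n_days > 3))
  }
  out
}

#' Signed percent change between two means
#'
#' `100 * (comparison - reference) / reference`.
#'
#' @param reference_mean Reference (non-zero).
#' @param comparison_mean Comparison value.
#' @return Signed percent change (unrounded; see [format_percent_change()]
#'   for reporting precision).
#' @examples
#' percent_change(20.12, 26.69) # +32.7 after 1-decimal rounding
#' @export
percent_change <- function(reference_mean, comparison_mean) {
  if (any(reference_mean == 0)) stopf("reference mean must be non-zero")
  100 * (comparison_mean - reference_mean) / reference_mean
}

#' Round a percent change to reporting precision
#'
#' IOP percent changes are conventionally reported to one decimal; marker
#' ratio changes to the nearest integer.
#'
#' @param x Signed percent change.
#' @param kind `"iop"` (1 decimal) or `"ratio"` (integer).
#' @return Rounded value.
#' @export
format_percent_change <- function(x, kind = c("iop", "ratio")) {
  kind <- match.arg(kind)
  round(x, if (kind == "iop") 1 else 0)
}

#' One-sided t test of a sample mean against a hypothesized value
#'
#' Used to test group ratios against the expected microbead:saline ratio of
#' unity. `alternative = "auto"` (default) takes the one-sided direction from
#' the observed side of the hypothesized value, which matches per-panel usage
#' where the direction of departure is evident; for null-calibration work a
#' fixed direction should be supplied (the auto rule doubles the null
#' rejection rate by construction).
#'
#' @param ratios Numeric sample (n >= 2).
#' @param value Hypothesized mean (default 1, the unity ratio).
#' @param alternative `"auto"`, `"greater"`, `"less"` or `"two.sided"`.
#' @return A `test_result` (`test_name = "t_one_sided_vs_value"` unless
#'   two-sided); zero variance with mean != value yields p = 0 with a
#'   `degenerate` flag.
#' @examples
#' test_vs_unity(c(2.0, 2.1, 1.9))$p_value # < 0.05
#' @export
test_vs_unity <- function(ratios, value = 1,
                          alternative = c("auto", "greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- ratios[!is.na(ratios)]
  n <- length(x)
  if (n < 2) stopf("need n >= 2 ratios for a t test against a value")
  m <- mean(x)
  s <- stats::sd(x)
  if (alternative == "auto") {
    alternative <- if (m >= value) "greater" else "less"
  }
  if (s == 0) {
    if (m == value) {
      return(test_result("t_one_sided_vs_value", 0, 0.5, n, degenerate = FALSE))
    }
    return(test_result("t_one_sided_vs_value",
                       statistic = sign(m - value) * Inf, p_value = 0, n = n,
                       degenerate = TRUE))
  }
  t <- (m - value) / (s / sqrt(n))
  p <- switch(alternative,
              greater = stats::pt(t, n - 1, lower.tail = FALSE),
              less = stats::pt(t, n - 1),
              two.sided = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE))
  test_result(if (alternative == "two.sided") "t_two_sided" else "t_one_sided_vs_value",
              t, p, n, degenerate = FALSE, alternative = alternative)
}

#' Normality-gated two-group comparison
#'
#' Each sample is screened with the Shapiro-Wilk test at `alpha`; if both
#' pass, a two-sided t test is used (pooled variance, or paired when
#' `paired = TRUE`, screening the differences); otherwise the Mann-Whitney
#' rank-sum test (Wilcoxon signed-rank when paired). The route taken is
#' recorded on the result.
#'
#' @param a,b Numeric samples (n >= 3 each for the normality gate).
#' @param paired Paired comparison?
#' @param alpha Shapiro-Wilk gate level.
#' @return A `test_result` with `route` `"t_two_sided"` or `"mann_whitney"`,
#'   `normality_pass`, and `shapiro_p`.
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stopf("normality gate (Shapiro-Wilk) needs n >= 3 per group")
  }
  sw <- if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) list(p.value = 1) else stats::shapiro.test(d)
  } else NULL
  if (paired) {
    sw_p <- sw$p.value
    normal <- sw_p > alpha
  } else {
    p_a <- if (stats::sd(a) == 0) 1 else stats::shapiro.test(a)$p.value
    p_b <- if (stats::sd(b) == 0) 1 else stats::shapiro.test(b)$p.value
    sw_p <- c(a = p_a, b = p_b)
    normal <- all(sw_p > alpha)
  }
  if (normal) {
    if (!paired && stats::sd(c(a, b)) == 0) {
      res <- list(statistic = 0, p.value = 1)
    } else {
      res <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
    }
    test_result("t_two_sided", res$statistic, res$p.value,
                n = c(length(a), length(b)), normality_pass = TRUE,
                route = "t_two_sided", shapiro_p = sw_p)
  } else {
    res <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                               exact = FALSE, correct = TRUE))
    test_result("mann_whitney", res$statistic, res$p.value,
                n = c(length(a), length(b)), normality_pass = FALSE,
                route = "mann_whitney", shapiro_p = sw_p)
  }
}

#' Holm-Sidak step-down adjustment of raw p-values
#'
#' Ordered raw p-values receive `1 - (1 - p_i)^(m - i + 1)`, with cumulative
#' maxima enforcing monotonicity.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way ANOVA followed by Holm-Sidak pairwise comparisons
#'
#' The omnibus F test uses the classical equal-variance one-way layout;
#' pairwise t statistics share the ANOVA residual mean square, and their
#' two-sided p-values are Holm-Sidak adjusted.
#'
#' @param groups Named list of >= 3 numeric samples (each n >= 2).
#' @return A list with `anova` (a `test_result`) and `pairwise` (data.frame:
#'   `group1`, `group2`, `t`, `p_raw`, `p_adjusted`).
#' @export
anova_holm_sidak <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    stopf("need >= 3 groups; use compare_groups() for two")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2)) stopf("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::lm(y ~ g)
  av <- stats::anova(fit)
  mse <- av$`Mean Sq`[2]
  df <- av$Df[2]
  omnibus <- test_result("anova", av$`F value`[1], av$`Pr(>F)`[1],
                         n = lengths(groups))
  combs <- utils::combn(names(groups), 2)
  means <- vapply(groups, mean, 0)
  ns <- lengths(groups)
  t_stat <- p_raw <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    se <- sqrt(mse * (1 / ns[g1] + 1 / ns[g2]))
    t_stat[i] <- (means[g1] - means[g2]) / se
    p_raw[i] <- 2 * stats::pt(abs(t_stat[i]), df, lower.tail = FALSE)
  }
  pairwise <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                         t = t_stat, p_raw = p_raw,
                         p_adjusted = holm_sidak_adjust(p_raw))
  list(anova = omnibus, pairwise = pairwise)
}

#' Observed power of a two-sample t comparison
#'
#' Post-hoc power at the observed effect size, reported for parity with
#' legacy statistical software output; never used for gating inference.
#'
#' @param a,b Numeric samples.
#' @param alpha Test level.
#' @return Observed power in `[0, 1]`.
#' @export
observed_power <- function(a, b, alpha = 0.05) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
  if (sp == 0) return(1)
  d <- abs(mean(a) - mean(b)) / sp
  res <- stats::power.t.test(n = (n1 + n2) / 2, delta = d, sd = 1,
                             sig.level = alpha)
  unname(res$power)
}

#' Per-group IOP elevation summary
#'
#' Post-injection readings (day >= 1) are averaged per animal and eye, then
#' summarized per group and eye as mean +/- SEM, with the percent elevation
#' of the microbead over the saline eye. Animals missing one eye are flagged
#' and dropped; a single-animal group reports SEM as `NA` with a flag.
#'
#' @param records Data.frame `animal_id`, `eye`, `day`, `iop_mmHg`, and
#'   optionally `group`.
#' @return A list with `per_animal` (animal x eye means), `per_group`
#'   (group x eye mean, SEM, n), and `elevation` (data.frame per group:
#'   saline/microbead means and `percent_elevation`).
#' @export
iop_elevation_summary <- function(records) {
  post <- records[records$day >= 1, , drop = FALSE]
  if (nrow(post) == 0) stopf("no post-injection (day >= 1) records")
  if (is.null(post$group)) post$group <- "ALL"
  pa <- stats::aggregate(iop_mmHg ~ animal_id + eye + group, post, mean)
  have_both <- names(which(table(pa$animal_id) == 2))
  flagged <- setdiff(unique(pa$animal_id), have_both)
  if (length(flagged)) {
    warnf("animal(s) missing one eye, flagged and dropped: %s",
          paste(flagged, collapse = ", "))
    pa <- pa[pa$animal_id %in% have_both, , drop = FALSE]
  }
  pg <- do.call(rbind, lapply(split(pa, list(pa$group, pa$eye), drop = TRUE),
                              function(d) {
    data.frame(group = d$group[1], eye = d$eye[1], n = nrow(d),
               mean_iop = mean(d$iop_mmHg), sem = sem(d$iop_mmHg),
               sem_undefined = nrow(d) < 2)
  }))
  rownames(pg) <- NULL
  elev <- do.call(rbind, lapply(split(pg, pg$group), function(d) {
    sal <- d$mean_iop[d$eye == "SALINE"]
    mb <- d$mean_iop[d$eye == "MICROBEAD"]
    data.frame(group = d$group[1], saline_mean = sal, microbead_mean = mb,
               percent_elevation = percent_change(sal, mb))
  }))
  rownames(elev) <- NULL
  list(per_animal = pa, per_group = pg, elevation = elev)
}
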