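# The statistical battery: baselines, percent change, unity tests, the
# normality gate, ANOVA + Holm-Sidak, and the IOP summary.

test_that("baseline_iop averages pre-injection readings per eye", {
  rec <- data.frame(animal_id = "A1", eye = "SALINE", day = -2:0,
                    iop_mmHg = c(19, 20, 21))
  expect_equal(baseline_iop(rec)$baseline_iop_mmHg, 20)
  one <- data.frame(animal_id = "A1", eye = "SALINE", day = 0, iop_mmHg = 20.5)
  expect_warning(b <- baseline_iop(one), "2-3")
  expect_equal(b$baseline_iop_mmHg, 20.5)
  expect_error(baseline_iop(rec[rec$day > 0, ]), "pre-injection")
})

test_that("percent_change matches hand arithmetic and its inverse identity", {
  expect_equal(format_percent_change(percent_change(20.12, 26.69), "iop"), 32.7)
  expect_equal(format_percent_change(percent_change(2.34, 0.71), "ratio"), -70)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "non-zero")
  # (1 + d1/100)(1 + d2/100) = 1 for forward and reverse changes
  set.seed(1)
  for (i in 1:25) {
    a <- runif(1, 0.1, 50); b <- runif(1, 0.1, 50)
    d1 <- percent_change(a, b); d2 <- percent_change(b, a)
    expect_equal((1 + d1 / 100) * (1 + d2 / 100), 1)
  }
})

test_that("test_vs_unity matches the closed-form t distribution", {
  # all ratios exactly 1 -> t = 0, one-sided p = 0.5
  r <- test_vs_unity(c(1, 1, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5)

  # closed-form oracle
  x <- c(2.0, 2.1, 1.9)
  r2 <- test_vs_unity(x)
  t_oracle <- (mean(x) - 1) / (sd(x) / sqrt(3))
  expect_equal(r2$statistic, t_oracle)
  expect_equal(r2$p_value, pt(t_oracle, 2, lower.tail = FALSE))
  expect_lt(r2$p_value, 0.05)

  # degenerate: zero variance away from the value
  r3 <- test_vs_unity(c(2, 2, 2))
  expect_equal(r3$p_value, 0)
  expect_true(r3$degenerate)
  expect_error(test_vs_unity(1.2), "n >= 2")
})

test_that("compare_groups gates on Shapiro-Wilk and records the route", {
  # identical samples -> t route, t = 0, p = 1
  a <- c(1, 2, 3, 4, 5)
  r <- compare_groups(a, a)
  expect_equal(r$route, "t_two_sided")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  # strongly skewed sample routes to Mann-Whitney
  skew <- exp(seq(0, 6, length.out = 20))
  r2 <- compare_groups(skew, rnorm(20, mean(skew)))
  expect_equal(r2$route, "mann_whitney")
  expect_false(r2$normality_pass)

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "n >= 3")

  # power oracle: N(0,1) vs N(2,1), n = 10 -> rejection rate > 0.9
  set.seed(7)
  rej <- mean(vapply(1:300, function(i) {
    compare_groups(rnorm(10), rnorm(10, 2))$p_value < 0.05
  }, TRUE))
  expect_gt(rej, 0.9)
})

test_that("holm_sidak_adjust is correct, monotone and order-preserving", {
  p <- c(0.01, 0.04, 0.03)
  adj <- holm_sidak_adjust(p)
  # hand computation: ordered 0.01, 0.03, 0.04 with exponents 3, 2, 1
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[3], max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2))
  expect_equal(adj[2], max(adj[3], 1 - (1 - 0.04)^1))
  # monotone in raw p over random vectors
  set.seed(2)
  for (i in 1:20) {
    p <- runif(6)
    a <- holm_sidak_adjust(p)
    expect_true(all(diff(a[order(p)]) >= -1e-12))
    expect_true(all(a >= p - 1e-12) && all(a <= 1))
  }
})

test_that("anova_holm_sidak rejects only where the effect is", {
  # three identical groups -> no rejections
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  r <- anova_holm_sidak(g)
  expect_true(all(r$pairwise$p_adjusted > 0.99))

  # one group shifted by 3 sd: its comparisons reject in a simulation majority
  set.seed(11)
  hits <- replicate(60, {
    gs <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6, 3))
    r <- anova_holm_sidak(gs)
    with_c <- grepl("c", paste(r$pairwise$group1, r$pairwise$group2))
    c(all(r$pairwise$p_adjusted[with_c] < 0.05),
      r$pairwise$p_adjusted[!with_c] < 0.05)
  })
  expect_gt(mean(hits[1, ]), 0.5)   # both c-comparisons reject
  expect_lt(mean(hits[2, ]), 0.2)   # a-b rarely rejects
  expect_error(anova_holm_sidak(list(1:3, 1:3)), ">= 3 groups")
})

test_that("iop_elevation_summary reproduces noise-free arithmetic", {
  spec <- synthetic_spec(seed = 1)
  s <- generate_iop_series(spec, baseline_mmHg = 20, elevation_fraction = 0.327,
                           n_days = 4, animal_sd = 0, measure_sd = 0)
  out <- iop_elevation_summary(s)
  expect_equal(out$elevation$percent_elevation, 32.7)

  # single animal: SEM undefined and flagged
  expect_true(all(out$per_group$sem_undefined))
  expect_true(all(is.na(out$per_group$sem)))

  # missing eye -> flagged with a warning
  s2 <- generate_iop_series(spec, animal_ids = c("A1", "A2"))
  s2 <- s2[!(s2$animal_id == "A2" & s2$eye == "MICROBEAD"), ]
  expect_warning(out2 <- iop_elevation_summary(s2), "A2")
  expect_false("A2" %in% out2$per_animal$animal_id)
})

test_that("observed_power reports and never gates", {
  p <- observed_power(rnorm(10), rnorm(10, 3))
  expect_true(p > 0.9 && p <= 1)
  expect_equal(observed_power(rep(1, 5), rep(1, 5)), 1)
})
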