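test_that("Shapiro-Wilk wrapper validates input and detects departures", {
  # a sample built from normal order-statistic quantiles is maximally normal
  x <- qnorm((seq_len(20) - 0.5) / 20)
  expect_gt(shapiro_wilk(x)$p_value, 0.9)
  # a point mass with one extreme outlier is not normal
  y <- c(rep(1, 9) + seq(0, 1e-4, length.out = 9), 100)
  expect_lt(shapiro_wilk(y)$p_value, 0.01)
  # affine transforms leave W unchanged
  set.seed(91)
  z <- rnorm(25)
  expect_equal(shapiro_wilk(z)$statistic,
               shapiro_wilk(3 - 2.5 * z)$statistic, tolerance = 1e-10)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(c(1, 2, Inf)), "finite")
  expect_warning(shapiro_wilk(c(1, 1, 2, 3)), "ties")
})

test_that("identical samples give p = 1 and degenerate input errors", {
  a <- c(1.2, 3.4, 5.6, 7.8)
  t1 <- two_sample_test(a, a)
  expect_equal(t1$p_value, 1, tolerance = 1e-9)
  expect_error(two_sample_test(rep(2, 5), rep(2, 5)), "identical")
  expect_error(two_sample_test(c(1, 2), c(3, 4, 5)), "n >= 3")
})

test_that("the exact Mann-Whitney matches full enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)

  set.seed(92)
  for (n in 3:6) {
    for (m in n:min(9, 12 - n)) {
      if (n + m > 12) next
      vals <- sample(seq_len(100), n + m)  # tie-free
      a <- vals[seq_len(n)]
      b <- vals[-seq_len(n)]
      mw <- mann_whitney_u(a, b)
      expect_equal(mw$p_value, mw_enum_p(a, b), tolerance = 1e-12,
                   info = sprintf("n=%d m=%d", n, m))
    }
  }
})

test_that("the normality gate selects the branch and records it", {
  set.seed(93)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  t_norm <- two_sample_test(a, b)
  expect_equal(t_norm$method, "student_t")
  # heavy-tailed data fails the gate and falls through to Mann-Whitney
  c1 <- rlnorm(40, 0, 1.5); c2 <- rlnorm(40, 1, 1.5)
  t_mw <- two_sample_test(c1, c2)
  expect_equal(t_mw$method, "mann_whitney_u")
  expect_true(all(c(t_norm$p_value, t_mw$p_value) >= 0))
  expect_true(all(c(t_norm$p_value, t_mw$p_value) <= 1))
  td <- tidy(t_mw)
  expect_equal(td$method, "mann_whitney_u")
  expect_true(all(c("normality_p_a", "normality_p_b") %in% names(td)))
})

test_that("two-sample tests are symmetric in their arguments", {
  set.seed(94)
  a <- rnorm(15); b <- rnorm(12, 1)
  t1 <- two_sample_test(a, b)
  t2 <- two_sample_test(b, a)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
  expect_equal(t1$statistic, -t2$statistic, tolerance = 1e-12)
  c1 <- rlnorm(20, 0, 2); c2 <- rlnorm(20, 0.5, 2)
  m1 <- two_sample_test(c1, c2)
  m2 <- two_sample_test(c2, c1)
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
})

test_that("balanced additive two-way ANOVA matches the closed form", {
  # cell means: mu + a_i + b_j, zero noise except tiny jitter for df
  g <- rep(c("control", "AD"), each = 8)
  f <- rep(rep(c("CD68+", "CD68-"), each = 4), 2)
  mu <- 10; eff_g <- ifelse(g == "AD", 3, -3); eff_f <- ifelse(f == "CD68+", 2, -2)
  set.seed(95)
  eps <- rnorm(16, sd = 1e-3)
  df <- data.frame(volume_um3 = mu + eff_g + eff_f + eps,
                   group = g, cd68_status = f)
  an <- two_way_anova_bonferroni(df)
  tab <- an$anova
  # balanced closed form: SS_group = n * sum over levels of effect^2
  expect_equal(tab$sumsq[1], 16 * 3^2, tolerance = 1e-3)
  expect_equal(tab$sumsq[2], 16 * 2^2, tolerance = 1e-3)
  # additive model: interaction F indistinguishable from 0
  expect_lt(tab$statistic[3], 1e-2 / (1e-3)^2 * 1e-6 + 5)
  expect_gt(tab$p_value[3], 0.05)
})

test_that("ANOVA rejects designs with an empty or single-observation cell", {
  df <- data.frame(volume_um3 = rnorm(7),
                   group = c("control", "control", "control", "AD", "AD",
                             "AD", "AD"),
                   cd68_status = c("CD68+", "CD68+", "CD68-", "CD68+",
                                   "CD68+", "CD68+", "CD68+"))
  expect_error(two_way_anova_bonferroni(df), "fewer than 2")
})

test_that("Bonferroni correction never falls below the raw p-value", {
  set.seed(96)
  df <- data.frame(volume_um3 = rnorm(100),
                   group = sample(c("control", "AD"), 100, TRUE),
                   cd68_status = sample(c("CD68+", "CD68-"), 100, TRUE))
  an <- two_way_anova_bonferroni(df)
  expect_true(all(an$contrasts$p_bonferroni >= an$contrasts$p_raw - 1e-15))
  expect_true(all(an$contrasts$p_bonferroni <= 1))
  gl <- glance(an)
  expect_true(all(c("p_group", "p_factor2", "p_interaction") %in% names(gl)))
})

test_that("group summaries report mean and SEM in the house style", {
  s <- summarize_groups(data.frame(v = c(2, 4, 6), g = "a"), "v", "g")
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3), tolerance = 1e-12)
  s0 <- summarize_groups(data.frame(v = rep(5, 4), g = "a"), "v", "g")
  expect_equal(s0$sem, 0)
  # order invariance
  set.seed(97)
  v <- rnorm(20)
  s1 <- summarize_groups(data.frame(v = v, g = "a"), "v", "g")
  s2 <- summarize_groups(data.frame(v = sample(v), g = "a"), "v", "g")
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sem, s2$sem)
})

test_that("star annotations follow the reporting convention", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
})
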