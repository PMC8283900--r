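test_that("percent change reproduces hand arithmetic", {
  expect_equal(round(delta_percent(38, 32.7), 1), 13.9)
  expect_equal(round(delta_percent(42, 23), 1), 45.2)
  expect_equal(delta_percent(17, 17), 0)
  # agrees with referenced improvement at reference zero
  expect_equal(delta_percent(63, 50), referenced_improvement(63, 50, 0))
})

test_that("effect size uses the pooled-SD standardizer by default", {
  expect_equal(effect_size(63, 22, 50, 24), 13 / sqrt((22^2 + 24^2) / 2))
  expect_equal(round(effect_size(63, 22, 50, 24), 2), 0.56)
  expect_equal(effect_size(10, 3, 10, 5), 0)
  expect_equal(effect_size(14, 13, 6.2, 4.3, method = "baseline"),
               (14 - 6.2) / 13)
  d <- c(1, 2, 3, 2, 4)
  expect_equal(effect_size(NA, NA, NA, NA, method = "paired",
                           before = d + 5, after = rep(5, 5)),
               mean(d) / sd(d))
  expect_error(effect_size(1, 1, 1, 1, method = "paired"), "per-subject")
})

test_that("Welch's t matches the closed-form statistic", {
  x <- c(12.1, 9.8, 11.4, 10.2, 13.0, 9.9, 12.5)
  y <- c(8.8, 10.1, 9.4, 7.9, 9.2, 8.5)
  got <- welch_t(x, y)
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  t_manual <- (mean(x) - mean(y)) / se
  df_manual <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                         (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(got$statistic, t_manual, tolerance = 1e-10)
  expect_equal(got$df, df_manual, tolerance = 1e-10)
  expect_equal(got$p_value,
               2 * pt(abs(t_manual), df_manual, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical groups: statistic 0, p in the null region
  same <- welch_t(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("a one-sigma shift at n = 50 is detected in >= 95% of replicates", {
  set.seed(202)
  hits <- 0L
  for (i in 1:200) {
    x <- rnorm(50)
    y <- rnorm(50, mean = 1)
    hits <- hits + (welch_t(x, y)$p_value < 0.01)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Pearson r and Fisher-z interval match the closed form", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.5, 6.1, 7.9, 8.2, 9.9, 11)
  y <- 0.5 * x + c(0.3, -0.2, 0.4, -0.5, 0.2, 0.1, -0.3, 0.6, -0.1, 0.2)
  got <- pearson_ci(x, y)
  r <- cor(x, y)
  z <- atanh(r)
  half <- qnorm(0.975) / sqrt(length(x) - 3)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$ci, tanh(c(z - half, z + half)), tolerance = 1e-10)
  expect_equal(pearson_ci(x, x)$r, 1)

  # closed-form interval width at rho = 0.4, n = 170 is about a quarter unit
  z4 <- atanh(0.4)
  w <- qnorm(0.975) / sqrt(170 - 3)
  expect_equal(tanh(z4 + w) - tanh(z4 - w), 0.254, tolerance = 0.005)

  # independent Gaussians rarely show |r| > 0.2 at n = 200
  set.seed(303)
  big <- replicate(100, abs(pearson_ci(rnorm(200), rnorm(200))$r))
  expect_gte(mean(big < 0.2), 0.95)
})

test_that("transition tables match brute-force enumeration", {
  before <- c("NFU", "NFU", "NFU", "NFC", "FC_P", "FC_P", "FU_WO", "NFC",
              "FC_WO", "NFU")
  after <- c("FC_P", "FU_P", "NFU", "NFC", "NFC", "FC_P", "FU_WO", "NFC",
             "FC_P", "NFU")
  tt <- transition_table(before, after)
  expect_equal(tt$n, 10L)
  # brute-force counts
  expect_equal(unname(tt$table["NFU", "FC_P"]), 1L)
  expect_equal(unname(tt$table["NFU", "NFU"]), 2L)
  expect_equal(sum(tt$table), 10L)
  expect_equal(tt$pct_unchanged, 100 * 6 / 10)
  # marginals consistent with the input vectors
  expect_equal(tt$marginals$before,
               as.integer(table(factor(before,
                                       levels = tt$marginals$class))))
  identical_case <- transition_table(before, before)
  expect_equal(identical_case$pct_unchanged, 100)
  expect_error(transition_table(before, after[-1]), "paired")
  expect_error(transition_table("NFB", "NFC"), "unknown class")
})

test_that("ANOVA with Sidak adjustment orders p-values sensibly", {
  set.seed(404)
  g <- rep(c("a", "b", "c"), each = 20)
  v <- rnorm(60) + rep(c(0, 0, 2), each = 20)
  res <- anova_sidak(v, g)
  expect_lt(res$anova_p, 0.001)
  expect_true(all(res$pairwise$p_sidak >= res$pairwise$p_raw))
  expect_equal(nrow(res$pairwise), 3L)
  ab <- res$pairwise$p_sidak[res$pairwise$group1 == "a" &
                               res$pairwise$group2 == "b"]
  ac <- res$pairwise$p_sidak[res$pairwise$group1 == "a" &
                               res$pairwise$group2 == "c"]
  expect_gt(ab, 0.05)
  expect_lt(ac, 0.01)
})

test_that("treatment-change tables assemble the published arithmetic", {
  set.seed(505)
  before <- data.frame(subject_id = sprintf("s%02d", 1:30),
                       ptb = rnorm(30, 63, 22), mbks = rnorm(30, 29.4, 4.2))
  after <- data.frame(subject_id = before$subject_id,
                      ptb = rnorm(30, 50, 24), mbks = rnorm(30, 27, 4.3))
  tab <- treatment_change_table(before, after, c("ptb", "mbks"))
  expect_equal(tab$measure, c("ptb", "mbks"))
  expect_equal(tab$delta_pct[1],
               delta_percent(mean(before$ptb), mean(after$ptb)))
  expect_equal(tab$effect_size[2],
               effect_size(mean(before$mbks), sd(before$mbks),
                           mean(after$mbks), sd(after$mbks)))
  expect_equal(tab$n, c(30L, 30L))
})
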