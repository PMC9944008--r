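test_that("molar C:P follows the atomic masses and is scale invariant", {
  expect_equal(molar_cp(12.011, 30.974), 1)
  expect_equal(molar_cp(120.11, 30.974), 10)
  expect_equal(molar_cp(100, 2.237), 115.3, tolerance = 1e-3)
  set.seed(2)
  C <- runif(10, 10, 500); P <- runif(10, 1, 50); k <- runif(10, 0.1, 9)
  expect_equal(molar_cp(k * C, k * P), molar_cp(C, P), tolerance = 1e-12)
  expect_error(molar_cp(10, 0), "undefined")
})

test_that("percent reduction matches the worked examples", {
  expect_equal(round(percent_reduction(1.33, 0.23)), 83)
  expect_equal(round(percent_reduction(3.18, 2.48)), 22)
  expect_equal(percent_reduction(5, 5), 0)
  expect_error(percent_reduction(0, 1), "control_mean")
})

test_that("grazing rate converts dry-mass loss to ug per hour per grazer", {
  expect_equal(grazing_rate(1, 1, 100, 4, 10), 0)
  expect_equal(grazing_rate(1.33, 0.23, 158.7, 8, 336), 64.9,
               tolerance = 1e-3)
  expect_equal(grazing_rate(2, 1, 1, 1, 1), 1000)
  expect_warning(r <- grazing_rate(1, 2, 100, 4, 10), "truncated")
  expect_equal(r, 0)
  expect_error(grazing_rate(1, 0.5, 100, 4, 0), "duration")
})

test_that("summary-mode t equals raw-mode t and base R", {
  set.seed(5)
  for (method in c("student", "welch")) {
    a <- rnorm(6, 10, 2); b <- rnorm(4, 8, 3)
    raw <- compare_two_groups(a, b, method)
    summ <- compare_two_groups(list(mean = mean(a), sd = sd(a), n = 6),
                               list(mean = mean(b), sd = sd(b), n = 4),
                               method)
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-9)
    expect_equal(raw$df, summ$df, tolerance = 1e-9)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-9)
    tt <- t.test(a, b, var.equal = method == "student")
    expect_equal(raw$statistic, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(raw$df, unname(tt$parameter), tolerance = 1e-9)
  }
  # identical groups: t = 0, p = 1
  x <- c(1, 2, 3)
  eq <- compare_two_groups(x, x, "student")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # zero variance in both groups with equal means: undefined, flagged
  z <- compare_two_groups(c(2, 2, 2), c(2, 2, 2), "student")
  expect_true(is.na(z$statistic))
  expect_match(z$note, "undefined")
})

test_that("the published resting-detections t-test is reproduced", {
  tt <- compare_two_groups(list(mean = 27741, sd = 1718, n = 3),
                           list(mean = 6550, sd = 2380, n = 3), "student")
  expect_equal(round(tt$statistic, 2), 12.50)
  expect_equal(tt$df, 4)
  expect_lt(tt$p_value, 0.001)
})

test_that("exact Wilcoxon p equals full enumeration for small samples", {
  w <- compare_two_groups(c(1, 2, 3), c(4, 5, 6), "wilcoxon")
  expect_equal(w$statistic, 0)
  expect_equal(w$p_exact, 0.10, tolerance = 1e-9)
  set.seed(13)
  for (n in 2:5) {
    for (k in 1:4) {
      a <- round(runif(n, 0, 100), 3)
      b <- round(runif(n, 0, 100), 3)
      if (anyDuplicated(c(a, b))) next
      w <- compare_two_groups(a, b, "wilcoxon")
      expect_equal(w$p_exact, oracle_wilcox_p(a, b), tolerance = 1e-9)
      expect_true(is.finite(w$p_approx))
    }
  }
})

test_that("the two-way ANOVA reproduces hand-computed sums of squares", {
  d <- data.frame(y = c(1, 3, 2, 4, 5, 7, 6, 8),
                  A = rep(c("a1", "a2"), each = 4),
                  B = rep(c("b1", "b2", "b1", "b2"), each = 2))
  fa <- factorial_anova(d, "y", "A", "B")
  tab <- fa$table
  expect_equal(tab$sum_sq[tab$term == "A"], 32)
  expect_equal(tab$sum_sq[tab$term == "B"], 2)
  expect_equal(tab$sum_sq[tab$term == "A:B"], 0, tolerance = 1e-9)
  expect_equal(tab$mean_sq[tab$term == "Residuals"], 2)
  expect_equal(tab$F[tab$term == "A"], 16)
  expect_equal(tab$F[tab$term == "B"], 1)
  expect_equal(tab$F[tab$term == "A:B"], 0, tolerance = 1e-9)
  # location invariance
  d2 <- d; d2$y <- d2$y + 100
  fa2 <- factorial_anova(d2, "y", "A", "B")
  expect_equal(fa2$table$F, fa$table$F, tolerance = 1e-9)
  # SS decomposition on random balanced data
  set.seed(19)
  d3 <- data.frame(y = rnorm(16),
                   A = rep(c("a1", "a2"), each = 8),
                   B = rep(rep(c("b1", "b2"), each = 4), 2))
  fa3 <- factorial_anova(d3, "y", "A", "B")
  ss_total <- sum((d3$y - mean(d3$y))^2)
  expect_equal(sum(fa3$table$sum_sq), ss_total, tolerance = 1e-9)
  # all-equal cell means: Tukey-adjusted p of 1 for every pair
  d4 <- data.frame(y = rep(c(1, 3), 4),
                   A = rep(c("a1", "a2"), each = 4),
                   B = rep(c("b1", "b1", "b2", "b2"), 2))
  fa4 <- factorial_anova(d4, "y", "A", "B")
  expect_true(all(abs(fa4$tukey$p_adj - 1) < 1e-9))
  # unbalanced designs are outside the model
  expect_error(factorial_anova(d3[-1, ], "y", "A", "B"), "balanced")
})

test_that("assumption checks report Shapiro-Wilk and Levene sensibly", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  ch <- assumption_checks(g)
  expect_equal(ch$levene$F, 0, tolerance = 1e-12)
  ch2 <- assumption_checks(list(a = c(2, 2, 2), b = c(1, 2, 3)))
  expect_true(is.na(ch2$shapiro$W[1]))
  expect_match(ch2$shapiro$note[1], "undefined")
  ch3 <- assumption_checks(list(a = c(1, 2), b = c(1, 2, 3)))
  expect_match(ch3$shapiro$note[1], "skipped")
})

test_that("Shapiro-Wilk holds its nominal size under the null", {
  set.seed(29)
  keep <- vapply(1:100, function(k) {
    shapiro.test(rnorm(5000))$p.value > 0.05
  }, logical(1))
  expect_gte(mean(keep), 0.90)
})
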