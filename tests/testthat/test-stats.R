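test_that("two-sample t matches hand formula and its symmetries", {
  r <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r <- t_test_two_sample(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r$statistic, -2 / sqrt(2 / 3), tolerance = 1e-6)  # -2.449
  expect_equal(r$df, 4)

  fw <- t_test_two_sample(c(1, 2, 3), c(3, 4, 5))
  bw <- t_test_two_sample(c(3, 4, 5), c(1, 2, 3))
  expect_equal(fw$statistic, -bw$statistic)
  expect_equal(fw$p_value, bw$p_value)

  same <- t_test_two_sample(c(2, 2, 2), c(2, 2))
  expect_equal(same$p_value, 1)
})

test_that("Fisher's exact test follows the minimum-likelihood two-sided rule", {
  # the study's sex table: observed cell at the hypergeometric mode
  expect_equal(round(fisher_exact_2x2(matrix(c(12, 9, 7, 4), 2))$p_value, 3),
               1.000)
  # enumeration of the 6 tables with margins (5,5)/(5,5)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 5, 0), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher p matches full enumeration and respects table symmetry", {
  set.seed(31)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_enum_p(tab), tolerance = 1e-9)
    expect_gt(p, 0)
    expect_lte(p, 1)
    swapped <- tab[2:1, 2:1]
    expect_equal(fisher_exact_2x2(swapped)$p_value, p, tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches hand computation and is affine-invariant", {
  expect_equal(pearson_correlation(1:3, c(2, 4, 6))$statistic, 1)
  expect_equal(pearson_correlation(1:3, c(6, 4, 2))$statistic, -1)
  r <- pearson_correlation(1:4, c(1, 3, 2, 4))
  expect_equal(r$statistic, 0.8)
  expect_equal(r$df, 2)
  set.seed(32)
  x <- rnorm(15); y <- rnorm(15)
  r0 <- pearson_correlation(x, y)$statistic
  r1 <- pearson_correlation(3 * x - 2, 0.5 * y + 7)$statistic
  expect_equal(r0, r1)
  expect_true(abs(r0) <= 1)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("mixed ANOVA reproduces the hand-decomposed toy example", {
  a <- mixed_anova(toy_anova_data(), "y", "subject", "grp", "cond")
  expect_equal(a$ss, c(288, 32, 32, 8, 0))
  expect_equal(a$F[a$term == "group"], 18)
  expect_equal(a$df[a$term == "group"], 1)
  expect_equal(a$df_error[a$term == "group"], 2)
  # zero residual: within-subject Fs are flagged, never infinite
  expect_true(a$degenerate[a$term == "condition"])
  expect_true(a$degenerate[a$term == "group:condition"])
  expect_true(is.na(a$F[a$term == "condition"]))

  flat <- toy_anova_data(); flat$y <- 5
  af <- mixed_anova(flat, "y", "subject", "grp", "cond")
  expect_equal(af$ss, rep(0, 5))
  expect_true(all(is.na(af$F)))
})

test_that("mixed ANOVA SS match stats::aov strata on random unbalanced tables", {
  set.seed(33)
  for (rep in 1:8) {
    d <- random_anova_table(n1 = sample(3:7, 1), n2 = sample(2:6, 1),
                            w = sample(2:4, 1))
    a <- mixed_anova(d, "y", "subject", "grp", "cond")
    oracle <- aov_ss(d, "y", "subject", "grp", "cond")
    expect_equal(a$ss, unname(oracle), tolerance = 1e-8)
    # conservation: components sum to the total SS
    expect_equal(sum(a$ss), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
  }
})

test_that("mixed ANOVA is invariant to subject relabelling within groups", {
  set.seed(34)
  d <- random_anova_table(4, 3, 3)
  a1 <- mixed_anova(d, "y", "subject", "grp", "cond")
  d2 <- d
  d2$subject[d2$subject == "a1"] <- "zz"
  a2 <- mixed_anova(d2, "y", "subject", "grp", "cond")
  expect_equal(a1$ss, a2$ss)
  expect_error(mixed_anova(d[-1, ], "y", "subject", "grp", "cond"),
               "balanced")
})

test_that("Holm-Sidak thresholds follow the closed form and step-down rule", {
  out <- holm_sidak(c(0.01, 0.02, 0.20), alpha = 0.05)
  expect_equal(out$threshold,
               c(1 - 0.95^(1 / 3), 1 - 0.95^(1 / 2), 0.05), tolerance = 1e-9)
  expect_equal(out$rejected, c(TRUE, TRUE, FALSE))
  expect_equal(holm_sidak(c(0.9, 0.9, 0.9))$rejected, rep(FALSE, 3))
  expect_equal(holm_sidak(0.04)$rejected, TRUE)   # m = 1 reduces to p < alpha
  expect_equal(holm_sidak(0.06)$rejected, FALSE)
})

test_that("step-down decisions match step-by-step enumeration and dominate single-step Sidak", {
  set.seed(35)
  for (rep in 1:20) {
    m <- sample(2:8, 1)
    p <- round(runif(m), 3)
    out <- holm_sidak(p, alpha = 0.05)
    # independent enumeration of the step-down walk
    ord <- order(p)
    expected <- logical(m)
    for (i in seq_len(m)) {
      thr <- 1 - 0.95^(1 / (m - i + 1))
      if (p[ord[i]] < thr) expected[ord[i]] <- TRUE else break
    }
    expect_equal(out$rejected, expected)
    single <- p < 1 - 0.95^(1 / m)
    expect_true(all(out$rejected[single]))  # superset of single-step Sidak
  }
})

test_that("switching cost is a plain difference, reusable for Ter", {
  expect_equal(switching_cost(900, 800), 100)
  expect_equal(switching_cost(700, 700), 0)
  expect_equal(switching_cost(c(350, 400), c(300, 420)), c(50, -20))
})

test_that("fit r-squared squares the correlation and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(as.numeric(fit_r2(x, x)), 1)
  flat <- fit_r2(x, rep(2, 4))
  expect_true(is.na(flat))
  expect_true(attr(flat, "undefined"))
  expect_equal(as.numeric(fit_r2(c(1, 3, 2, 4), 1:4)), 0.64)
})

test_that("power-analysis sample size tracks the normal approximation", {
  n <- sample_size_two_sample(1.0, alpha = 0.05, power = 0.8, tails = 1)
  approx_n <- 2 * (qnorm(0.95) + qnorm(0.8))^2
  expect_lte(abs(n - approx_n), 2)
  expect_equal(n, 14)  # exact t-based: power at n = 13 is 0.797
  # attained power is >= target and n is minimal
  expect_gte(power.t.test(n = n, delta = 1, sig.level = 0.05,
                          type = "two.sample",
                          alternative = "one.sided")$power, 0.8)
  expect_lt(power.t.test(n = n - 1, delta = 1, sig.level = 0.05,
                         type = "two.sample",
                         alternative = "one.sided")$power, 0.8)
  expect_equal(sample_size_two_sample(1.0, power = 0.049), 2L)
  # 1/d^2 scaling: doubling d roughly quarters n
  n_half <- sample_size_two_sample(0.5)
  expect_lt(abs(n_half / sample_size_two_sample(1.0) - 4), 1)
})
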