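test_that("one-way ANOVA and omega-squared match hand arithmetic", {
  res <- anova_omega2(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df, c(1, 4))
  # SSB = 13.5, MSW = 1, SST = 17.5 -> (13.5 - 1) / (17.5 + 1)
  expect_equal(res$effect_size, 12.5 / 18.5)
  expect_equal(res$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("omega-squared is negative exactly when F < 1", {
  set.seed(2)
  repeat {
    v <- rnorm(30)
    g <- rep(1:3, each = 10)
    res <- anova_omega2(v, g)
    if (res$statistic < 1) break
  }
  expect_lt(res$effect_size, 0)
  # zero within-group variance everywhere is flagged with omega2 = 0
  res0 <- anova_omega2(rep(1, 8), rep(1:2, each = 4))
  expect_equal(res0$effect_size, 0)
  expect_true(res0$zero_variance)
})

test_that("Kruskal-Wallis H matches direct rank arithmetic", {
  v <- c(1, 2, 10, 11, 20, 21)
  g <- rep(c("a", "b", "c"), each = 2)
  res <- kruskal_wallis_eta2(v, g)
  expect_equal(res$statistic, oracle_kruskal_h(v, g))
  expect_equal(res$df, 2)
  expect_equal(res$eta2_raw, (res$statistic - 2) / (6 - 3))
  # with ties
  v2 <- c(1, 1, 2, 2, 3, 3, 9, 9)
  g2 <- rep(c("a", "b"), each = 4)
  expect_equal(kruskal_wallis_eta2(v2, g2)$statistic,
               oracle_kruskal_h(v2, g2))
  # identical groups: H = 0, p = 1
  res0 <- kruskal_wallis_eta2(rep(5, 9), rep(1:3, each = 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(5)
  v <- rexp(24)
  g <- rep(1:3, each = 8)
  h <- kruskal_wallis_eta2(v, g)$statistic
  expect_equal(kruskal_wallis_eta2(log(v), g)$statistic, h)
  expect_equal(kruskal_wallis_eta2(v^3, g)$statistic, h)
})

test_that("Mann-Whitney post hocs report U, r and the Bonferroni cap", {
  sep <- mann_whitney_posthoc(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(sep$statistic), 0)  # complete separation
  same <- mann_whitney_posthoc(c(1, 2, 3, 4), c(1, 2, 3, 4),
                               n_comparisons = 3)
  expect_equal(same$effect_size, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  # Bonferroni multiplies and caps, never decreases
  set.seed(6)
  a <- rnorm(15); b <- rnorm(15)
  raw <- mann_whitney_posthoc(a, b, 1)
  adj <- mann_whitney_posthoc(a, b, 3)
  expect_equal(adj$p_value, min(1, raw$p_value * 3))
  expect_gte(adj$p_value, raw$p_value)
})

test_that("the exact r x c test reproduces known p-values", {
  expect_equal(freeman_halton_exact(rbind(c(1, 1), c(1, 1)))$p_value, 1)
  expect_equal(freeman_halton_exact(rbind(c(5, 0), c(0, 5)))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_error(freeman_halton_exact(rbind(c(0, 0), c(1, 1))), "margin")
})

test_that("the exact test on 2x2 tables equals the classical Fisher p", {
  set.seed(8)
  for (r in 1:10) {
    tab <- matrix(rpois(4, 5) + 1, 2, 2)
    expect_equal(freeman_halton_exact(tab)$p_value,
                 fisher.test(tab)$p.value)
  }
})

test_that("Monte-Carlo fallback agrees with enumeration within its SE", {
  tab <- rbind(c(4, 2, 1), c(1, 3, 5))
  exact <- freeman_halton_exact(tab)
  mc <- freeman_halton_exact(tab, exact_budget = 0, mc_B = 2e4, seed = 9)
  expect_equal(mc$method, "monte_carlo")
  expect_lt(abs(mc$p_value - exact$p_value), 3 * mc$mc_se + 1e-4)
})

test_that("Cramer's V spans its range and matches hand chi-squared", {
  expect_equal(cramers_v(diag(c(10, 10))), 1)
  indep <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(cramers_v(indep), 0, tolerance = 1e-12)
  tab <- rbind(c(10, 5), c(5, 10))
  expect_equal(cramers_v(tab), sqrt((30 * (10 * 10 - 5 * 5)^2 /
                                       (15 * 15 * 15 * 15)) / 30),
               tolerance = 1e-12)
  expect_equal(cramers_v(tab), cramers_v(tab[2:1, 2:1]))
  expect_error(cramers_v(matrix(1:3, 1)), "single")
})

test_that("Little's MCAR statistic is zero for complete data", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  res <- little_mcar(X)
  expect_equal(res$statistic, 0, tolerance = 1e-8)
  expect_equal(res$df, 0)
  expect_equal(res$p_value, 1)
})

test_that("Little's MCAR statistic matches the direct pattern formula", {
  X <- rbind(c(1, 2), c(2, 5), c(3, 3), c(4, 6),
             c(10, NA), c(0, NA))
  res <- little_mcar(X)
  est <- lpacourse:::mvn_em(X)
  pats <- list(complete = 1:4, partial = 5:6)
  d2 <- 0
  # complete rows: both variables observed
  xb <- colMeans(X[1:4, ])
  d2 <- d2 + 4 * drop(t(xb - est$mu) %*% solve(est$sigma) %*% (xb - est$mu))
  # partial rows: only variable 1 observed
  xb1 <- mean(X[5:6, 1])
  d2 <- d2 + 2 * (xb1 - est$mu[1])^2 / est$sigma[1, 1]
  expect_equal(res$statistic, d2, tolerance = 1e-8)
  expect_equal(res$df, 2 + 1 - 2)
})

test_that("all reported p-values stay within [0, 1]", {
  set.seed(12)
  for (r in 1:10) {
    v <- rnorm(30)
    g <- sample(1:3, 30, replace = TRUE)
    expect_true(anova_omega2(v, g)$p_value >= 0)
    expect_true(anova_omega2(v, g)$p_value <= 1)
    kw <- kruskal_wallis_eta2(v, g)
    expect_true(kw$p_value >= 0 && kw$p_value <= 1)
  }
})

test_that("the validation battery produces a row per configured variable", {
  cfg <- cohort_config(n_patients = 300, seed = 19)
  b <- sample_baseline(cfg)
  b$class <- b$true_class
  scored <- score_baseline(b)
  rep <- validate_classes(scored)
  expect_true(all(c("variable", "p_value", "effect_size") %in% names(rep)))
  expect_true("neuroticism" %in% rep$variable)
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  # the scales that define the classes separate far more strongly than noise
  expect_lt(rep$p_value[rep$variable == "neuroticism"], 0.001)
  expect_lt(rep$p_value[rep$variable == "conscientiousness"], 0.001)
})
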