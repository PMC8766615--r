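test_that("screening keeps a perfect correlate and logs its rho", {
  set.seed(1)
  d <- data.frame(y = rnorm(50))
  d$twin <- d$y
  d$noise <- rnorm(50)
  res <- screen_predictors(d, "y", c("twin", "noise"))
  expect_true("twin" %in% res$selected)
  expect_equal(res$log$rho[res$log$candidate == "twin" &
                             res$log$against == "y"], 1)
})

test_that("screening of pure noise selects at about the nominal rate", {
  set.seed(2)
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    d <- data.frame(y = rnorm(80), cand = rnorm(80))
    if (length(screen_predictors(d, "y", "cand")$selected)) hits <- hits + 1
  }
  band <- 2.576 * sqrt(reps * 0.05 * 0.95)
  expect_gte(hits, floor(reps * 0.05 - band))
  expect_lte(hits, ceiling(reps * 0.05 + band))
})

test_that("constant candidates are skipped with a warning", {
  d <- data.frame(y = rnorm(30), flat = 1)
  expect_warning(res <- screen_predictors(d, "y", "flat"), "constant")
  expect_length(res$selected, 0)
})

test_that("omnibus F and Stein's formula reproduce hand arithmetic", {
  f <- omnibus_f(0.271, 6, 80)
  expect_equal(f$f, (0.271 / 6) / ((1 - 0.271) / 73))
  expect_lt(abs(f$f - 4.52), 0.01)
  expect_lt(abs(omnibus_f(0.108, 4, 80)$f - 2.27), 0.01)
  expect_equal(omnibus_f(0, 3, 50)$f, 0)
  expect_error(omnibus_f(1, 3, 50), "r2")

  expect_equal(round(stein_adjusted_r2(0.271, 6, 80), 2), 0.13)
  expect_equal(stein_adjusted_r2(1, 6, 80), 1)
  expect_equal(stein_adjusted_r2(0, 6, 80),
               1 - (79 / 73) * (78 / 72) * (81 / 80), tolerance = 1e-12)
  expect_lt(stein_adjusted_r2(0, 6, 80), 0)
})

test_that("hierarchical steps report exact R-squared changes", {
  set.seed(3)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), z = rbinom(n, 1, 0.4))
  d$y <- 0.5 * d$x1 + 0.8 * d$z + rnorm(n)
  fit <- hierarchical_fit(d, "y", c("x1", "x2"), "z")
  s <- fit$steps
  expect_gte(s$step2$r2, s$step1$r2)
  expect_equal(s$step2$delta_r2, s$step2$r2 - s$step1$r2, tolerance = 1e-12)
  # F statistics agree with their R2-based closed forms
  expect_equal(s$step2$omnibus$f,
               omnibus_f(s$step2$r2, 3, fit$n)$f, tolerance = 1e-10)
  r2a <- s$step1$r2; r2b <- s$step2$r2
  expect_equal(s$step2$f_change$f,
               ((r2b - r2a) / 1) / ((1 - r2b) / (fit$n - 3 - 1)),
               tolerance = 1e-10)
})

test_that("a step-2 addition explains nothing when step 1 already fits", {
  set.seed(4)
  n <- 60
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), z = rnorm(n))
  d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(n, sd = 1e-7)
  fit <- hierarchical_fit(d, "y", c("x1", "x2"), "z")
  expect_lt(fit$steps$step2$delta_r2, 1e-8)
})

test_that("standardized beta is invariant to predictor rescaling", {
  set.seed(5)
  n <- 100
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- d$x1 - 0.5 * d$x2 + rnorm(n)
  f1 <- hierarchical_fit(d, "y", c("x1", "x2"))
  d2 <- d; d2$x1 <- d2$x1 * 100 + 7
  f2 <- hierarchical_fit(d2, "y", c("x1", "x2"))
  b1 <- f1$steps$step1$coefficients
  b2 <- f2$steps$step1$coefficients
  expect_equal(b1$beta[b1$term == "x1"], b2$beta[b2$term == "x1"],
               tolerance = 1e-10)
})

test_that("collinear designs fail loudly", {
  set.seed(6)
  d <- data.frame(x1 = rnorm(40))
  d$x2 <- 2 * d$x1
  d$y <- rnorm(40)
  expect_error(hierarchical_fit(d, "y", c("x1", "x2")), "collinear")
})

test_that("diagnostics: Durbin-Watson, VIF and tolerance behave as defined", {
  expect_equal(durbin_watson(c(1, 1, 1, 1)), 0)
  alt <- rep(c(2, -2), 50)
  expect_equal(durbin_watson(alt), sum(diff(alt)^2) / sum(alt^2))
  expect_gt(durbin_watson(alt), 3.9)

  # orthogonal predictors: VIF = tolerance = 1
  x1 <- rep(c(-1, 1), each = 20)
  x2 <- rep(c(-1, 1), times = 20)
  set.seed(7)
  d <- data.frame(x1 = x1, x2 = x2, y = rnorm(40))
  dg <- regression_diagnostics(lm(y ~ x1 + x2, d))
  expect_equal(unname(dg$vif), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(dg$tolerance * dg$vif), c(1, 1), tolerance = 1e-12)

  # correlated predictors: VIF >= 1 always
  d$x3 <- d$x1 + rnorm(40, sd = 0.6)
  dg2 <- regression_diagnostics(lm(y ~ x1 + x2 + x3, d))
  expect_true(all(dg2$vif >= 1))
  expect_true(all(c("max_cooks_distance", "max_abs_dfbeta", "ks_p") %in%
                    names(dg2)))
})

test_that("generating coefficients are recovered within sampling error", {
  set.seed(8)
  cover <- 0
  reps <- 100
  b_true <- c(2, 0.7, -0.4)
  for (r in seq_len(reps)) {
    n <- 150
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- b_true[1] + b_true[2] * d$x1 + b_true[3] * d$x2 + rnorm(n)
    co <- hierarchical_fit(d, "y", c("x1", "x2"))$steps$step1$coefficients
    ok <- abs(co$b - b_true) <= 3 * co$se_b
    if (all(ok)) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.95 - 2.576 * sqrt(0.05 * 0.95 / reps))
})

test_that("class dummies carry positive, ordered effects on the synthetic cohort", {
  cfg <- cohort_config(n_patients = 2000, seed = 23)
  b <- sample_baseline(cfg)
  mi <- morbidity_index(sample_visits(b, cfg))
  d <- merge(b, mi[mi$eligible, c("patient_id", "mi")])
  d$vulnerable <- as.integer(d$true_class == 2)
  d$highly_vulnerable <- as.integer(d$true_class == 3)
  scr <- screen_predictors(d, "mi", c("past_episodes", "true_class"))
  rho <- scr$log$rho[scr$log$against == "mi"]
  expect_true(all(rho > 0))  # illness history and class track the outcome
  fit <- hierarchical_fit(d, "mi",
                          c("comorbidity_count", "age_at_onset",
                            "past_episodes", "rapid_cycling"),
                          c("vulnerable", "highly_vulnerable"))
  co <- fit$steps$step2$coefficients
  b_v <- co$b[co$term == "vulnerable"]
  b_h <- co$b[co$term == "highly_vulnerable"]
  expect_gt(b_v, 0)
  expect_gt(b_h, b_v)
  expect_gt(fit$steps$step2$delta_r2, 0.05)
})
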