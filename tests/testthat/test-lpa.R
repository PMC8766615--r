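test_that("the 1-class fit is the closed-form normal MLE", {
  set.seed(1)
  x <- matrix(rnorm(120, mean = 2), 40, 3)
  m <- lpa_fit(x, 1)
  expect_equal(as.numeric(m$means), colMeans(x))
  expect_equal(unname(m$variances), unname(colMeans(sweep(x, 2, colMeans(x))^2)))
  ll <- sum(vapply(1:3, function(j)
    sum(dnorm(x[, j], mean(x[, j]),
              sqrt(mean((x[, j] - mean(x[, j]))^2)), log = TRUE)), 1))
  expect_equal(m$loglik, ll)
  # and EM from any start cannot improve on it
  m2 <- lpa_em(x, 1)
  expect_equal(m2$loglik, ll)
})

test_that("EM matches a direct-optimization oracle on a tiny instance", {
  set.seed(3)
  x <- rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
             matrix(rnorm(8, 5, 0.1), 4, 2))
  fit <- lpa_fit(x, 2, control = lpa_control(n_starts = 100, n_survivors = 20),
                 seed = 5)
  oracle <- oracle_mixture_loglik(x, 2)
  expect_lt(abs(fit$loglik - oracle), 1e-4)
})

test_that("EM agrees with the mclust EEI model on a moderate instance", {
  d <- draw_mixture(300, c(0.6, 0.4),
                    matrix(c(0, 0, 3, 3), 2, 2, byrow = TRUE),
                    c(1, 1), seed = 8)
  fit <- lpa_fit(d$x, 2, control = lpa_control(n_starts = 100), seed = 2)
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(d$x, G = 2, modelNames = "EEI", verbose = FALSE)
  # same constrained likelihood: we must do at least as well as the oracle
  # (up to its convergence tolerance) and land on the same optimum
  expect_gte(fit$loglik, mc$loglik - 1e-4)
  expect_lt(abs(fit$loglik - mc$loglik), 0.05)
})

test_that("the log-likelihood trace is non-decreasing", {
  set.seed(9)
  x <- matrix(rnorm(500), 100, 5)
  for (K in 2:3) {
    m <- lpa_fit(x, K, control = lpa_control(n_starts = 30, n_survivors = 5),
                 seed = K)
    expect_true(all(diff(m$trace) >= -1e-8))
  }
})

test_that("posterior rows and weights are proper probabilities", {
  d <- draw_mixture(200, table1_weights, table1_means(), table1_sds, seed = 4)
  m <- lpa_fit(d$x, 3, control = lpa_control(n_starts = 60), seed = 6)
  expect_equal(rowSums(m$posterior), rep(1, 200), tolerance = 1e-10)
  expect_equal(sum(m$weights), 1, tolerance = 1e-10)
  expect_true(all(m$posterior >= 0 & m$posterior <= 1))
  expect_true(all(m$variances >= 1e-6))
})

test_that("multi-start fitting is deterministic given a seed and improves with starts", {
  d <- draw_mixture(150, table1_weights, table1_means(), table1_sds, seed = 10)
  ctrl <- lpa_control(n_starts = 40, n_survivors = 8)
  a <- lpa_fit(d$x, 3, control = ctrl, seed = 77)
  b <- lpa_fit(d$x, 3, control = ctrl, seed = 77)
  expect_identical(a$loglik, b$loglik)
  expect_identical(a$means, b$means)
  # nested-start property: more starts from the same stream can only help
  few <- lpa_fit(d$x, 3, control = lpa_control(n_starts = 5, n_survivors = 5),
                 seed = 31)
  many <- lpa_fit(d$x, 3, control = lpa_control(n_starts = 50, n_survivors = 50),
                  seed = 31)
  expect_gte(many$loglik, few$loglik - 1e-8)
})

test_that("multi-start defaults echo the published optimisation settings", {
  ctrl <- lpa_control()
  expect_equal(ctrl$n_starts, 500L)
  expect_equal(ctrl$n_survivors, 50L)
  expect_equal(ctrl$burn_iters, 50L)
})

test_that("free-parameter counting follows p*K + p + (K-1)", {
  expect_equal(count_free_parameters(5, 3), 22L)
  expect_equal(count_free_parameters(5, 1), 10L)
  expect_equal(count_free_parameters(1, 1), 2L)
})

test_that("information criteria reproduce hand arithmetic", {
  ic <- information_criteria(-525.3, 16, 134)
  expect_equal(ic$aic, 1082.6)
  expect_equal(ic$bic, 1050.6 + 16 * log(134))
  expect_equal(ic$abic, 1050.6 + 16 * log(136 / 24))
  ic0 <- information_criteria(0, 0, 1)
  expect_equal(c(ic0$aic, ic0$bic, ic0$abic), c(0, 0, 0))
  expect_error(information_criteria(0, 0, 0), "n")
})

test_that("relative entropy behaves at its endpoints and on a hand example", {
  one_hot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(relative_entropy(one_hot), 1)
  uniform <- matrix(1 / 3, 5, 3)
  expect_equal(relative_entropy(uniform), 0)
  p <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1)) + log(2)
  expect_equal(relative_entropy(p), 1 - h / (2 * log(2)))
  expect_equal(round(relative_entropy(p), 4), 0.2655)
  expect_true(is.na(relative_entropy(matrix(1, 4, 1))))
})

test_that("modal classification takes the argmax with low-index ties", {
  expect_equal(classify_modal(rbind(c(0.7, 0.2, 0.1))), 1L)
  expect_equal(classify_modal(rbind(c(0.5, 0.5))), 1L)
  post <- matrix(runif(30), 10, 3)
  post <- post / rowSums(post)
  expect_length(classify_modal(post), 10)
})

test_that("canonical ordering sorts classes by neuroticism and keeps the likelihood", {
  d <- draw_mixture(400, table1_weights, table1_means(), table1_sds, seed = 12)
  m <- lpa_fit(d$x, 3, control = lpa_control(n_starts = 60), seed = 3,
               canonicalize = FALSE)
  ll_before <- m$loglik
  mc <- canonicalize_classes(m)
  expect_equal(mc$loglik, ll_before)
  expect_true(!is.unsorted(mc$means[, "neuroticism"]))
  # the low-neuroticism (resilient) class has the largest conscientiousness
  expect_equal(unname(which.max(mc$means[, "conscientiousness"])), 1L)
  expect_equal(rowSums(mc$posterior), rep(1, 400), tolerance = 1e-10)
})

test_that("class means and weights are recovered from a known 3-class model", {
  d <- draw_mixture(5000, table1_weights, table1_means(), table1_sds,
                    seed = 20)
  m <- lpa_fit(d$x, 3, control = lpa_control(n_starts = 100, n_survivors = 20),
               seed = 21)
  expect_lt(max(abs(m$means - table1_means())), 0.05)
  expect_lt(max(abs(m$weights - table1_weights)), 0.02)
})

test_that("the bootstrap LRT honours its p-value bound and detects separation", {
  set.seed(30)
  x <- matrix(rnorm(100 * 2), 100, 2)
  r <- bootstrap_lrt(x, 2, B = 19, seed = 1,
                     control = lpa_control(n_starts = 20, n_survivors = 5))
  expect_gte(r$p_value, 1 / 20)
  expect_lte(r$p_value, 1)
  expect_gte(r$observed_lr, -1e-6)

  # strongly separated two-class data: smallest attainable p in most runs
  hits <- 0
  for (s in 1:5) {
    d <- draw_mixture(300, c(0.5, 0.5), matrix(c(0, 0, 4, 4), 2, 2,
                                               byrow = TRUE), c(1, 1),
                      seed = 100 + s)
    r <- bootstrap_lrt(d$x, 2, B = 99, seed = s,
                       control = lpa_control(n_starts = 30, n_survivors = 5))
    if (r$p_value <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
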