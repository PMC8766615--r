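# Shared fixtures and independent oracles.

neo_cols <- c("neuroticism", "extraversion", "openness", "agreeableness",
              "conscientiousness")

# Draw n observations from a K-class diagonal Gaussian mixture with shared
# per-indicator SDs (the generating counterpart of the fitted model).
draw_mixture <- function(n, weights, means, sds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- sample.int(nrow(means), n, replace = TRUE, prob = weights)
  p <- ncol(means)
  x <- means[cls, , drop = FALSE] +
    matrix(rnorm(n * p, sd = rep(sds, each = n)), n, p)
  colnames(x) <- colnames(means)
  list(x = x, class = cls)
}

table1_means <- function() {
  matrix(c(1.44, 2.25, 2.36, 2.68, 2.85,
           2.39, 1.88, 2.54, 2.45, 2.31,
           3.10, 1.00, 2.25, 2.04, 1.55), nrow = 3, byrow = TRUE,
         dimnames = list(NULL, neo_cols))
}
table1_sds <- c(0.430, 0.493, 0.537, 0.397, 0.395)
table1_weights <- c(0.51, 0.41, 0.08)

# Direct maximisation of the constrained mixture log-likelihood with a
# generic numeric optimizer (independent of the EM path): weights through a
# softmax, variances through a log link.
oracle_mixture_loglik <- function(x, K, n_restarts = 20, seed = 1) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  loglik_fn <- function(par) {
    w_free <- par[seq_len(K - 1)]
    w <- exp(c(w_free, 0)); w <- w / sum(w)
    mu <- matrix(par[K:(K - 1 + K * p)], K, p)
    s2 <- exp(par[(K + K * p):(K - 1 + K * p + p)])
    ld <- sapply(seq_len(K), function(k)
      log(w[k]) + rowSums(sapply(seq_len(p), function(j)
        dnorm(x[, j], mu[k, j], sqrt(s2[j]), log = TRUE))))
    m <- apply(ld, 1, max)
    -sum(m + log(rowSums(exp(ld - m))))
  }
  best <- Inf
  for (r in seq_len(n_restarts)) {
    par0 <- c(rnorm(K - 1, 0, 0.5),
              apply(x, 2, function(v) runif(K, min(v), max(v))),
              log(apply(x, 2, var) * runif(p, 0.3, 1.5)))
    fit <- tryCatch(optim(par0, loglik_fn, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) best <- fit$value
  }
  -best
}

# Hand/rank-arithmetic Kruskal-Wallis H (tie-corrected), independent of
# kruskal.test.
oracle_kruskal_h <- function(values, group) {
  r <- rank(values)
  n <- length(values)
  groups <- split(r, group)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) sum(g)^2 / length(g), 1)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
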