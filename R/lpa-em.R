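#' Control parameters for the latent profile EM
#'
#' Collects the optimisation settings used by [lpa_fit()] and
#' [bootstrap_lrt()]. The multi-start scheme follows the common practice for
#' mixture models: many short random starts, of which the best by
#' log-likelihood are run to full convergence.
#'
#' @param n_starts number of random starting value sets (default 500).
#' @param n_survivors number of best starts (by log-likelihood after the burn
#'   phase) optimised to convergence (default 50).
#' @param burn_iters EM iterations run for every start before ranking
#'   (default 50).
#' @param tol absolute log-likelihood improvement below which EM stops
#'   (default 1e-6).
#' @param max_iter maximum EM iterations for a surviving start (default 1000).
#' @param var_floor lower bound for each indicator variance; estimates below
#'   it are clamped and flagged (default 1e-6).
#' @param empty_tol mixing weight below which a run is declared degenerate and
#'   discarded by the multi-start scheme (default 1e-8).
#' @return A list of class \code{lpa_control}.
#' @export
lpa_control <- function(n_starts = 500L, n_survivors = 50L, burn_iters = 50L,
                        tol = 1e-6, max_iter = 1000L, var_floor = 1e-6,
                        empty_tol = 1e-8) {
  stopifnot(n_starts >= 1, n_survivors >= 1, burn_iters >= 1,
            tol > 0, max_iter >= 1, var_floor > 0)
  structure(list(n_starts = as.integer(n_starts),
                 n_survivors = as.integer(min(n_survivors, n_starts)),
                 burn_iters = as.integer(burn_iters),
                 tol = tol, max_iter = as.integer(max_iter),
                 var_floor = var_floor, empty_tol = empty_tol),
            class = "lpa_control")
}

as_indicator_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("indicator data must be numeric")
  if (anyNA(x)) stop("indicator data must not contain missing values")
  if (is.null(colnames(x))) colnames(x) <- paste0("ind", seq_len(ncol(x)))
  x
}

new_lpa_model <- function(fit, x, K) {
  means <- fit$means
  dimnames(means) <- list(paste0("class", seq_len(K)), colnames(x))
  post <- fit$posterior
  colnames(post) <- paste0("class", seq_len(K))
  structure(list(K = K,
                 weights = as.numeric(fit$weights),
                 means = means,
                 variances = setNames(as.numeric(fit$variances), colnames(x)),
                 loglik = fit$loglik,
                 n = nrow(x),
                 posterior = post,
                 trace = fit$trace,
                 converged = isTRUE(fit$converged),
                 variance_floored = isTRUE(fit$variance_floored)),
            class = "lpa_model")
}

#' Single-start EM for the constrained latent profile model
#'
#' Fits a \code{K}-class Gaussian mixture to continuous indicators under the
#' latent-profile constraints: class-specific means, indicator variances
#' shared across classes, and zero covariance between indicators. The E-step
#' computes responsibilities from the current parameters (in log space); the
#' M-step updates weights, means and the pooled variances. The log-likelihood
#' is non-decreasing across iterations.
#'
#' @param x numeric matrix or data frame, observations in rows, indicators in
#'   columns; no missing values.
#' @param K number of latent classes.
#' @param start optional list with elements \code{weights} (length K),
#'   \code{means} (K x p) and \code{variances} (length p). Defaults to a
#'   quantile-based spread of the data.
#' @param control an [lpa_control()] list.
#' @return An object of class \code{lpa_model}: weights, class-by-indicator
#'   mean matrix, shared variances, log-likelihood, posterior responsibility
#'   matrix, and the per-iteration log-likelihood trace.
#' @export
lpa_em <- function(x, K, start = NULL, control = lpa_control()) {
  x <- as_indicator_matrix(x)
  K <- as.integer(K)
  stopifnot(K >= 1, nrow(x) > K)
  if (K == 1L) return(lpa_closed_form_k1(x))
  if (is.null(start)) {
    qs <- apply(x, 2, quantile, probs = seq(0.1, 0.9, length.out = K))
    start <- list(weights = rep(1 / K, K),
                  means = matrix(qs, nrow = K),
                  variances = apply(x, 2, function(v) mean((v - mean(v))^2)))
  }
  fit <- em_fit_cpp(x, as.numeric(start$weights),
                    matrix(as.numeric(start$means), nrow = K),
                    as.numeric(start$variances),
                    control$tol, control$max_iter, control$var_floor,
                    control$empty_tol)
  if (isTRUE(fit$degenerate))
    stop("EM collapsed to an empty class (degenerate start)")
  new_lpa_model(fit, x, K)
}

# K = 1 maximum likelihood in closed form: indicator means and the
# divide-by-n mean squared deviations; no EM iterations can improve it.
lpa_closed_form_k1 <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  s2 <- colMeans(sweep(x, 2, mu)^2)
  ll <- sum(vapply(seq_len(ncol(x)), function(j)
    sum(dnorm(x[, j], mu[j], sqrt(s2[j]), log = TRUE)), numeric(1)))
  fit <- list(weights = 1, means = matrix(mu, nrow = 1), variances = s2,
              loglik = ll,
              posterior = matrix(1, n, 1), trace = ll,
              converged = TRUE, variance_floored = FALSE)
  new_lpa_model(fit, x, 1L)
}

# Random start: means uniform within each indicator's observed range, weights
# uniform on the simplex, variances at the pooled data variances.
random_start <- function(x, K) {
  rng <- apply(x, 2, range)
  mu <- matrix(runif(K * ncol(x), rep(rng[1, ], each = K),
                     rep(rng[2, ], each = K)), nrow = K)
  w <- rexp(K)
  list(weights = w / sum(w), means = mu,
       variances = apply(x, 2, function(v) mean((v - mean(v))^2)))
}

#' Multi-start EM fit of a latent profile model
#'
#' Runs \code{n_starts} random initialisations for a fixed number of burn-in
#' EM iterations, keeps the \code{n_survivors} best by log-likelihood, runs
#' those to convergence, and returns the best final solution with classes in
#' canonical order (ascending neuroticism / first-indicator mean). The result
#' is deterministic given \code{seed}.
#'
#' @inheritParams lpa_em
#' @param seed integer seed for the random starts; the caller's RNG state is
#'   preserved.
#' @param canonicalize relabel classes via [canonicalize_classes()]
#'   (default TRUE).
#' @return An \code{lpa_model} (see [lpa_em()]).
#' @export
lpa_fit <- function(x, K, control = lpa_control(), seed = NULL,
                    canonicalize = TRUE) {
  x <- as_indicator_matrix(x)
  K <- as.integer(K)
  stopifnot(K >= 1, nrow(x) > K)
  if (K == 1L) return(lpa_closed_form_k1(x))
  fit <- with_seed(seed, {
    starts <- replicate(control$n_starts, random_start(x, K), simplify = FALSE)
    burns <- lapply(starts, function(s)
      em_fit_cpp(x, s$weights, s$means, s$variances, control$tol,
                 control$burn_iters, control$var_floor, control$empty_tol))
    ok <- !vapply(burns, function(b) isTRUE(b$degenerate), logical(1))
    if (!any(ok))
      stop("all ", control$n_starts, " starts collapsed; fitting failed for K = ", K)
    burns <- burns[ok]
    lls <- vapply(burns, function(b) b$loglik, numeric(1))
    keep <- order(lls, decreasing = TRUE)[seq_len(min(control$n_survivors,
                                                      length(burns)))]
    finals <- lapply(burns[keep], function(b) {
      f <- em_fit_cpp(x, b$weights, b$means, b$variances, control$tol,
                      control$max_iter, control$var_floor, control$empty_tol)
      if (isTRUE(f$degenerate)) NULL else f
    })
    finals <- Filter(Negate(is.null), finals)
    if (!length(finals))
      stop("all surviving starts collapsed; fitting failed for K = ", K)
    finals[[which.max(vapply(finals, function(f) f$loglik, numeric(1)))]]
  })
  out <- new_lpa_model(fit, x, K)
  if (canonicalize) out <- canonicalize_classes(out) else out
}

#' @export
print.lpa_model <- function(x, ...) {
  cat(sprintf("Latent profile model: %d class(es), n = %d, logLik = %.3f\n",
              x$K, x$n, x$loglik))
  cat("Class weights:", sprintf("%.3f", x$weights), "\n")
  cat("Class means:\n")
  print(round(x$means, 3))
  cat("Shared variances:\n")
  print(round(x$variances, 4))
  invisible(x)
}

#' Free parameters of a constrained latent profile model
#'
#' Class-specific means (\code{p * K}), shared indicator variances (\code{p})
#' and free mixing weights (\code{K - 1}).
#'
#' @param n_indicators number of continuous indicators \code{p}.
#' @param K number of latent classes.
#' @return Integer count \code{p*K + p + (K - 1)}.
#' @export
count_free_parameters <- function(n_indicators, K) {
  stopifnot(n_indicators >= 1, K >= 1)
  as.integer(n_indicators * K + n_indicators + (K - 1))
}

#' Information criteria for a fitted mixture
#'
#' @param loglik maximised log-likelihood.
#' @param fp number of free parameters.
#' @param n sample size.
#' @return Named list with \code{aic} (\code{-2 LL + 2 fp}), \code{bic}
#'   (\code{-2 LL + fp log n}) and \code{abic}, the sample-size-adjusted BIC
#'   using the effective sample size \code{(n + 2) / 24}.
#' @export
information_criteria <- function(loglik, fp, n) {
  if (n < 1) stop("n must be at least 1")
  list(aic = -2 * loglik + 2 * fp,
       bic = -2 * loglik + fp * log(n),
       abic = -2 * loglik + fp * log((n + 2) / 24))
}

#' Relative entropy of a posterior classification
#'
#' \code{1 - sum_i sum_k (-p_ik log p_ik) / (n log K)}, with
#' \code{0 log 0 := 0}. 1 means perfectly separated classes, 0 an
#' uninformative classification. Undefined for a 1-class model.
#'
#' @param posterior n x K matrix of posterior class probabilities.
#' @return A number in \[0, 1\], or \code{NA} for K = 1.
#' @export
relative_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  K <- ncol(posterior)
  if (K < 2) return(NA_real_)
  h <- -posterior * log(posterior)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (nrow(posterior) * log(K))
}

#' Modal class assignment
#'
#' Assigns each observation to its highest-posterior class; exact ties go to
#' the lowest class index.
#'
#' @param posterior n x K posterior matrix.
#' @return Integer vector of class labels in \code{1..K}.
#' @export
classify_modal <- function(posterior) {
  posterior <- as.matrix(posterior)
  apply(posterior, 1, which.max)
}

#' Canonical class ordering
#'
#' Relabels classes in ascending order of the first indicator's class mean
#' (neuroticism when the indicators are the NEO-FFI scales), so class 1 is
#' the low-neuroticism "resilient" profile and class K the most vulnerable.
#' Exact ties fall back to descending mean of the last indicator
#' (conscientiousness). The likelihood is invariant under the relabelling.
#'
#' @param model an \code{lpa_model}.
#' @param order_by indicator used for ordering (default first column).
#' @return The model with weights, means and posterior columns permuted.
#' @export
canonicalize_classes <- function(model, order_by = 1L) {
  stopifnot(inherits(model, "lpa_model"))
  if (model$K == 1L) return(model)
  key <- model$means[, order_by]
  tie_break <- -model$means[, ncol(model$means)]
  perm <- order(key, tie_break)
  model$weights <- model$weights[perm]
  model$means <- model$means[perm, , drop = FALSE]
  rownames(model$means) <- paste0("class", seq_len(model$K))
  model$posterior <- model$posterior[, perm, drop = FALSE]
  colnames(model$posterior) <- paste0("class", seq_len(model$K))
  model
}
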