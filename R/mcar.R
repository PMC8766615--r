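# Maximum-likelihood mean and covariance of a multivariate normal with
# missing entries, by EM over missingness patterns (E-step: conditional
# means/covariances of the missing block given the observed block).
mvn_em <- function(X, max_iter = 200L, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu)) stop("some variable has no observed values")
  S <- cov(X, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  diag(S)[diag(S) <= 0] <- 1
  pat <- apply(is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  for (it in seq_len(max_iter)) {
    sumx <- numeric(p)
    sumxx <- matrix(0, p, p)
    for (rows in groups) {
      miss <- is.na(X[rows[1], ])
      Xg <- X[rows, , drop = FALSE]
      ng <- length(rows)
      if (!any(miss)) {
        sumx <- sumx + colSums(Xg)
        sumxx <- sumxx + crossprod(Xg)
        next
      }
      o <- which(!miss); m <- which(miss)
      if (!length(o)) {
        # nothing observed: the row contributes the marginal moments
        sumx <- sumx + ng * mu
        sumxx <- sumxx + ng * (S + tcrossprod(mu))
        next
      }
      Soo_inv_Som <- solve(S[o, o, drop = FALSE], S[o, m, drop = FALSE])
      C <- S[m, m, drop = FALSE] - crossprod(S[o, m, drop = FALSE],
                                             Soo_inv_Som)
      Xo <- Xg[, o, drop = FALSE]
      Xm_hat <- matrix(mu[m], ng, length(m), byrow = TRUE) +
        sweep(Xo, 2, mu[o]) %*% Soo_inv_Som
      Xc <- matrix(0, ng, p)
      Xc[, o] <- Xo; Xc[, m] <- Xm_hat
      sumx <- sumx + colSums(Xc)
      xx <- crossprod(Xc)
      xx[m, m] <- xx[m, m] + ng * C
      sumxx <- sumxx + xx
    }
    mu_new <- sumx / n
    S_new <- sumxx / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(S_new - S))
    mu <- mu_new; S <- S_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = S, iterations = it)
}

#' Little's omnibus test of missing completely at random
#'
#' Tests whether the observed-variable means of each missingness pattern are
#' consistent with a single multivariate normal: the grand mean and
#' covariance are estimated by EM under normality, and the statistic
#' \code{d^2 = sum_j n_j (xbar_j - mu_j)' Sigma_j^{-1} (xbar_j - mu_j)}
#' accumulates the Mahalanobis distances of the pattern-wise observed means
#' (subscript j restricting to the pattern's observed variables). Under MCAR
#' \code{d^2} is asymptotically chi-squared with \code{sum_j p_j - p} degrees
#' of freedom. A significant result argues against MCAR.
#'
#' @param data numeric matrix or data frame with \code{NA} for missing
#'   entries.
#' @return A \code{group_test_result} with the chi-squared statistic, df and
#'   p-value (\code{p = 1} when df = 0, e.g. complete data); patterns whose
#'   restricted covariance is singular are dropped with a warning.
#' @export
little_mcar <- function(data) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("data must be numeric")
  keep <- rowSums(!is.na(X)) > 0
  X <- X[keep, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  est <- mvn_em(X)
  pat <- apply(is.na(X), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  d2 <- 0
  df <- -p
  dropped <- 0L
  for (rows in groups) {
    o <- which(!is.na(X[rows[1], ]))
    xbar <- colMeans(X[rows, o, drop = FALSE])
    diffv <- xbar - est$mu[o]
    q <- tryCatch(drop(crossprod(diffv,
                                 solve(est$sigma[o, o, drop = FALSE], diffv))),
                  error = function(e) NA_real_)
    if (is.na(q)) {
      dropped <- dropped + 1L
      next
    }
    d2 <- d2 + length(rows) * q
    df <- df + length(o)
  }
  if (dropped > 0)
    warning(dropped, " missingness pattern(s) dropped (singular restricted ",
            "covariance)")
  df <- max(df, 0L)
  p_value <- if (df == 0) 1 else pchisq(d2, df, lower.tail = FALSE)
  group_test_result("Little's MCAR test", statistic = d2, df = df,
                    p_value = p_value, effect_size = NA_real_,
                    effect_size_type = "none",
                    n_patterns = length(groups), dropped_patterns = dropped)
}
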