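#' Screen candidate predictors by Spearman correlation
#'
#' A candidate enters the model if its Spearman rank correlation with the
#' outcome, or with any already-selected predictor, is significant at
#' \code{alpha}. Candidates are examined in the given order (the a-priori
#' clinical list first); constant candidates are skipped with a warning.
#' Correlations use pairwise-complete cases.
#'
#' @param data data frame holding outcome and candidates.
#' @param outcome name of the outcome column.
#' @param candidates character vector of candidate predictor columns.
#' @param alpha significance level for selection (default 0.05).
#' @param min_pairs minimum pairwise-complete cases per correlation
#'   (default 10).
#' @return List: \code{selected} (character vector) and \code{log}, a data
#'   frame of every correlation examined (candidate, against, rho, p,
#'   n, selected).
#' @export
screen_predictors <- function(data, outcome, candidates, alpha = 0.05,
                              min_pairs = 10L) {
  stopifnot(outcome %in% names(data), all(candidates %in% names(data)))
  selected <- character(0)
  log_rows <- list()
  spearman <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_pairs)
      return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- suppressWarnings(cor.test(a[ok], b[ok], method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  for (cand in candidates) {
    v <- data[[cand]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("candidate '", cand, "' is constant; skipped")
      next
    }
    hit <- FALSE
    for (against in c(outcome, selected)) {
      r <- spearman(v, data[[against]])
      sel_now <- !is.na(r$p) && r$p < alpha
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(candidate = cand, against = against, rho = r$rho,
                   p = r$p, n = r$n, stringsAsFactors = FALSE)
      if (sel_now) { hit <- TRUE; break }
    }
    if (hit) selected <- c(selected, cand)
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(candidate = character(0), against = character(0),
               rho = numeric(0), p = numeric(0), n = integer(0))
  log_df$selected <- log_df$candidate %in% selected
  list(selected = selected, log = log_df)
}

#' Omnibus F statistic from R-squared
#'
#' \code{F = (R^2 / k) / ((1 - R^2) / (n - k - 1))} on \code{(k, n - k - 1)}
#' degrees of freedom.
#'
#' @param r2 coefficient of determination in \[0, 1).
#' @param k number of predictors.
#' @param n sample size.
#' @return List with \code{f}, \code{df1}, \code{df2}, \code{p}.
#' @export
omnibus_f <- function(r2, k, n) {
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  if (n <= k + 1) stop("n must exceed k + 1")
  f <- (r2 / k) / ((1 - r2) / (n - k - 1))
  list(f = f, df1 = k, df2 = n - k - 1,
       p = pf(f, k, n - k - 1, lower.tail = FALSE))
}

#' Stein's adjusted R-squared
#'
#' Shrinkage estimate of the cross-validated squared multiple correlation:
#' \code{1 - [(n-1)/(n-k-1)] [(n-2)/(n-k-2)] [(n+1)/n] (1 - R^2)}.
#'
#' @inheritParams omnibus_f
#' @return Numeric adjusted R-squared (can fall below 0).
#' @export
stein_adjusted_r2 <- function(r2, k, n) {
  if (n <= k + 2) stop("n must exceed k + 2")
  1 - ((n - 1) / (n - k - 1)) * ((n - 2) / (n - k - 2)) * ((n + 1) / n) *
    (1 - r2)
}

coefficient_table <- function(fit, data, outcome) {
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- confint(fit)
  sd_y <- sd(data[[outcome]])
  beta <- vapply(rownames(co), function(nm) {
    if (nm == "(Intercept)") return(NA_real_)
    unname(co[nm, "Estimate"]) * sd(model.matrix(fit)[, nm]) / sd_y
  }, numeric(1))
  data.frame(term = rownames(co), b = co[, "Estimate"],
             se_b = co[, "Std. Error"], beta = beta,
             t = co[, "t value"], p = co[, "Pr(>|t|)"],
             ci_lower = ci[, 1], ci_upper = ci[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-step hierarchical regression of the Morbidity Index
#'
#' Step 1 regresses the outcome on the clinical predictors by ordinary least
#' squares; step 2 adds further predictors (typically the dummy-coded
#' personality classes with the resilient class as reference). Cases are
#' deleted listwise across all variables so both steps use the same sample.
#' Reports per-step coefficient tables (B, SE, standardized beta, t, p, 95
#' percent CI), R-squared, the R-squared change with its F test, the omnibus
#' F, and the diagnostics block of [regression_diagnostics()].
#'
#' @param data data frame with outcome and predictors.
#' @param outcome outcome column name.
#' @param step1 character vector of step-1 predictor columns.
#' @param step2 character vector of predictors added in step 2; may be empty,
#'   in which case step 2 is skipped with a message.
#' @return List of class \code{hierarchical_fit}: \code{steps} (per-step list
#'   with \code{coefficients}, \code{r2}, \code{delta_r2}, \code{f_change},
#'   \code{omnibus}), \code{fit1}, \code{fit2}, \code{n},
#'   \code{diagnostics}, \code{stein_r2}.
#' @export
hierarchical_fit <- function(data, outcome, step1, step2 = character(0)) {
  vars <- c(outcome, step1, step2)
  stopifnot(all(vars %in% names(data)))
  cc <- data[complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(cc)
  k_full <- length(step1) + length(step2)
  if (n <= k_full + 2) stop("too few complete cases for the full model")
  qr_x <- qr(scale(as.matrix(cc[, c(step1, step2), drop = FALSE])))
  if (qr_x$rank < k_full) {
    bad <- setdiff(c(step1, step2),
                   c(step1, step2)[qr_x$pivot[seq_len(qr_x$rank)]])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  form1 <- as.formula(paste(outcome, "~",
                            paste(step1, collapse = " + ")))
  fit1 <- lm(form1, data = cc)
  r2_1 <- summary(fit1)$r.squared
  k1 <- length(step1)
  steps <- list(step1 = list(coefficients = coefficient_table(fit1, cc, outcome),
                             r2 = r2_1, delta_r2 = r2_1,
                             f_change = omnibus_f(r2_1, k1, n),
                             omnibus = omnibus_f(r2_1, k1, n)))
  fit2 <- NULL
  if (length(step2)) {
    form2 <- as.formula(paste(outcome, "~",
                              paste(c(step1, step2), collapse = " + ")))
    fit2 <- lm(form2, data = cc)
    r2_2 <- summary(fit2)$r.squared
    q <- length(step2)
    f_change <- ((r2_2 - r2_1) / q) / ((1 - r2_2) / (n - k_full - 1))
    steps$step2 <- list(coefficients = coefficient_table(fit2, cc, outcome),
                        r2 = r2_2, delta_r2 = r2_2 - r2_1,
                        f_change = list(f = f_change, df1 = q,
                                        df2 = n - k_full - 1,
                                        p = pf(f_change, q, n - k_full - 1,
                                               lower.tail = FALSE)),
                        omnibus = omnibus_f(r2_2, k_full, n))
  } else {
    message("no step-2 predictors supplied; step 2 skipped")
  }
  final <- if (is.null(fit2)) fit1 else fit2
  final_k <- if (is.null(fit2)) k1 else k_full
  final_r2 <- if (is.null(fit2)) r2_1 else summary(fit2)$r.squared
  structure(list(steps = steps, fit1 = fit1, fit2 = fit2, n = n,
                 diagnostics = regression_diagnostics(final),
                 stein_r2 = stein_adjusted_r2(final_r2, final_k, n)),
            class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat(sprintf("%s: R2 = %.3f, dR2 = %.3f, F(%d,%d) = %.2f, p = %.4g\n",
                nm, s$r2, s$delta_r2, s$f_change$df1, s$f_change$df2,
                s$f_change$f, s$f_change$p))
    tab <- s$coefficients
    tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
    print(tab, row.names = FALSE)
  }
  cat(sprintf("n = %d, Stein adjusted R2 = %.3f\n", x$n, x$stein_r2))
  invisible(x)
}

#' Durbin-Watson statistic
#'
#' \code{d = sum (e_t - e_\{t-1\})^2 / sum e_t^2}; values near 2 indicate
#' uncorrelated residuals, near 0 positive and near 4 negative first-order
#' autocorrelation.
#'
#' @param residuals numeric residual vector in case order.
#' @return Numeric d.
#' @export
durbin_watson <- function(residuals) {
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Regression diagnostics block
#'
#' The residual, influence and collinearity checks reported with the course
#' regression: count and fraction of absolute externally studentized
#' residuals beyond 1.96, maximum Cook's distance, maximum absolute
#' standardized DFBeta, Durbin-Watson d, a Lilliefors-corrected
#' Kolmogorov-Smirnov normality test of the standardized residuals, and
#' per-predictor tolerance / variance inflation factors with their mean.
#'
#' @param fit an \code{lm} fit with at least one predictor.
#' @return List of class \code{regression_diagnostics}.
#' @export
regression_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "lm"))
  rs <- rstudent(fit)
  rz <- rstandard(fit)
  dfb <- dfbetas(fit)
  ks <- nortest::lillie.test(rz)
  k <- length(coef(fit)) - 1
  vifs <- if (k >= 2) {
    v <- car::vif(fit)
    if (!is.null(dim(v))) v <- v[, 1]
    v
  } else if (k == 1) {
    setNames(1, names(coef(fit))[2])
  } else stop("model has no predictors")
  structure(list(
    n = length(rs),
    studentized_gt_196 = sum(abs(rs) > 1.96),
    studentized_gt_196_pct = 100 * mean(abs(rs) > 1.96),
    max_cooks_distance = max(cooks.distance(fit)),
    max_abs_dfbeta = max(abs(dfb)),
    durbin_watson = durbin_watson(resid(fit)),
    ks_statistic = unname(ks$statistic),
    ks_p = ks$p.value,
    vif = vifs,
    tolerance = 1 / vifs,
    mean_vif = mean(vifs)), class = "regression_diagnostics")
}

#' @export
print.regression_diagnostics <- function(x, ...) {
  cat(sprintf("Residuals |t| > 1.96: %d of %d (%.1f%%)\n",
              x$studentized_gt_196, x$n, x$studentized_gt_196_pct))
  cat(sprintf("Max Cook's distance: %.3f; max |std DFBeta|: %.3f\n",
              x$max_cooks_distance, x$max_abs_dfbeta))
  cat(sprintf("Durbin-Watson d = %.3f; KS D = %.3f (p = %.3f)\n",
              x$durbin_watson, x$ks_statistic, x$ks_p))
  cat(sprintf("Mean VIF = %.3f; min tolerance = %.3f\n",
              x$mean_vif, min(x$tolerance)))
  invisible(x)
}
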