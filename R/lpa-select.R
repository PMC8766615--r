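#' Fit a sequence of latent profile models and tabulate fit indices
#'
#' Fits models with \code{K} in \code{k_range} by multi-start EM and returns
#' the model-selection table: free parameters, log-likelihood, relative
#' entropy (blank for 1 class), AIC, BIC, sample-size-adjusted BIC, and
#' optionally the parametric bootstrap likelihood ratio test p-value for
#' K vs K-1 classes.
#'
#' @inheritParams lpa_fit
#' @param k_range integer vector of class counts to fit (default \code{1:6}).
#' @param blrt logical; run [bootstrap_lrt()] for each K > min(k_range)?
#' @param blrt_B bootstrap replicates for the BLRT (default 99).
#' @param blrt_control [lpa_control()] used inside bootstrap replicates;
#'   defaults to a lighter multi-start than the observed-data fits.
#' @return A list of class \code{lpa_selection} with elements \code{table}
#'   (data frame, one row per K), \code{models} (named list of
#'   \code{lpa_model}s) and \code{best_bic} (K minimising BIC).
#' @export
lpa_select <- function(x, k_range = 1:6, control = lpa_control(), seed = NULL,
                       blrt = FALSE, blrt_B = 99L,
                       blrt_control = lpa_control(n_starts = 20L,
                                                  n_survivors = 5L,
                                                  burn_iters = 20L)) {
  x <- as_indicator_matrix(x)
  k_range <- sort(as.integer(k_range))
  models <- lapply(k_range, function(K)
    lpa_fit(x, K, control = control, seed = stage_seed(seed, paste0("fit", K))))
  names(models) <- paste0("K", k_range)
  n <- nrow(x)
  p <- ncol(x)
  rows <- lapply(seq_along(k_range), function(i) {
    m <- models[[i]]
    fp <- count_free_parameters(p, m$K)
    ic <- information_criteria(m$loglik, fp, n)
    data.frame(model = paste0(m$K, "-class"), K = m$K, fp = fp,
               loglik = m$loglik,
               entropy = relative_entropy(m$posterior),
               aic = ic$aic, bic = ic$bic, abic = ic$abic,
               blrt_p = NA_real_)
  })
  tab <- do.call(rbind, rows)
  if (blrt) {
    for (i in seq_along(k_range)[-1]) {
      if (k_range[i] - k_range[i - 1] != 1L) next
      res <- bootstrap_lrt(x, K = k_range[i], B = blrt_B,
                           seed = stage_seed(seed, paste0("blrt", k_range[i])),
                           control = control, replicate_control = blrt_control,
                           fitted = list(null = models[[i - 1]],
                                         alt = models[[i]]))
      tab$blrt_p[i] <- res$p_value
    }
  }
  structure(list(table = tab, models = models,
                 best_bic = tab$K[which.min(tab$bic)]),
            class = "lpa_selection")
}

#' @export
print.lpa_selection <- function(x, ...) {
  tab <- x$table
  tab$loglik <- round(tab$loglik, 1)
  tab$entropy <- round(tab$entropy, 3)
  tab[c("aic", "bic", "abic")] <- round(tab[c("aic", "bic", "abic")], 1)
  print(tab, row.names = FALSE)
  cat("Lowest BIC at K =", x$best_bic, "\n")
  invisible(x)
}

# Draw n observations from a fitted latent profile model.
simulate_lpa_model <- function(model, n) {
  cls <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
  p <- ncol(model$means)
  x <- model$means[cls, , drop = FALSE] +
    matrix(rnorm(n * p, sd = rep(sqrt(model$variances), each = n)), n, p)
  colnames(x) <- colnames(model$means)
  x
}

#' Parametric bootstrap likelihood ratio test for K vs K-1 classes
#'
#' The observed statistic is \code{2 * (LL_K - LL_{K-1})} on the data. The
#' null distribution is built by simulating \code{B} data sets from the
#' fitted (K-1)-class model, fitting both models to each replicate, and
#' recording the replicate statistic. The p-value uses the add-one estimator
#' \code{(1 + #\{replicate >= observed\}) / (B + 1)}, so it is never below
#' \code{1/(B+1)}.
#'
#' Replicates whose fits collapse are redrawn (counted in
#' \code{n_redraws}); more than 20\% failures aborts with a diagnostic.
#'
#' @inheritParams lpa_fit
#' @param K the larger class count tested (\code{K >= 2}).
#' @param B number of bootstrap replicates.
#' @param replicate_control [lpa_control()] for the replicate fits; lighter
#'   than the observed-data fits by default.
#' @param fitted optional list with pre-fitted \code{null} ((K-1)-class) and
#'   \code{alt} (K-class) models on \code{x}, to avoid refitting.
#' @return List of class \code{blrt_result}: \code{observed_lr}, \code{B},
#'   \code{p_value}, \code{null_lrs}, \code{n_redraws}.
#' @export
bootstrap_lrt <- function(x, K, B = 99L, seed = NULL,
                          control = lpa_control(),
                          replicate_control = lpa_control(n_starts = 20L,
                                                          n_survivors = 5L,
                                                          burn_iters = 20L),
                          fitted = NULL) {
  x <- as_indicator_matrix(x)
  K <- as.integer(K)
  stopifnot(K >= 2)
  null_model <- fitted$null %||%
    lpa_fit(x, K - 1L, control = control, seed = stage_seed(seed, "null"))
  alt_model <- fitted$alt %||%
    lpa_fit(x, K, control = control, seed = stage_seed(seed, "alt"))
  observed <- 2 * (alt_model$loglik - null_model$loglik)
  n <- nrow(x)
  with_seed(stage_seed(seed, "boot"), {
    lrs <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        xb <- simulate_lpa_model(null_model, n)
        lr <- tryCatch({
          f0 <- lpa_fit(xb, K - 1L, control = replicate_control,
                        canonicalize = FALSE)
          f1 <- lpa_fit(xb, K, control = replicate_control,
                        canonicalize = FALSE)
          2 * (f1$loglik - f0$loglik)
        }, error = function(e) NA_real_)
        if (!is.na(lr)) break
        redraws <- redraws + 1L
        if (redraws > 0.2 * B)
          stop("more than 20% of bootstrap replicates failed to fit; ",
               "aborting BLRT for K = ", K)
      }
      lrs[b] <- lr
    }
    structure(list(observed_lr = observed, B = B,
                   p_value = (1 + sum(lrs >= observed)) / (B + 1),
                   null_lrs = lrs, n_redraws = redraws),
              class = "blrt_result")
  })
}

#' @export
print.blrt_result <- function(x, ...) {
  cat(sprintf("Bootstrap LRT: 2*dLL = %.3f, B = %d, p = %.4f (redraws: %d)\n",
              x$observed_lr, x$B, x$p_value, x$n_redraws))
  invisible(x)
}
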