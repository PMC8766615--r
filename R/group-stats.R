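group_test_result <- function(test_name, statistic, df, p_value, effect_size,
                              effect_size_type, ...) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 effect_size_type = effect_size_type, ...),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g, %s = %.3f\n",
              x$test_name, x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value, x$effect_size_type, x$effect_size))
  invisible(x)
}

#' One-way ANOVA with omega-squared effect size
#'
#' Omnibus F test across classes for variables treated as parametric, with
#' \code{omega^2 = (SS_between - (k-1) MS_within) / (SS_total + MS_within)}.
#' Omega-squared is negative whenever F < 1.
#'
#' @param values numeric outcome.
#' @param group class labels (coerced to factor).
#' @return A \code{group_test_result} with effect size type \code{eta2}
#'   replaced by \code{omega2}.
#' @export
anova_omega2 <- function(values, group) {
  group <- factor(group)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  k <- nlevels(group); n <- length(values)
  if (k < 2 || any(table(group) < 2))
    stop("need at least 2 groups with at least 2 values each")
  fit <- aov(values ~ group)
  tab <- suppressWarnings(anova(fit))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  msw <- tab$`Mean Sq`[2]
  flagged <- FALSE
  if (msw <= .Machine$double.eps * (ssb + ssw + 1)) {
    # zero within-group variance everywhere: effect size undefined
    omega2 <- 0
    flagged <- TRUE
  } else {
    omega2 <- (ssb - (k - 1) * msw) / (ssb + ssw + msw)
  }
  group_test_result("ANOVA", statistic = tab$`F value`[1],
                    df = c(k - 1, n - k), p_value = tab$`Pr(>F)`[1],
                    effect_size = omega2, effect_size_type = "omega2",
                    zero_variance = flagged)
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Tie-corrected H statistic with df = k - 1 and the asymptotic chi-squared
#' p-value. The H-based effect size \code{eta^2 = (H - k + 1) / (n - k)} is
#' floored at 0 for reporting (the raw value is kept in
#' \code{eta2_raw}).
#'
#' @inheritParams anova_omega2
#' @return A \code{group_test_result}.
#' @export
kruskal_wallis_eta2 <- function(values, group) {
  group <- factor(group)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  k <- nlevels(group); n <- length(values)
  if (k < 2) stop("need at least 2 groups")
  kt <- kruskal.test(values, group)
  h <- unname(kt$statistic)
  if (is.nan(h)) h <- 0  # all values tied: no rank variation at all
  eta2_raw <- (h - k + 1) / (n - k)
  group_test_result("Kruskal-Wallis", statistic = h, df = k - 1,
                    p_value = if (is.nan(kt$p.value)) 1 else kt$p.value,
                    effect_size = max(eta2_raw, 0),
                    effect_size_type = "eta2", eta2_raw = eta2_raw)
}

#' Mann-Whitney post hoc comparison with Bonferroni correction
#'
#' Two-group rank test used for pairwise follow-ups after a significant
#' Kruskal-Wallis test. Reports the U statistic, the tie-corrected
#' normal-approximation Z, the Bonferroni-adjusted p-value (raw p times the
#' number of comparisons, capped at 1), and the effect size
#' \code{r = |Z| / sqrt(n1 + n2)}.
#'
#' @param x,y numeric values of the two classes.
#' @param n_comparisons number of post hoc comparisons for the Bonferroni
#'   correction (default 1 = no correction).
#' @return A \code{group_test_result}; \code{p_value} is the adjusted one,
#'   \code{p_raw} the unadjusted.
#' @export
mann_whitney_posthoc <- function(x, y, n_comparisons = 1L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  u <- unname(suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                           correct = FALSE))$statistic)
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  var_u <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (var_u > 0) (u - n1 * n2 / 2) / sqrt(var_u) else 0
  p_raw <- 2 * pnorm(-abs(z))
  group_test_result("Mann-Whitney U", statistic = u, df = NA_real_,
                    p_value = min(1, p_raw * n_comparisons),
                    effect_size = abs(z) / sqrt(n), effect_size_type = "r",
                    z = z, p_raw = p_raw, n = c(n1 = n1, n2 = n2))
}

#' Freeman-Halton exact test for an r x c contingency table
#'
#' Exact conditional test of independence: the p-value sums the
#' hypergeometric probabilities of every table with the observed margins
#' whose probability does not exceed that of the observed table (the r x c
#' generalisation of Fisher's exact test). Tables whose total exceeds
#' \code{exact_budget} fall back to Monte-Carlo estimation with a reported
#' simulation standard error.
#'
#' @param tab matrix of non-negative integer counts.
#' @param exact_budget largest table total enumerated exactly (default 200).
#' @param mc_B Monte-Carlo tables for the fallback (default 1e5).
#' @param seed seed for the Monte-Carlo fallback.
#' @return A \code{group_test_result}; for the Monte-Carlo path,
#'   \code{mc_se} holds the simulation SE.
#' @export
freeman_halton_exact <- function(tab, exact_budget = 200L, mc_B = 1e5L,
                                 seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty margin")
  total <- sum(tab)
  if (total <= exact_budget) {
    p <- fisher.test(tab, workspace = 2e7)$p.value
    mc_se <- NA_real_
    method <- "exact"
  } else {
    p <- with_seed(stage_seed(seed, "fh_mc"),
                   fisher.test(tab, simulate.p.value = TRUE, B = mc_B)$p.value)
    mc_se <- sqrt(p * (1 - p) / mc_B)
    method <- "monte_carlo"
  }
  group_test_result("Freeman-Halton exact", statistic = NA_real_,
                    df = NA_real_, p_value = min(p, 1),
                    effect_size = if (min(dim(tab)) >= 2) cramers_v(tab)
                                  else NA_real_,
                    effect_size_type = "cramers_v", method = method,
                    mc_se = mc_se)
}

#' Cramer's V association measure
#'
#' \code{V = sqrt(chi^2 / (n (min(r, c) - 1)))} with the Pearson chi-squared
#' statistic (no continuity correction). Lies in \[0, 1\] and is invariant to
#' row/column permutation.
#'
#' @param tab contingency table (matrix), at least 2 x 2.
#' @return Numeric V.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("Cramer's V is undefined for a single row or column")
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  sqrt(unname(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

#' Class-validation battery for a labelled baseline table
#'
#' Runs the per-variable omnibus test across latent classes: exact
#' contingency tests with Cramer's V for binary variables, one-way ANOVA
#' with omega-squared for variables configured as parametric, and
#' Kruskal-Wallis with eta-squared otherwise. Which variables are treated as
#' parametric is configuration, not hard-coded.
#'
#' @param data baseline table including a class column.
#' @param class_col name of the class-label column (default
#'   \code{"class"}).
#' @param variables named character vector mapping variable names to
#'   \code{"binary"}, \code{"parametric"} or \code{"nonparametric"}.
#'   Defaults to the standard clinical battery when those columns exist.
#' @return Data frame: variable, test, statistic, df, p_value, effect_size,
#'   effect_size_type.
#' @export
validate_classes <- function(data, class_col = "class",
                             variables = default_validation_variables()) {
  cls <- data[[class_col]]
  if (is.null(cls)) stop("class column '", class_col, "' not found")
  variables <- variables[names(variables) %in% names(data)]
  rows <- lapply(names(variables), function(v) {
    type <- variables[[v]]
    res <- tryCatch(switch(type,
      binary = freeman_halton_exact(table(data[[v]], cls)),
      parametric = anova_omega2(data[[v]], cls),
      nonparametric = kruskal_wallis_eta2(data[[v]], cls),
      stop("unknown variable type: ", type)), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(variable = v, test = res$test_name,
               statistic = res$statistic,
               df = paste(signif(res$df, 6), collapse = ","),
               p_value = res$p_value, effect_size = res$effect_size,
               effect_size_type = res$effect_size_type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' @rdname validate_classes
#' @export
default_validation_variables <- function() {
  c(bipolar_I = "binary", gender_female = "binary", employment = "binary",
    relationship = "binary", alcohol = "binary", drugs = "binary",
    rapid_cycling = "binary", attempted_suicide = "binary",
    age_years = "parametric", education_years = "nonparametric",
    comorbidity_count = "nonparametric", medication_groups = "nonparametric",
    age_at_onset = "nonparametric", past_episodes = "nonparametric",
    hospitalizations = "nonparametric",
    neuroticism = "nonparametric", extraversion = "nonparametric",
    openness = "parametric", agreeableness = "parametric",
    conscientiousness = "parametric",
    hdrs = "nonparametric", ymrs = "nonparametric",
    mi = "nonparametric")
}
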