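#' Pipeline configuration
#'
#' Settings for the end-to-end analysis: euthymia gate thresholds, scoring
#' key and minimum valid items, the latent-profile K range and optimisation
#' controls, Morbidity Index attribution and eligibility rules, predictor
#' screening, and the root seed (all stages draw named substreams from it so
#' each stage is independently reproducible).
#'
#' @param k_range class counts fitted (subset of 1..10; default 1:6).
#' @param lpa_control [lpa_control()] for the observed-data fits.
#' @param blrt run the bootstrap LRT column of the fit table (default FALSE;
#'   it dominates run time).
#' @param blrt_B bootstrap replicates when \code{blrt = TRUE}.
#' @param scoring_key a scoring key (default the synthetic
#'   [default_scoring_key()]).
#' @param min_valid_items minimum valid items per scale for scoring.
#' @param hdrs_max,ymrs_max euthymia gate thresholds.
#' @param attribution,max_gap,min_weeks Morbidity Index settings (see
#'   [morbidity_index()]).
#' @param screen_alpha significance level for predictor screening.
#' @param clinical_predictors a-priori clinical candidate predictors.
#' @param seed root seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(k_range = 1:6,
                            lpa_control = lpacourse::lpa_control(),
                            blrt = FALSE, blrt_B = 99L,
                            scoring_key = default_scoring_key(),
                            min_valid_items = 6L,
                            hdrs_max = 9L, ymrs_max = 12L,
                            attribution = "backward",
                            max_gap = 20, min_weeks = 8,
                            screen_alpha = 0.05,
                            clinical_predictors = c("comorbidity_count",
                                                    "age_at_onset",
                                                    "past_episodes",
                                                    "rapid_cycling"),
                            seed = 1L) {
  if (!all(k_range %in% 1:10)) stop("k_range must be a subset of 1..10")
  if (max_gap <= 0 || min_weeks <= 0) stop("thresholds must be positive")
  structure(list(k_range = sort(as.integer(k_range)),
                 lpa_control = lpa_control, blrt = blrt,
                 blrt_B = as.integer(blrt_B),
                 scoring_key = scoring_key,
                 min_valid_items = as.integer(min_valid_items),
                 hdrs_max = hdrs_max, ymrs_max = ymrs_max,
                 attribution = attribution, max_gap = max_gap,
                 min_weeks = min_weeks, screen_alpha = screen_alpha,
                 clinical_predictors = clinical_predictors,
                 seed = seed), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: the euthymia gate, NEO-FFI scale scoring, latent
#' profile model fitting over the configured K range with canonical class
#' ordering and modal assignment, Morbidity Index computation with
#' observation-time eligibility, the class-validation battery, predictor
#' screening, and the two-step hierarchical regression of the Morbidity
#' Index on clinical predictors plus class dummies (resilient class as
#' reference). Patients excluded at each gate are accounted for; input n
#' always equals analyzed n plus the per-reason exclusions.
#'
#' @param baseline baseline table (one row per patient) or a CSV path.
#' @param visits longitudinal visit table or a CSV path.
#' @param config a [pipeline_config()].
#' @param dir optional directory for the CSV/JSON artifacts (fit-index
#'   table, class-labelled baseline, Morbidity Index table, validation
#'   report, regression coefficients, summary JSON).
#' @return List of class \code{pipeline_result}: \code{exclusions},
#'   \code{fit_table}, \code{model} (selected \code{lpa_model}),
#'   \code{selected_K}, \code{labelled} (analysis table with class and mi),
#'   \code{validation}, \code{screening}, \code{regression},
#'   \code{summary}.
#' @export
run_pipeline <- function(baseline, visits, config = pipeline_config(),
                         dir = NULL) {
  if (is.character(baseline)) baseline <- read.csv(baseline)
  if (is.character(visits)) visits <- read.csv(visits)
  n_input <- nrow(baseline)

  # stage 1: euthymia gate
  gate <- euthymia_gate(baseline$hdrs, baseline$ymrs,
                        config$hdrs_max, config$ymrs_max)
  gated <- baseline[gate, , drop = FALSE]

  # stage 2: scale scoring (ipsative imputation)
  scored <- score_baseline(gated, config$scoring_key, config$min_valid_items)
  failures <- attr(scored, "failures")
  scored <- scored[!is.na(scored$neuroticism), , drop = FALSE]

  # stage 3: latent profile analysis over the K range
  sel <- lpa_select(scored[NEO_SCALES], k_range = config$k_range,
                    control = config$lpa_control,
                    seed = stage_seed(config$seed, "lpa"),
                    blrt = config$blrt, blrt_B = config$blrt_B)
  model <- sel$models[[paste0("K", sel$best_bic)]]
  scored$class <- classify_modal(model$posterior)

  # stage 4: Morbidity Index with eligibility exclusions
  mi <- morbidity_index(visits[visits$patient_id %in% scored$patient_id, ],
                        attribution = config$attribution,
                        max_gap = config$max_gap,
                        min_weeks = config$min_weeks)
  labelled <- merge(scored, mi, by = "patient_id", all.x = TRUE)
  labelled$eligible[is.na(labelled$eligible)] <- FALSE
  labelled$exclusion_reason[is.na(labelled$exclusion_reason)] <-
    "observation_too_short"

  exclusions <- data.frame(
    stage = c("input", "not_euthymic", "scoring_failure", "analyzed_lpa",
              "mi_gap_too_long", "mi_observation_too_short", "analyzed_mi"),
    n = c(n_input, sum(!gate), nrow(failures), nrow(scored),
          sum(labelled$exclusion_reason == "gap_too_long"),
          sum(labelled$exclusion_reason == "observation_too_short"),
          sum(labelled$eligible)))

  # stage 5: class validation battery
  validation <- validate_classes(labelled)

  # stage 6: screening + hierarchical regression on eligible patients
  prosp <- labelled[labelled$eligible, , drop = FALSE]
  screening <- screen_predictors(prosp, "mi",
                                 intersect(config$clinical_predictors,
                                           names(prosp)),
                                 alpha = config$screen_alpha)
  step1 <- screening$selected
  if (!length(step1)) step1 <- intersect(config$clinical_predictors,
                                         names(prosp))
  K <- model$K
  step2 <- character(0)
  if (K >= 2) {
    for (k in 2:K) {
      nm <- paste0("class", k, "_vs_1")
      prosp[[nm]] <- as.integer(prosp$class == k)
      step2 <- c(step2, nm)
    }
  } else message("single-class solution: regression step 2 skipped")
  regression <- tryCatch(
    hierarchical_fit(prosp, "mi", step1, step2),
    error = function(e) {
      message("regression stage failed: ", conditionMessage(e))
      NULL
    })

  per_class_mi <- tapply(prosp$mi, prosp$class, mean)
  summary_list <- list(
    n_input = n_input,
    n_lpa = nrow(scored),
    n_prospective = nrow(prosp),
    selected_K = model$K,
    class_sizes = as.integer(table(factor(scored$class,
                                          levels = seq_len(model$K)))),
    entropy = relative_entropy(model$posterior),
    class_mi_means = as.numeric(per_class_mi),
    screening_selected = step1,
    r2_step1 = regression$steps$step1$r2 %||% NA_real_,
    r2_final = if (!is.null(regression$steps$step2))
      regression$steps$step2$r2 else regression$steps$step1$r2 %||% NA_real_,
    stein_r2 = regression$stein_r2 %||% NA_real_)

  out <- structure(list(exclusions = exclusions, fit_table = sel$table,
                        model = model, selected_K = model$K,
                        labelled = labelled, validation = validation,
                        screening = screening, regression = regression,
                        summary = summary_list), class = "pipeline_result")
  if (!is.null(dir)) write_pipeline_artifacts(out, dir)
  out
}

write_pipeline_artifacts <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(result$fit_table, file.path(dir, "fit_indices.csv"),
            row.names = FALSE)
  write.csv(result$exclusions, file.path(dir, "exclusions.csv"),
            row.names = FALSE)
  write.csv(result$labelled, file.path(dir, "baseline_labelled.csv"),
            row.names = FALSE, na = "")
  write.csv(result$validation, file.path(dir, "class_validation.csv"),
            row.names = FALSE)
  if (!is.null(result$regression)) {
    steps <- result$regression$steps
    final <- steps[[length(steps)]]
    write.csv(final$coefficients, file.path(dir, "regression_coefficients.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Exclusion accounting:\n")
  print(x$exclusions, row.names = FALSE)
  cat("\nModel selection (lowest BIC at K =", x$selected_K, "):\n")
  print(structure(list(table = x$fit_table, best_bic = x$selected_K),
                  class = "lpa_selection"))
  cat(sprintf("\nPer-class Morbidity Index means: %s\n",
              paste(sprintf("%.3f", x$summary$class_mi_means),
                    collapse = ", ")))
  if (!is.null(x$regression))
    cat(sprintf("Regression: R2 step1 = %.3f, final = %.3f, Stein = %.3f\n",
                x$summary$r2_step1, x$summary$r2_final, x$summary$stein_r2))
  invisible(x)
}

#' Plot class-specific personality profiles
#'
#' Line plot of the estimated class means across the five NEO-FFI scales,
#' one line per latent class.
#'
#' @param model an \code{lpa_model} fitted on the five scales.
#' @return A ggplot object.
#' @export
plot_class_profiles <- function(model) {
  stopifnot(inherits(model, "lpa_model"))
  df <- data.frame(
    class = factor(rep(rownames(model$means), ncol(model$means))),
    scale = factor(rep(colnames(model$means), each = nrow(model$means)),
                   levels = colnames(model$means)),
    mean = as.vector(model$means))
  ggplot2::ggplot(df, ggplot2::aes(x = scale, y = mean,
                                   group = class, colour = class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "scale mean", colour = "class") +
    ggplot2::theme_minimal()
}
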