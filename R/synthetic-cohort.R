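#' Configuration of the synthetic bipolar-disorder cohort
#'
#' Collects every generating parameter of the synthetic cohort: the 3-class
#' mixture over the five NEO-FFI scale scores (class weights, class-by-scale
#' means, within-class SDs shared across classes), item-level missingness,
#' the follow-up visit schedule, the class-conditional symptom-severity
#' process, and the per-class clinical covariate distributions. The defaults
#' reproduce the published characteristics of a 134-patient euthymic cohort:
#' class weights 51/41/8 percent, the per-class scale means and pooled
#' within-class SDs, 0.8 percent item missingness, visits roughly every 8
#' weeks over an observation horizon of mean 54.7 (SD 34.9) weeks, and a
#' severity process calibrated so the class-wise expected Morbidity Index is
#' near 0.30 / 0.53 / 0.90.
#'
#' @param n_patients cohort size (default 134).
#' @param class_weights three class proportions summing to 1.
#' @param class_means 3 x 5 matrix of scale means (rows = classes in order
#'   resilient, vulnerable, highly vulnerable; columns = neuroticism,
#'   extraversion, openness, agreeableness, conscientiousness).
#' @param shared_sds five positive within-class SDs shared across classes.
#' @param item_missing_rate probability in \[0, 1) that an item response is
#'   missing (MCAR).
#' @param visit_interval_weeks nominal weeks between follow-up visits.
#' @param visit_jitter_sd SD of the Gaussian jitter on each visit time.
#' @param visit_miss_prob probability a scheduled follow-up visit is missed
#'   (creates realistic long-gap exclusions).
#' @param max_followup_weeks upper truncation of the observation horizon.
#' @param observation_mean_weeks,observation_sd_weeks truncated-normal
#'   parameters of the per-patient observation horizon (lower bound 1 week,
#'   so some horizons fall below the 8-week eligibility minimum).
#' @param severity_params per-class two-state (well/symptomatic) Markov
#'   process: \code{p_enter} (well to symptomatic per visit), \code{p_stay}
#'   (symptomatic to symptomatic), \code{q_sub_well} (probability of
#'   subthreshold symptoms while well), and \code{sym_degree_probs}, a 3 x 4
#'   matrix of degree probabilities (columns = degrees 0.5, 1, 2, 3) given
#'   the symptomatic state.
#' @param covariate_params per-class clinical covariate distributions; see
#'   the default for the expected shape. Includes a patient-level frailty
#'   (chronicity) factor that links the number of past episodes to the
#'   severity process so that illness history correlates with outcome.
#' @param scale_min,scale_max item response bounds (default 0-4).
#' @param seed root seed; all generation stages draw from named substreams.
#' @return A validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 134L,
                          class_weights = c(0.51, 0.41, 0.08),
                          class_means = default_class_means(),
                          shared_sds = c(0.430, 0.493, 0.537, 0.397, 0.395),
                          item_missing_rate = 0.008,
                          visit_interval_weeks = 8,
                          visit_jitter_sd = 0.7,
                          visit_miss_prob = 0.06,
                          max_followup_weeks = 122,
                          observation_mean_weeks = 54.7,
                          observation_sd_weeks = 34.9,
                          severity_params = default_severity_params(),
                          covariate_params = default_covariate_params(),
                          scale_min = 0L, scale_max = 4L,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              class_weights = class_weights,
              class_means = class_means, shared_sds = shared_sds,
              item_missing_rate = item_missing_rate,
              visit_interval_weeks = visit_interval_weeks,
              visit_jitter_sd = visit_jitter_sd,
              visit_miss_prob = visit_miss_prob,
              max_followup_weeks = max_followup_weeks,
              observation_mean_weeks = observation_mean_weeks,
              observation_sd_weeks = observation_sd_weeks,
              severity_params = severity_params,
              covariate_params = covariate_params,
              scale_min = as.integer(scale_min),
              scale_max = as.integer(scale_max),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_class_means <- function() {
  m <- matrix(c(1.44, 2.25, 2.36, 2.68, 2.85,
                2.39, 1.88, 2.54, 2.45, 2.31,
                3.10, 1.00, 2.25, 2.04, 1.55),
              nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("resilient", "vulnerable", "highly_vulnerable"),
                      NEO_SCALES)
  m
}

#' @rdname cohort_config
#' @export
default_severity_params <- function() {
  list(
    p_enter = c(0.187, 0.311, 0.502),
    p_stay = c(0.45, 0.55, 0.70),
    q_sub_well = c(0.12, 0.18, 0.25),
    sym_degree_probs = matrix(c(0.50, 0.30, 0.15, 0.05,
                                0.40, 0.33, 0.17, 0.10,
                                0.30, 0.33, 0.22, 0.15),
                              nrow = 3, byrow = TRUE,
                              dimnames = list(NULL, c("d0.5", "d1", "d2", "d3")))
  )
}

#' @rdname cohort_config
#' @export
default_covariate_params <- function() {
  list(
    age = list(mean = c(45.1, 43.7, 41.9), sd = 13.3),
    education = list(mean = c(13.8, 13.4, 12.2), sd = 3.2, min = 8),
    gender_female = c(0.632, 0.636, 0.727),
    bipolar_I = c(0.691, 0.618, 0.545),
    employment = c(0.500, 0.545, 0.455),
    relationship = c(0.544, 0.473, 0.545),
    alcohol = c(0.309, 0.273, 0.273),
    drugs = c(0.118, 0.109, 0.182),
    attempted_suicide = c(0.279, 0.364, 0.182),
    rapid_cycling = c(0.162, 0.255, 0.182),
    rapid_cycling_episode_slope = 1.0,
    comorbidity_mean = c(0.20, 0.29, 1.25),
    medication_mean = c(1.78, 1.78, 2.10),
    age_at_onset = list(mean = c(29.3, 24.5, 27.3), sd = c(9.6, 10.2, 11.3),
                        min = 10),
    past_episodes = list(mean = c(14.9, 16.3, 13.6), size = 0.75),
    hospitalizations = list(mean = c(3.0, 2.8, 4.3), size = 1.4),
    hdrs = list(mean = c(1.85, 3.82, 4.50), size = 1.2),
    ymrs = list(mean = c(1.94, 1.06, 0.75), size = 1.2),
    frailty_sd = 1.0,
    past_episodes_frailty = 0.35,
    severity_frailty = 0.30
  )
}

validate_cohort_config <- function(cfg) {
  err <- function(field, msg) stop("invalid cohort config: field '", field,
                                   "' ", msg, call. = FALSE)
  if (cfg$n_patients < 1) err("n_patients", "must be a positive count")
  if (length(cfg$class_weights) != 3) err("class_weights", "must have length 3")
  if (any(cfg$class_weights < 0)) err("class_weights", "must be non-negative")
  if (abs(sum(cfg$class_weights) - 1) > 1e-12)
    err("class_weights", "must sum to 1")
  if (!all(dim(cfg$class_means) == c(3, 5)))
    err("class_means", "must be a 3 x 5 matrix")
  if (length(cfg$shared_sds) != 5 || any(cfg$shared_sds <= 0))
    err("shared_sds", "must be 5 positive SDs")
  if (cfg$item_missing_rate < 0 || cfg$item_missing_rate >= 1)
    err("item_missing_rate", "must lie in [0, 1)")
  if (cfg$visit_interval_weeks <= 0)
    err("visit_interval_weeks", "must be positive")
  if (cfg$max_followup_weeks <= 0)
    err("max_followup_weeks", "must be positive")
  sp <- cfg$severity_params
  if (any(sp$p_enter < 0 | sp$p_enter > 1) || any(sp$p_stay < 0 | sp$p_stay > 1))
    err("severity_params", "transition probabilities must lie in [0, 1]")
  if (!all(abs(rowSums(sp$sym_degree_probs) - 1) < 1e-9))
    err("severity_params", "sym_degree_probs rows must sum to 1")
  invisible(cfg)
}

# Integer item responses consistent with a target scale score: the 12 items
# sum to round(12 * score), so the item mean is within 1/24 of the target.
expand_items <- function(score, n_items, lo, hi) {
  target <- round(n_items * score)
  target <- min(max(target, n_items * lo), n_items * hi)
  items <- pmin(pmax(round(rnorm(n_items, score, 0.9)), lo), hi)
  gap <- target - sum(items)
  while (gap != 0) {
    if (gap > 0) {
      ix <- which(items < hi)
      i <- ix[sample.int(length(ix), 1L)]
      items[i] <- items[i] + 1L
    } else {
      ix <- which(items > lo)
      i <- ix[sample.int(length(ix), 1L)]
      items[i] <- items[i] - 1L
    }
    gap <- target - sum(items)
  }
  items
}

rnbinom_mean <- function(n, mean, size) rnbinom(n, size = size, mu = mean)

#' Sample a synthetic baseline table
#'
#' Draws one row per patient: the latent (true) personality class, the five
#' class-conditional scale scores expanded into 60 integer item responses
#' (reverse-keyed items stored in reversed form, per the generator's
#' [default_scoring_key()]), and class-linked clinical covariates. The
#' vulnerable class has the earliest illness onset and the highly vulnerable
#' class the highest co-morbidity load, mirroring the cohort the generator
#' emulates. Columns \code{true_class}, \code{frailty} and the generating
#' scale scores \code{true_neuroticism} ... \code{true_conscientiousness} are
#' synthetic truth that real data would not contain.
#'
#' @param config a [cohort_config()].
#' @param seed overrides \code{config$seed} when given.
#' @return Data frame with one row per patient.
#' @export
sample_baseline <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  with_seed(stage_seed(seed, "baseline"), {
    n <- config$n_patients
    cp <- config$covariate_params
    cls <- sample.int(3L, n, replace = TRUE, prob = config$class_weights)
    z <- rnorm(n, 0, cp$frailty_sd)

    # scale scores: class-conditional normal, clamped just inside the
    # response bounds so item expansion can always realise them
    lo <- config$scale_min; hi <- config$scale_max
    scores <- matrix(rnorm(n * 5,
                           mean = config$class_means[cls, ],
                           sd = rep(config$shared_sds, each = n)), n, 5)
    scores <- pmin(pmax(scores, lo + 0.02), hi - 0.02)
    colnames(scores) <- NEO_SCALES

    key <- default_scoring_key(lo, hi)
    items <- matrix(NA_integer_, n, 60L,
                    dimnames = list(NULL, sprintf("item%02d", 1:60)))
    for (i in seq_len(n)) {
      for (s in seq_len(5)) {
        ix <- key$items[[s]]
        vals <- expand_items(scores[i, s], 12L, lo, hi)
        rev_here <- ix %in% key$reverse_keyed
        vals[rev_here] <- reverse_key(vals[rev_here], key)
        items[i, ix] <- vals
      }
    }

    past <- rnbinom_mean(n, cp$past_episodes$mean[cls] *
                           exp(cp$past_episodes_frailty * z),
                         cp$past_episodes$size)
    rc_lin <- qlogis(cp$rapid_cycling[cls]) +
      cp$rapid_cycling_episode_slope *
        (log1p(past) - mean(log1p(cp$past_episodes$mean)))
    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      true_class = cls,
      frailty = z,
      age_years = round(pmax(rnorm(n, cp$age$mean[cls], cp$age$sd), 18), 1),
      education_years = round(pmax(rnorm(n, cp$education$mean[cls],
                                         cp$education$sd), cp$education$min)),
      gender_female = rbinom(n, 1, cp$gender_female[cls]),
      bipolar_I = rbinom(n, 1, cp$bipolar_I[cls]),
      employment = rbinom(n, 1, cp$employment[cls]),
      relationship = rbinom(n, 1, cp$relationship[cls]),
      alcohol = rbinom(n, 1, cp$alcohol[cls]),
      drugs = rbinom(n, 1, cp$drugs[cls]),
      attempted_suicide = rbinom(n, 1, cp$attempted_suicide[cls]),
      rapid_cycling = rbinom(n, 1, plogis(rc_lin)),
      comorbidity_count = rpois(n, cp$comorbidity_mean[cls]),
      medication_groups = rpois(n, cp$medication_mean[cls]),
      age_at_onset = round(pmax(rnorm(n, cp$age_at_onset$mean[cls],
                                      cp$age_at_onset$sd[cls]),
                                cp$age_at_onset$min), 1),
      past_episodes = past,
      hospitalizations = rnbinom_mean(n, cp$hospitalizations$mean[cls],
                                      cp$hospitalizations$size),
      hdrs = rnbinom_mean(n, cp$hdrs$mean[cls], cp$hdrs$size),
      ymrs = rnbinom_mean(n, cp$ymrs$mean[cls], cp$ymrs$size),
      stringsAsFactors = FALSE)
    truth <- as.data.frame(scores)
    names(truth) <- paste0("true_", NEO_SCALES)
    cbind(out, truth, as.data.frame(items))
  })
}

#' Inject missing-completely-at-random item missingness
#'
#' Replaces each NEO item response independently by \code{NA} with
#' probability \code{rate} (MCAR by construction).
#'
#' @param baseline baseline table with \code{item01..item60} columns.
#' @param rate missingness probability in \[0, 1).
#' @param seed RNG seed.
#' @return The baseline table with missing item entries.
#' @export
inject_missingness <- function(baseline, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("missingness rate must lie in [0, 1)")
  if (rate == 0) return(baseline)
  item_cols <- sprintf("item%02d", 1:60)
  with_seed(stage_seed(seed, "missing"), {
    m <- as.matrix(baseline[item_cols])
    drop <- matrix(runif(length(m)) < rate, nrow(m), ncol(m))
    m[drop] <- NA_integer_
    baseline[item_cols] <- as.data.frame(m)
    baseline
  })
}

# Truncated-normal horizon via rejection sampling (bounds [1, upper]).
r_truncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# HDRS/YMRS ratings and flags consistent with an intended degree, so that
# assign_degree() on the generated table recovers the intended degree.
scores_for_degree <- function(degree) {
  esc <- FALSE; hosp <- FALSE
  if (degree == 0) {
    hdrs <- sample(0:3, 1, prob = c(0.5, 0.25, 0.15, 0.1))
    ymrs <- sample(0:2, 1, prob = c(0.6, 0.25, 0.15))
  } else if (degree == 0.5) {
    if (runif(1) < 0.7) { hdrs <- sample(4:9, 1); ymrs <- sample(0:2, 1) }
    else { hdrs <- sample(0:3, 1); ymrs <- sample(3:11, 1) }
  } else if (degree == 1) {
    if (runif(1) < 0.7) { hdrs <- sample(10:20, 1); ymrs <- sample(0:2, 1) }
    else { hdrs <- sample(0:3, 1); ymrs <- sample(12:20, 1) }
  } else if (degree == 2) {
    esc <- TRUE
    if (runif(1) < 0.7) { hdrs <- sample(10:24, 1); ymrs <- sample(0:2, 1) }
    else { hdrs <- sample(0:3, 1); ymrs <- sample(12:25, 1) }
  } else {
    hosp <- TRUE
    if (runif(1) < 0.7) { hdrs <- sample(18:34, 1); ymrs <- sample(0:4, 1) }
    else { hdrs <- sample(0:6, 1); ymrs <- sample(20:40, 1) }
  }
  list(hdrs = hdrs, ymrs = ymrs, esc = esc, hosp = hosp)
}

#' Sample longitudinal follow-up visits
#'
#' Generates each patient's visit series: a truncated-normal observation
#' horizon, visits at the nominal interval with Gaussian jitter (some visits
#' missed at random, producing occasional over-long gaps), and per-visit
#' symptom ratings driven by a class-conditional two-state (well /
#' symptomatic) Markov process whose first state is drawn from its stationary
#' distribution. Patient frailty shifts the probability of entering the
#' symptomatic state, linking illness history to outcome. Ratings and
#' treatment flags are generated to be consistent with the intended morbidity
#' degree of the visit.
#'
#' @inheritParams sample_baseline
#' @param baseline a [sample_baseline()] table (needs \code{patient_id},
#'   \code{true_class}, \code{frailty}).
#' @return Visit data frame: \code{patient_id}, \code{week}, \code{hdrs},
#'   \code{ymrs}, \code{treatment_escalation}, \code{hospitalized}.
#' @export
sample_visits <- function(baseline, config, seed = config$seed) {
  validate_cohort_config(config)
  sp <- config$severity_params
  cp <- config$covariate_params
  with_seed(stage_seed(seed, "visits"), {
    res <- vector("list", nrow(baseline))
    for (i in seq_len(nrow(baseline))) {
      k <- baseline$true_class[i]
      z <- baseline$frailty[i] %||% 0
      p_enter <- plogis(qlogis(sp$p_enter[k]) + cp$severity_frailty * z)
      if (sp$p_enter[k] == 0) p_enter <- 0
      p_stay <- sp$p_stay[k]
      horizon <- r_truncnorm(1, config$observation_mean_weeks,
                             config$observation_sd_weeks, 1,
                             config$max_followup_weeks)
      nominal <- seq(0, horizon, by = config$visit_interval_weeks)
      weeks <- nominal +
        c(0, rnorm(length(nominal) - 1, 0, config$visit_jitter_sd))
      keep <- c(TRUE, runif(length(weeks) - 1) > config$visit_miss_prob)
      weeks <- sort(weeks[keep])
      weeks <- weeks[c(TRUE, diff(weeks) > 0.5)]
      m <- length(weeks)
      stat_p <- if (p_enter + (1 - p_stay) > 0)
        p_enter / (p_enter + (1 - p_stay)) else 0
      state <- runif(1) < stat_p
      deg <- numeric(m); hdrs <- integer(m); ymrs <- integer(m)
      esc <- logical(m); hosp <- logical(m)
      for (v in seq_len(m)) {
        if (v > 1) state <- runif(1) < (if (state) p_stay else p_enter)
        if (state) {
          deg[v] <- c(0.5, 1, 2, 3)[sample.int(4L, 1L,
                                               prob = sp$sym_degree_probs[k, ])]
        } else {
          deg[v] <- if (runif(1) < sp$q_sub_well[k]) 0.5 else 0
        }
        sc <- scores_for_degree(deg[v])
        hdrs[v] <- sc$hdrs; ymrs[v] <- sc$ymrs
        esc[v] <- sc$esc; hosp[v] <- sc$hosp
      }
      res[[i]] <- data.frame(patient_id = baseline$patient_id[i],
                             week = round(weeks, 2), hdrs = hdrs, ymrs = ymrs,
                             treatment_escalation = esc, hospitalized = hosp,
                             stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs [sample_baseline()], [inject_missingness()] (at the configured rate)
#' and [sample_visits()] from one root seed, optionally writing
#' \code{baseline.csv}, \code{visits.csv} and the generating configuration as
#' \code{cohort_config.json} to a directory.
#'
#' @inheritParams sample_baseline
#' @param dir optional output directory.
#' @return List with \code{baseline}, \code{visits}, \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed,
                            dir = NULL) {
  baseline <- sample_baseline(config, seed)
  baseline <- inject_missingness(baseline, config$item_missing_rate, seed)
  visits <- sample_visits(baseline, config, seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.csv(baseline, file.path(dir, "baseline.csv"), row.names = FALSE,
              na = "")
    write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE,
              na = "")
    cfg <- unclass(config)
    cfg$class_means <- as.data.frame(cfg$class_means)
    jsonlite::write_json(cfg, file.path(dir, "cohort_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(baseline = baseline, visits = visits, config = config)
}
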