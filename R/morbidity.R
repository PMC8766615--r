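#' Symptom degree of a follow-up visit
#'
#' Maps a visit's observer ratings and treatment flags to the modified
#' morbidity degree scale: 0 = no symptoms; 0.5 = subthreshold symptoms
#' (HDRS-21 in 4-9 or YMRS in 3-11); 1 = mild syndromal symptoms
#' (HDRS-21 >= 10 or YMRS >= 12) without treatment change; 2 = aggravation
#' needing additional treatment (escalation flag); 3 = aggravation with acute
#' need for hospitalization. Hospitalization dominates escalation, which
#' dominates the score-based degrees; when depression and mania imply
#' different degrees the maximum applies.
#'
#' @param hdrs,ymrs non-negative integer severity ratings (vectorised).
#' @param treatment_escalation,hospitalized logical flags.
#' @param subthreshold_hdrs,subthreshold_ymrs inclusive (low, high) bands for
#'   degree 0.5; the next integer above each band starts degree 1.
#' @return Numeric vector of degrees in \{0, 0.5, 1, 2, 3\}.
#' @export
assign_degree <- function(hdrs, ymrs, treatment_escalation = FALSE,
                          hospitalized = FALSE,
                          subthreshold_hdrs = c(4L, 9L),
                          subthreshold_ymrs = c(3L, 11L)) {
  n <- max(length(hdrs), length(ymrs))
  hdrs <- rep_len(hdrs, n); ymrs <- rep_len(ymrs, n)
  treatment_escalation <- rep_len(as.logical(treatment_escalation), n)
  hospitalized <- rep_len(as.logical(hospitalized), n)
  if (any(hdrs < 0) || any(ymrs < 0))
    stop("severity ratings must be non-negative")
  deg <- numeric(n)
  sub <- (hdrs >= subthreshold_hdrs[1] & hdrs <= subthreshold_hdrs[2]) |
         (ymrs >= subthreshold_ymrs[1] & ymrs <= subthreshold_ymrs[2])
  syndromal <- hdrs > subthreshold_hdrs[2] | ymrs > subthreshold_ymrs[2]
  deg[sub] <- 0.5
  deg[syndromal] <- 1
  deg[treatment_escalation] <- 2
  deg[hospitalized] <- 3
  deg
}

#' Observation-time eligibility of a visit series
#'
#' A patient's follow-up series enters the course analysis only if no
#' inter-visit gap exceeds \code{max_gap} weeks and the total observation
#' span (last minus first visit) is at least \code{min_weeks} weeks.
#'
#' @param weeks sorted non-negative visit times in weeks since baseline.
#' @param max_gap largest tolerated interval between consecutive visits
#'   (default 20 weeks).
#' @param min_weeks minimum observation span (default 8 weeks).
#' @return List: \code{eligible} (logical) and \code{exclusion_reason}, one of
#'   \code{"none"}, \code{"gap_too_long"}, \code{"observation_too_short"}.
#' @export
mi_eligibility <- function(weeks, max_gap = 20, min_weeks = 8) {
  if (length(weeks) == 0)
    return(list(eligible = FALSE, exclusion_reason = "observation_too_short"))
  if (is.unsorted(weeks, strictly = TRUE))
    stop("visit weeks must be strictly increasing within a patient")
  if (length(weeks) > 1 && any(diff(weeks) > max_gap))
    return(list(eligible = FALSE, exclusion_reason = "gap_too_long"))
  if (max(weeks) - min(weeks) < min_weeks)
    return(list(eligible = FALSE, exclusion_reason = "observation_too_short"))
  list(eligible = TRUE, exclusion_reason = "none")
}

# Interval weights for one patient's visit degrees. Backward attribution
# (default): a visit's rating summarises the interval since the previous
# visit, so the first visit gets a zero-length interval. Forward: a rating
# holds until the next visit. Midpoint: each interval is split between its
# two visits.
interval_weights <- function(weeks, attribution) {
  m <- length(weeks)
  gaps <- diff(weeks)
  switch(attribution,
         backward = c(0, gaps),
         forward = c(gaps, 0),
         midpoint = c(gaps / 2, 0) + c(0, gaps / 2),
         stop("unknown attribution mode: ", attribution))
}

#' Morbidity Index of a single visit series
#'
#' The Morbidity Index is the time-weighted average symptom degree over the
#' observation period: each visit's degree is weighted by the length of the
#' interval it is attributed to, summed, and divided by the total observation
#' time (last visit minus first). Values lie in \[0, 3\]; higher = more
#' time spent ill and/or more severe illness.
#'
#' @param weeks strictly increasing visit times (weeks).
#' @param degrees visit degrees from [assign_degree()].
#' @param attribution which interval a visit's rating covers:
#'   \code{"backward"} (default; the interval since the previous visit),
#'   \code{"forward"}, or \code{"midpoint"}.
#' @inheritParams mi_eligibility
#' @return List: \code{eligible}, \code{exclusion_reason},
#'   \code{total_weeks}, \code{mi} (\code{NA} when ineligible).
#' @export
compute_mi <- function(weeks, degrees,
                       attribution = c("backward", "forward", "midpoint"),
                       max_gap = 20, min_weeks = 8) {
  attribution <- match.arg(attribution)
  stopifnot(length(weeks) == length(degrees))
  el <- mi_eligibility(weeks, max_gap, min_weeks)
  if (!el$eligible)
    return(list(eligible = FALSE, exclusion_reason = el$exclusion_reason,
                total_weeks = if (length(weeks) > 1) diff(range(weeks)) else 0,
                mi = NA_real_))
  w <- interval_weights(weeks, attribution)
  total <- max(weeks) - min(weeks)
  list(eligible = TRUE, exclusion_reason = "none", total_weeks = total,
       mi = sum(degrees * w) / total)
}

#' Morbidity Index for a longitudinal visit table
#'
#' Applies [assign_degree()] and [compute_mi()] per patient to a visit table
#' (columns \code{patient_id}, \code{week}, \code{hdrs}, \code{ymrs},
#' \code{treatment_escalation}, \code{hospitalized}).
#'
#' @param visits visit data frame as above.
#' @inheritParams compute_mi
#' @return Data frame, one row per patient: \code{patient_id},
#'   \code{eligible}, \code{exclusion_reason}, \code{total_weeks}, \code{mi}.
#' @export
morbidity_index <- function(visits,
                            attribution = c("backward", "forward", "midpoint"),
                            max_gap = 20, min_weeks = 8) {
  attribution <- match.arg(attribution)
  need <- c("patient_id", "week", "hdrs", "ymrs",
            "treatment_escalation", "hospitalized")
  if (!all(need %in% names(visits)))
    stop("visit table must have columns: ", paste(need, collapse = ", "))
  visits <- visits[order(visits$patient_id, visits$week), ]
  out <- lapply(split(visits, visits$patient_id, drop = TRUE), function(v) {
    deg <- assign_degree(v$hdrs, v$ymrs, v$treatment_escalation,
                         v$hospitalized)
    r <- compute_mi(v$week, deg, attribution, max_gap, min_weeks)
    data.frame(patient_id = v$patient_id[1], eligible = r$eligible,
               exclusion_reason = r$exclusion_reason,
               total_weeks = r$total_weeks, mi = r$mi,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
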