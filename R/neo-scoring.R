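NEO_SCALES <- c("neuroticism", "extraversion", "openness",
                "agreeableness", "conscientiousness")

#' Scoring key for a 60-item five-factor inventory
#'
#' A scoring key maps each of the 60 items to one of the five scales
#' (12 items each), marks the reverse-keyed items, and records the response
#' range. The published NEO-FFI key is proprietary and not shipped; this
#' constructor builds the synthetic key used by the cohort generator
#' (items interleaved across scales, a fixed third of each scale
#' reverse-keyed), and [read_scoring_key()] loads a real key from JSON.
#'
#' @param scale_min,scale_max integer response bounds. The default internal
#'   coding is 0-4 (the published German NEO-FFI item coding); instruments
#'   coded 1-5 are handled by setting the bounds accordingly.
#' @return List of class \code{scoring_key}: \code{items} (named list of five
#'   12-item index vectors), \code{reverse_keyed}, \code{scale_min},
#'   \code{scale_max}.
#' @export
default_scoring_key <- function(scale_min = 0L, scale_max = 4L) {
  items <- lapply(seq_len(5), function(s) as.integer(seq(s, 60, by = 5)))
  names(items) <- NEO_SCALES
  reverse <- sort(unlist(lapply(items, function(ix) ix[c(2, 5, 8, 11)]),
                         use.names = FALSE))
  validate_scoring_key(structure(
    list(items = items, reverse_keyed = as.integer(reverse),
         scale_min = as.integer(scale_min), scale_max = as.integer(scale_max)),
    class = "scoring_key"))
}

validate_scoring_key <- function(key) {
  all_items <- sort(unlist(key$items, use.names = FALSE))
  if (!identical(all_items, 1:60))
    stop("scoring key item sets must partition items 1..60")
  if (!all(lengths(key$items) == 12L))
    stop("each scale must have exactly 12 items")
  if (!all(key$reverse_keyed %in% all_items))
    stop("reverse_keyed must be a subset of the item indices")
  if (key$scale_min >= key$scale_max) stop("scale_min must be < scale_max")
  key
}

#' @rdname default_scoring_key
#' @param path JSON file path.
#' @export
read_scoring_key <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_scoring_key(structure(
    list(items = lapply(raw$items, as.integer),
         reverse_keyed = as.integer(raw$reverse_keyed),
         scale_min = as.integer(raw$scale_min),
         scale_max = as.integer(raw$scale_max)),
    class = "scoring_key"))
}

#' @rdname default_scoring_key
#' @param key a \code{scoring_key}.
#' @export
write_scoring_key <- function(key, path) {
  jsonlite::write_json(unclass(key), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Reverse-keying x -> scale_min + scale_max - x; applying it twice is the
# identity.
reverse_key <- function(x, key) key$scale_min + key$scale_max - x

#' Score 60 item responses into the five scale means
#'
#' Reverse-keyed items are mapped \code{x -> scale_min + scale_max - x}; each
#' scale score is the mean of its valid (non-missing) items, which equals
#' ipsative mean imputation (each missing item replaced by the mean of the
#' scale's valid items) followed by a 12-item mean. A scale with fewer than
#' \code{min_valid_items} valid responses fails to score.
#'
#' @param items numeric vector of 60 responses, \code{NA} for missing; values
#'   must lie within the key's response bounds where present.
#' @param key a [default_scoring_key()]-style scoring key.
#' @param min_valid_items minimum valid items per scale (default 6 of 12).
#' @return Named numeric vector of the five scale scores.
#' @export
score_scales <- function(items, key = default_scoring_key(),
                         min_valid_items = 6L) {
  if (length(items) != 60L) stop("expected 60 item responses")
  present <- !is.na(items)
  if (any(items[present] < key$scale_min | items[present] > key$scale_max))
    stop("item responses outside the key's response bounds")
  items[key$reverse_keyed] <- reverse_key(items[key$reverse_keyed], key)
  out <- vapply(NEO_SCALES, function(sc) {
    v <- items[key$items[[sc]]]
    v <- v[!is.na(v)]
    if (length(v) < min_valid_items)
      stop("scoring failure: only ", length(v), " valid items on scale '",
           sc, "' (need ", min_valid_items, ")")
    mean(v)
  }, numeric(1))
  out
}

#' Score a baseline table of item responses
#'
#' Applies [score_scales()] to the \code{item01..item60} columns of a baseline
#' table and appends the five scale scores as named columns. Patients who fail
#' to score (too many missing items on some scale) get \code{NA} scores and
#' are listed in the \code{failures} attribute.
#'
#' @param baseline data frame with 60 item columns named \code{item01} ...
#'   \code{item60}.
#' @inheritParams score_scales
#' @return \code{baseline} with five additional scale-score columns; attribute
#'   \code{failures} is a data frame (patient_id, reason) of scoring failures.
#' @export
score_baseline <- function(baseline, key = default_scoring_key(),
                           min_valid_items = 6L) {
  item_cols <- sprintf("item%02d", 1:60)
  if (!all(item_cols %in% names(baseline)))
    stop("baseline must contain columns item01..item60")
  items <- as.matrix(baseline[item_cols])
  scores <- matrix(NA_real_, nrow(baseline), 5,
                   dimnames = list(NULL, NEO_SCALES))
  fail_id <- character(0); fail_reason <- character(0)
  for (i in seq_len(nrow(baseline))) {
    res <- tryCatch(score_scales(items[i, ], key, min_valid_items),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fail_id <- c(fail_id, as.character(baseline$patient_id[i]))
      fail_reason <- c(fail_reason, conditionMessage(res))
    } else scores[i, ] <- res
  }
  out <- cbind(baseline, as.data.frame(scores))
  attr(out, "failures") <- data.frame(patient_id = fail_id,
                                      reason = fail_reason,
                                      stringsAsFactors = FALSE)
  out
}

#' Euthymia inclusion gate
#'
#' A patient is euthymic (clinically stable, eligible for personality
#' assessment and the profile analysis) when the depression rating satisfies
#' HDRS-21 <= 9 and the mania rating YMRS <= 12.
#'
#' @param hdrs,ymrs non-negative integer severity ratings (vectorised).
#' @param hdrs_max,ymrs_max inclusion thresholds (defaults 9 and 12).
#' @return Logical vector: TRUE = euthymic, include.
#' @export
euthymia_gate <- function(hdrs, ymrs, hdrs_max = 9L, ymrs_max = 12L) {
  if (any(hdrs < 0, na.rm = TRUE) || any(ymrs < 0, na.rm = TRUE))
    stop("severity ratings must be non-negative")
  hdrs <= hdrs_max & ymrs <= ymrs_max
}
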