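#' Map one symptom score to its acuity tier
#'
#' Looks up the policy's score-to-tier table. Vectorised over `symptom` and
#' `score` (recycled to a common length).
#'
#' @param symptom Symptom name(s), see [symptom_names()].
#' @param score Integer score(s) in 0-3.
#' @param policy A [triage_policy()].
#' @return Ordered factor with levels GREEN < AMBER < RED.
#' @export
#' @examples
#' map_symptom_tier("diarrhea", 3, triage_policy())
map_symptom_tier <- function(symptom, score, policy = triage_policy()) {
  n <- max(length(symptom), length(score))
  symptom <- rep_len(symptom, n)
  score <- rep_len(score, n)
  if (!all(symptom %in% symptom_names())) {
    stop_invalid_config(paste0("unknown symptom '",
                               symptom[!symptom %in% symptom_names()][1], "'"))
  }
  if (any(is.na(score) | score < 0 | score > 3 | score != as.integer(score))) {
    stop_score_out_of_range(symptom[which(score < 0 | score > 3)[1]],
                            score[which(score < 0 | score > 3)[1]])
  }
  as_tier(policy$symptom_tier_map[cbind(symptom, as.character(as.integer(score)))])
}

#' Classify timestamps against the staffed monitoring window
#'
#' TRUE iff the timestamp, converted to the schedule's timezone, falls on a
#' staffed weekday strictly inside the half-open staffed window
#' `[start, end)` — an alert at exactly the window end is out of hours.
#'
#' @param ts POSIXct vector (or ISO 8601 strings with offset).
#' @param schedule A [monitoring_schedule()].
#' @return Logical vector.
#' @export
#' @examples
#' classify_coverage("2025-07-15T10:30:00+01:00", monitoring_schedule())
classify_coverage <- function(ts, schedule = monitoring_schedule()) {
  ts <- parse_timestamp(ts, schedule$timezone)
  local <- lubridate::with_tz(ts, schedule$timezone)
  wd <- lubridate::wday(local, week_start = 1)
  mins <- lubridate::hour(local) * 60L + lubridate::minute(local)
  wd %in% schedule$staffed_weekdays &
    mins >= schedule$start_min & mins < schedule$end_min
}

#' Triage validated check-ins into alerts
#'
#' Produces exactly one alert per check-in. The alert tier is the maximum of
#' the per-symptom tiers; when the multi-amber rule is enabled and at least
#' the threshold number of symptoms individually map to AMBER, a sub-RED
#' alert is upgraded to RED. Contributing symptoms are those whose individual
#' tier is AMBER or above; alert domains are their image under the policy's
#' domain map. Guidance follows the tier (green = reassurance, amber =
#' monitor while awaiting review, red = urgent contact), and each alert is
#' flagged in/out of the staffed monitoring hours.
#'
#' @param checkins Validated check-ins from [validate_checkins()].
#' @param policy A [triage_policy()].
#' @return Tibble of alerts: `alert_id`, `checkin_id`, `patient_id`,
#'   `raised_at`, `tier` (ordered factor), `contributing_symptoms` and
#'   `domains` (semicolon-joined, sorted), `guidance`, `in_hours`.
#' @export
#' @examples
#' raw <- data.frame(checkin_id = "c1", patient_id = "p1",
#'                   submitted_at = "2025-07-15T10:00:00+01:00")
#' raw[symptom_names()] <- 0
#' raw$dyspnea <- 3
#' triage_checkins(validate_checkins(raw), triage_policy())
triage_checkins <- function(checkins, policy = triage_policy()) {
  syms <- symptom_names()
  stopifnot(all(syms %in% names(checkins)))
  n <- nrow(checkins)

  score_mat <- as.matrix(checkins[syms])
  # per-symptom tier ranks: 1 GREEN, 2 AMBER, 3 RED
  rank_mat <- matrix(0L, nrow = n, ncol = length(syms),
                     dimnames = list(NULL, syms))
  for (s in syms) {
    rank_mat[, s] <- match(policy$symptom_tier_map[s, as.character(score_mat[, s])],
                           TIER_LEVELS)
  }

  base_rank <- if (n > 0) apply(rank_mat, 1, max) else integer(0)
  n_amber <- rowSums(rank_mat == 2L)
  tier_rank <- base_rank
  if (policy$multi_amber_upgrade) {
    upgrade <- n_amber >= policy$multi_amber_threshold & base_rank < 3L
    tier_rank[upgrade] <- 3L
  }

  contributing <- vapply(seq_len(n), function(i) {
    contrib <- syms[rank_mat[i, ] >= 2L]
    paste(sort(contrib), collapse = ";")
  }, character(1))
  domains <- vapply(seq_len(n), function(i) {
    contrib <- syms[rank_mat[i, ] >= 2L]
    paste(sort(unique(unname(policy$domain_map[contrib]))), collapse = ";")
  }, character(1))

  tibble(
    alert_id = paste0("A-", checkins$checkin_id),
    checkin_id = checkins$checkin_id,
    patient_id = checkins$patient_id,
    raised_at = checkins$submitted_at,
    tier = as_tier(TIER_LEVELS[tier_rank]),
    contributing_symptoms = contributing,
    domains = domains,
    guidance = unname(GUIDANCE_BY_TIER[TIER_LEVELS[tier_rank]]),
    in_hours = classify_coverage(checkins$submitted_at, policy$schedule)
  )
}

split_set <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}
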