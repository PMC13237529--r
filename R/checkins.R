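#' Validate raw check-in records
#'
#' Enforces the check-in contract: every record names a patient, carries an
#' ISO 8601 timestamp with explicit offset, and scores all eleven symptoms
#' with integers in 0-3. Nothing is imputed; any violation raises a classed
#' error naming the offending field.
#'
#' @param raw A data frame with columns `checkin_id`, `patient_id`,
#'   `submitted_at`, and one column per symptom (see [symptom_names()]).
#' @param policy A [triage_policy()]; supplies the service timezone.
#' @return A tibble of validated check-ins, `submitted_at` as POSIXct in the
#'   service timezone, sorted by patient, time, then `checkin_id`
#'   (lexicographic tie-break for equal timestamps).
#' @export
#' @examples
#' raw <- data.frame(checkin_id = "c1", patient_id = "p1",
#'                   submitted_at = "2025-07-14T09:30:00+01:00")
#' raw[symptom_names()] <- 0
#' validate_checkins(raw, triage_policy())
validate_checkins <- function(raw, policy = triage_policy()) {
  stopifnot(is.data.frame(raw))
  raw <- as_tibble(raw)
  syms <- symptom_names()

  for (col in c("checkin_id", "patient_id", "submitted_at")) {
    if (!col %in% names(raw)) stop_schema_mismatch("<check-ins>", col)
  }
  for (s in syms) {
    if (!s %in% names(raw)) stop_missing_symptom(s)
  }
  if (nrow(raw) == 0) {
    out <- raw[c("checkin_id", "patient_id", "submitted_at", syms)]
    out$submitted_at <- parse_timestamp(character(), policy$schedule$timezone)
    return(out)
  }

  dup <- raw$checkin_id[duplicated(raw$checkin_id)]
  if (length(dup) > 0) stop_duplicate_checkin(dup)

  for (s in syms) {
    v <- raw[[s]]
    if (anyNA(v)) stop_missing_symptom(s, raw$checkin_id[which(is.na(v))[1]])
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- is.na(v) | v != as.integer(v) | v < 0 | v > 3
    if (any(bad)) {
      i <- which(bad)[1]
      stop_score_out_of_range(s, raw[[s]][i], raw$checkin_id[i])
    }
    raw[[s]] <- as.integer(v)
  }

  raw$submitted_at <- parse_timestamp(raw$submitted_at, policy$schedule$timezone)
  raw <- raw[order(raw$patient_id, raw$submitted_at, raw$checkin_id), ]
  raw[c("checkin_id", "patient_id", "submitted_at", syms)]
}

#' Validate a single raw check-in record
#'
#' Convenience wrapper over [validate_checkins()] for one record supplied as
#' a named list or one-row data frame.
#'
#' @inheritParams validate_checkins
#' @param record Named list or one-row data frame.
#' @return A one-row validated check-in tibble.
#' @export
validate_checkin <- function(record, policy = triage_policy()) {
  if (!is.data.frame(record)) record <- as_tibble(record)
  for (s in symptom_names()) {
    if (!s %in% names(record)) stop_missing_symptom(s)
  }
  validate_checkins(record, policy)
}
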