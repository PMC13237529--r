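#' Structured safety case-finding against acute-care encounters
#'
#' For every acute-care encounter (OHAU attendance, ED presentation,
#' unplanned admission) the 48-hour lookback window
#' `[occurred_at - lookback, occurred_at]` of check-ins, alerts and clinical
#' responses is assembled and screened against four predefined candidate
#' safety-signal rules:
#'
#' * `missed_deterioration` — no amber/red alert in the lookback, but at
#'   least one green check-in on the encounter's local calendar day (the
#'   patient reported feeling well, then presented acutely the same day).
#' * `delayed_escalation` — an in-hours red alert in the lookback whose first
#'   clinical response took longer than `delay_threshold_hours` (an
#'   unanswered in-hours red counts as an unbounded delay).
#' * `inappropriate_reassurance` — a lookback check-in tiered GREEN overall
#'   that nevertheless contains a symptom score reaching the AMBER cutpoint
#'   of a reference audit policy (catches operating policies laxer than the
#'   reference).
#' * `technical_failure` — a lookback check-in with no corresponding alert
#'   record (the triage step demonstrably did not run).
#'
#' All findings are candidates for human adjudication, never automated
#' determinations of harm. Every encounter appears in the output exactly
#' once, flagged or not.
#'
#' @param encounters Data frame: `encounter_id`, `patient_id`, `occurred_at`
#'   (ISO 8601 with offset or POSIXct), `setting` (`OHAU`/`ED`/`admission`),
#'   optional `reason`.
#' @param checkins Validated check-ins.
#' @param alerts Alerts from [triage_checkins()].
#' @param responses Clinical response log (`alert_id`, `responded_at`).
#' @param policy Operating [triage_policy()].
#' @param roster Character vector of enrolled patient ids; encounters for
#'   unknown patients raise an error.
#' @param audit_policy Reference policy for the inappropriate-reassurance
#'   rule; defaults to the package default policy.
#' @param delay_threshold_hours Delay beyond which a first response is a
#'   delayed-escalation candidate; default 2.
#' @param lookback_hours Evidence window; default 48 (inclusive at -48h).
#' @return Tibble, one row per encounter: identifiers, the four logical flag
#'   columns, evidence counts (`n_checkins_lookback`, `n_amber_red_lookback`,
#'   `n_green_same_day`), and `evidence` (list column with the lookback
#'   check-in/alert ids and response delays).
#' @export
case_find <- function(encounters, checkins, alerts, responses, policy,
                      roster = unique(checkins$patient_id),
                      audit_policy = triage_policy(),
                      delay_threshold_hours = 2,
                      lookback_hours = 48) {
  tz <- policy$schedule$timezone
  encounters <- as_tibble(encounters)
  stopifnot(all(c("encounter_id", "patient_id", "occurred_at", "setting")
                %in% names(encounters)))
  if (!all(encounters$setting %in% ENCOUNTER_SETTINGS)) {
    stop_invalid_config(paste0(
      "unknown encounter setting '",
      encounters$setting[!encounters$setting %in% ENCOUNTER_SETTINGS][1], "'"))
  }
  unknown <- setdiff(encounters$patient_id, roster)
  if (length(unknown) > 0) {
    abort_data(paste0("Encounter for patient(s) with no enrolment record: ",
                      paste(unknown, collapse = ", ")),
               "oncotriage_error_unknown_patient")
  }
  encounters$occurred_at <- parse_timestamp(encounters$occurred_at, tz)

  responses <- as_tibble(responses)
  if (nrow(responses) > 0) {
    responses$responded_at <- parse_timestamp(responses$responded_at, tz)
    first_resp <- responses |>
      group_by(.data$alert_id) |>
      summarise(responded_at = min(.data$responded_at), .groups = "drop")
  } else {
    first_resp <- tibble(alert_id = character(),
                         responded_at = parse_timestamp(character(), tz))
  }

  syms <- symptom_names()
  # a green check-in is "audit-amber" if any score reaches the audit policy's
  # AMBER cutpoint for that symptom
  audit_rank <- function(ci_row) {
    max(vapply(syms, function(s) {
      match(audit_policy$symptom_tier_map[s, as.character(ci_row[[s]])],
            TIER_LEVELS)
    }, 0L))
  }

  rows <- lapply(seq_len(nrow(encounters)), function(i) {
    enc <- encounters[i, ]
    lb_start <- enc$occurred_at - lookback_hours * 3600
    pid <- enc$patient_id

    ci <- checkins[checkins$patient_id == pid &
                     checkins$submitted_at >= lb_start &
                     checkins$submitted_at <= enc$occurred_at, , drop = FALSE]
    al <- alerts[alerts$patient_id == pid &
                   alerts$raised_at >= lb_start &
                   alerts$raised_at <= enc$occurred_at, , drop = FALSE]
    amber_red <- al[al$tier != "GREEN", , drop = FALSE]

    enc_day <- local_date(enc$occurred_at, tz)
    green_al <- al[al$tier == "GREEN", , drop = FALSE]
    green_same_day <- green_al[local_date(green_al$raised_at, tz) == enc_day, ,
                               drop = FALSE]

    missed <- nrow(amber_red) == 0 && nrow(green_same_day) > 0

    in_reds <- al[al$tier == "RED" & al$in_hours, , drop = FALSE]
    delayed <- FALSE
    delays <- numeric(0)
    if (nrow(in_reds) > 0) {
      jr <- left_join(in_reds, first_resp, by = "alert_id")
      delays <- as.numeric(difftime(jr$responded_at, jr$raised_at, units = "hours"))
      delays[is.na(delays)] <- Inf
      delayed <- any(delays > delay_threshold_hours)
    }

    reassurance <- FALSE
    if (nrow(green_al) > 0) {
      green_ci <- ci[ci$checkin_id %in% green_al$checkin_id, , drop = FALSE]
      if (nrow(green_ci) > 0) {
        reassurance <- any(vapply(seq_len(nrow(green_ci)), function(k) {
          audit_rank(green_ci[k, ]) >= 2L
        }, logical(1)))
      }
    }

    technical <- !all(ci$checkin_id %in% al$checkin_id)

    tibble(
      encounter_id = enc$encounter_id,
      patient_id = pid,
      occurred_at = enc$occurred_at,
      setting = enc$setting,
      missed_deterioration = missed,
      delayed_escalation = delayed,
      inappropriate_reassurance = reassurance,
      technical_failure = technical,
      n_checkins_lookback = nrow(ci),
      n_amber_red_lookback = nrow(amber_red),
      n_green_same_day = nrow(green_same_day),
      evidence = list(list(
        lookback_start = format_timestamp(lb_start),
        lookback_end = format_timestamp(enc$occurred_at),
        checkin_ids = ci$checkin_id,
        alert_ids = al$alert_id,
        alert_tiers = as.character(al$tier),
        in_hours_red_response_delays_hours =
          delays[is.finite(delays)]
      ))
    )
  })
  if (length(rows) == 0) {
    return(tibble(encounter_id = character(), patient_id = character(),
                  occurred_at = parse_timestamp(character(), tz),
                  setting = character(),
                  missed_deterioration = logical(),
                  delayed_escalation = logical(),
                  inappropriate_reassurance = logical(),
                  technical_failure = logical(),
                  n_checkins_lookback = integer(),
                  n_amber_red_lookback = integer(),
                  n_green_same_day = integer(),
                  evidence = list()))
  }
  dplyr::bind_rows(rows)
}

#' Summarise safety case-finding output
#'
#' @param findings Output of [case_find()].
#' @return List: `n_encounters`, `counts` (named, per category),
#'   `n_findings` (total flags), and `narrative` (character lines; when no
#'   candidate is flagged this states so explicitly rather than emitting
#'   nothing).
#' @export
safety_report <- function(findings) {
  counts <- vapply(SAFETY_CATEGORIES, function(cat) {
    if (nrow(findings) == 0) 0L else sum(findings[[cat]])
  }, integer(1))
  total <- sum(counts)
  narrative <- if (total == 0) {
    paste0("No candidate safety signals identified across ",
           nrow(findings), " acute-care encounter(s).")
  } else {
    c(paste0(total, " candidate safety signal(s) across ",
             nrow(findings), " encounter(s) — for human adjudication:"),
      vapply(SAFETY_CATEGORIES[counts > 0], function(cat) {
        paste0("  ", cat, ": ", counts[[cat]])
      }, character(1)))
  }
  list(n_encounters = nrow(findings),
       counts = as.list(counts),
       n_findings = total,
       narrative = narrative)
}
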