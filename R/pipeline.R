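#' Run the full triage pipeline on files
#'
#' Chains the pipeline end to end from files on disk: read and validate
#' check-ins, triage to alerts, consolidate into episodes, attach review
#' outcomes, compute the cohort service report, and run safety case-finding
#' against acute encounters. Intermediate artifacts and the JSON report are
#' written to `out_dir`. This is what the `all` CLI subcommand calls.
#'
#' @param checkins_path Check-ins CSV/JSONL.
#' @param windows_path Enrollment windows CSV.
#' @param responses_path Clinical response log CSV (optional; empty log if
#'   `NULL`).
#' @param review_log_path Episode review log CSV (optional).
#' @param encounters_path Acute encounter CSV (optional; safety step skipped
#'   if `NULL`).
#' @param out_dir Output directory.
#' @param policy A [triage_policy()].
#' @param quiet Suppress per-stage record-count messages.
#' @return Invisibly, a list with all in-memory artifacts (`checkins`,
#'   `alerts`, `episodes`, `outcomes`, `report`, `findings`,
#'   `safety_summary`).
#' @export
run_pipeline <- function(checkins_path, windows_path,
                         responses_path = NULL, review_log_path = NULL,
                         encounters_path = NULL,
                         out_dir = ".", policy = triage_policy(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  tz <- policy$schedule$timezone
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  checkins <- read_checkins(checkins_path, policy)
  say("check-ins: ", nrow(checkins), " records")
  windows <- read_windows(windows_path, policy)
  say("enrollment windows: ", nrow(windows), " patients")
  responses <- if (is.null(responses_path)) {
    tibble(alert_id = character(),
           responded_at = parse_timestamp(character(), tz))
  } else read_responses(responses_path, policy)
  say("responses: ", nrow(responses), " records")

  alerts <- triage_checkins(checkins, policy)
  say("alerts: ", nrow(alerts), " (",
      paste(alert_distribution(alerts)$n, collapse = "/"), " green/amber/red)")
  write_table(alerts, file.path(out_dir, "alerts.csv"))

  episodes <- build_episodes(alerts, policy)
  say("episodes: ", nrow(episodes))
  write_table(episodes, file.path(out_dir, "episodes.csv"))
  jsonlite::write_json(
    lapply(seq_len(nrow(episodes)), function(i) {
      list(episode_id = episodes$episode_id[i],
           patient_id = episodes$patient_id[i],
           alert_ids = split_set(episodes$alert_ids[i])[[1]],
           domain_set = split_set(episodes$domain_set[i])[[1]],
           started_at = format_timestamp(episodes$started_at[i]),
           last_alert_at = format_timestamp(episodes$last_alert_at[i]),
           max_tier = as.character(episodes$max_tier[i]))
    }),
    file.path(out_dir, "episodes.json"), auto_unbox = TRUE, pretty = TRUE)

  review_log <- if (is.null(review_log_path)) {
    tibble(episode_id = character(),
           responded_at = parse_timestamp(character(), tz),
           action = character())
  } else read_review_log(review_log_path, policy)
  outcomes <- attach_outcomes(episodes, review_log)
  write_table(outcomes, file.path(out_dir, "episode_outcomes.csv"))

  report <- cohort_report(checkins, alerts, episodes, outcomes, responses,
                          windows, policy)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report written: ", file.path(out_dir, "report.json"))

  findings <- NULL
  summary <- NULL
  if (!is.null(encounters_path)) {
    encounters <- read_encounters(encounters_path, policy)
    say("encounters: ", nrow(encounters))
    findings <- case_find(encounters, checkins, alerts, responses, policy,
                          roster = unique(windows$patient_id))
    con <- file(file.path(out_dir, "safety_findings.jsonl"), "w")
    for (i in seq_len(nrow(findings))) {
      row <- findings[i, ]
      obj <- list(encounter_id = row$encounter_id,
                  patient_id = row$patient_id,
                  occurred_at = format_timestamp(row$occurred_at),
                  setting = row$setting,
                  flags = as.list(row[SAFETY_CATEGORIES]),
                  candidate = any(unlist(row[SAFETY_CATEGORIES])),
                  evidence = row$evidence[[1]])
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
    }
    close(con)
    summary <- safety_report(findings)
    writeLines(summary$narrative, file.path(out_dir, "safety_summary.txt"))
    say(summary$narrative[1])
  }

  invisible(list(checkins = checkins, alerts = alerts, episodes = episodes,
                 outcomes = outcomes, report = report, findings = findings,
                 safety_summary = summary))
}
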