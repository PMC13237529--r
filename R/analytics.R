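#' Engagement (check-in completion) summary
#'
#' Completion is completed patient-days divided by expected patient-days.
#' Expected patient-days are counted per enrollment window, inclusive of both
#' endpoints; a patient-day is completed when at least one check-in was
#' submitted on that local calendar day (multiple same-day submissions count
#' once).
#'
#' @param checkins Validated check-in tibble.
#' @param windows Data frame of enrollment windows: `patient_id`,
#'   `enrolled_from`, `enrolled_to` (Dates, inclusive).
#' @param tz Service timezone used to assign check-ins to calendar days.
#' @return List: `completed`, `expected`, `pct` (exact), `pct_1dp`
#'   (half-up, 1 decimal).
#' @export
#' @examples
#' # 1444 completed of 1574 expected patient-days -> 91.7%
engagement_summary <- function(checkins, windows, tz = "Europe/London") {
  stopifnot(is.data.frame(windows))
  windows$enrolled_from <- as.Date(windows$enrolled_from)
  windows$enrolled_to <- as.Date(windows$enrolled_to)
  if (any(windows$enrolled_from > windows$enrolled_to)) {
    stop_invalid_config("enrolled_from must be <= enrolled_to")
  }
  expected <- sum(as.numeric(windows$enrolled_to - windows$enrolled_from) + 1)
  if (expected == 0) {
    abort_data("no expected patient-days in enrollment windows",
               "oncotriage_error_zero_expected_days")
  }
  completed <- if (nrow(checkins) == 0) 0L else {
    nrow(distinct(tibble(patient_id = checkins$patient_id,
                         day = local_date(checkins$submitted_at, tz))))
  }
  pct <- 100 * completed / expected
  list(completed = completed, expected = expected,
       pct = pct, pct_1dp = round_half_up(pct, 1))
}

#' Alert distribution by acuity tier
#'
#' @param alerts Alert tibble from [triage_checkins()].
#' @return Tibble with one row per tier (GREEN, AMBER, RED): `tier`, `n`,
#'   `pct` (of all alerts, exact), `pct_1dp` (half-up, 1 decimal). Counts sum
#'   to the number of alerts.
#' @export
alert_distribution <- function(alerts) {
  n_by <- table(factor(alerts$tier, levels = TIER_LEVELS))
  total <- sum(n_by)
  pct <- if (total == 0) rep(NA_real_, 3) else 100 * as.numeric(n_by) / total
  tibble(tier = as_tier(TIER_LEVELS),
         n = as.integer(n_by),
         pct = pct,
         pct_1dp = round_half_up(pct, 1))
}

#' Per-patient red-alert burden
#'
#' Red-alert burden is typically right-skewed: many patients raise no red
#' alerts while a small minority account for a disproportionate share. The
#' roster must be supplied so zero-alert patients enter the denominator.
#'
#' @param alerts Alert tibble.
#' @param patient_ids Character vector: the full patient roster.
#' @return List: `per_patient` (tibble `patient_id`, `n_red`),
#'   `zero_fraction_pct`, `ge10_fraction_pct` (both exact, over roster size,
#'   with `*_1dp` half-up versions), `roster_size`.
#' @export
red_burden <- function(alerts, patient_ids) {
  if (length(patient_ids) == 0) {
    abort_data("patient roster is empty", "oncotriage_error_empty_roster")
  }
  reds <- alerts[alerts$tier == "RED", , drop = FALSE]
  counts <- table(factor(reds$patient_id, levels = patient_ids))
  per_patient <- tibble(patient_id = patient_ids, n_red = as.integer(counts))
  zero_pct <- 100 * sum(per_patient$n_red == 0) / length(patient_ids)
  ge10_pct <- 100 * sum(per_patient$n_red >= 10) / length(patient_ids)
  list(per_patient = per_patient,
       zero_fraction_pct = zero_pct,
       zero_fraction_pct_1dp = round_half_up(zero_pct, 1),
       ge10_fraction_pct = ge10_pct,
       ge10_fraction_pct_1dp = round_half_up(ge10_pct, 1),
       roster_size = length(patient_ids))
}

#' Timeliness of first clinical response to in-hours red alerts
#'
#' Restricted to red alerts raised during staffed monitoring hours (the
#' dashboard workflow); out-of-hours reds are reported as a count and
#' proportion of all reds but excluded from delay statistics. For each
#' in-hours red, the first response is used. `same_day_pct` is the share of
#' in-hours reds answered on the same local calendar day; in-hours reds with
#' no response count in the denominator and are also reported as
#' `n_unreviewed`.
#'
#' @param alerts Alert tibble.
#' @param responses Data frame: `alert_id`, `responded_at` (ISO 8601 with
#'   offset, or POSIXct).
#' @param schedule A [monitoring_schedule()] (timezone for calendar-day
#'   comparison).
#' @return List: `n_red`, `n_in_hours`, `n_out_of_hours`,
#'   `out_of_hours_pct`, `n_responded`, `n_unreviewed`,
#'   `median_minutes`, `min_minutes`, `max_minutes`, `same_day_n`,
#'   `same_day_pct`, `same_day_pct_1dp`, `delays_minutes`.
#' @export
timeliness <- function(alerts, responses, schedule = monitoring_schedule()) {
  tz <- schedule$timezone
  reds <- alerts[alerts$tier == "RED", , drop = FALSE]
  in_hours <- reds[reds$in_hours, , drop = FALSE]
  n_red <- nrow(reds)
  n_in <- nrow(in_hours)

  responses <- as_tibble(responses)
  if (nrow(responses) > 0) {
    responses$responded_at <- parse_timestamp(responses$responded_at, tz)
    first <- responses |>
      group_by(.data$alert_id) |>
      summarise(responded_at = min(.data$responded_at), .groups = "drop")
  } else {
    first <- tibble(alert_id = character(),
                    responded_at = parse_timestamp(character(), tz))
  }

  joined <- left_join(in_hours, first, by = "alert_id")
  if (any(!is.na(joined$responded_at) &
          joined$responded_at < joined$raised_at)) {
    stop_bad_timestamp("response precedes its alert")
  }
  responded <- joined[!is.na(joined$responded_at), , drop = FALSE]
  delays <- as.numeric(difftime(responded$responded_at, responded$raised_at,
                                units = "mins"))
  same_day_n <- sum(local_date(responded$responded_at, tz) ==
                      local_date(responded$raised_at, tz))
  same_day_pct <- if (n_in == 0) NA_real_ else 100 * same_day_n / n_in
  list(
    n_red = n_red,
    n_in_hours = n_in,
    n_out_of_hours = n_red - n_in,
    out_of_hours_pct = if (n_red == 0) NA_real_ else 100 * (n_red - n_in) / n_red,
    n_responded = nrow(responded),
    n_unreviewed = n_in - nrow(responded),
    median_minutes = if (length(delays)) median(delays) else NA_real_,
    min_minutes = if (length(delays)) min(delays) else NA_real_,
    max_minutes = if (length(delays)) max(delays) else NA_real_,
    same_day_n = same_day_n,
    same_day_pct = same_day_pct,
    same_day_pct_1dp = round_half_up(same_day_pct, 1),
    delays_minutes = delays
  )
}

#' Daily check-in run chart series
#'
#' One point per calendar day across the observed span (days with no
#' check-ins appear with count 0), plus the median daily count — the standard
#' quality-improvement run-chart construction.
#'
#' @param checkins Validated check-in tibble; must be nonempty.
#' @param tz Service timezone used to bucket days.
#' @return Tibble `date`, `n` with attribute `"median"` (the median of the
#'   daily counts).
#' @export
run_chart <- function(checkins, tz = "Europe/London") {
  if (nrow(checkins) == 0) stop_empty_input("no check-ins for run chart")
  days <- local_date(checkins$submitted_at, tz)
  span <- seq(min(days), max(days), by = "day")
  n <- as.integer(table(factor(as.character(days), levels = as.character(span))))
  out <- tibble(date = span, n = n)
  attr(out, "median") <- median(as.numeric(n))
  out
}

#' Plot a run chart with its median line
#'
#' @param series Output of [run_chart()].
#' @return A ggplot object.
#' @export
plot_run_chart <- function(series) {
  med <- attr(series, "median")
  ggplot2::ggplot(series, ggplot2::aes(x = .data$date, y = .data$n)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = med, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Check-ins per day",
                  subtitle = paste0("median = ", round_half_up(med, 1))) +
    ggplot2::theme_minimal()
}

#' Full cohort service report
#'
#' Assembles the descriptive service metrics into one JSON-serialisable
#' list: engagement, alert distribution, red-alert burden, timeliness,
#' escalation breakdown (per action, among actionable episodes and among all
#' episodes), and the run-chart series. Every percentage is emitted alongside
#' its numerator and denominator.
#'
#' @param checkins Validated check-ins.
#' @param alerts Alerts from [triage_checkins()].
#' @param episodes Episodes from [build_episodes()].
#' @param outcomes Outcomes from [attach_outcomes()].
#' @param responses Clinical response log (`alert_id`, `responded_at`).
#' @param windows Enrollment windows (see [engagement_summary()]).
#' @param policy A [triage_policy()].
#' @return A nested list; serialise with [jsonlite::write_json()].
#' @export
cohort_report <- function(checkins, alerts, episodes, outcomes, responses,
                          windows, policy = triage_policy()) {
  tz <- policy$schedule$timezone
  eng <- engagement_summary(checkins, windows, tz)
  dist <- alert_distribution(alerts)
  burden <- red_burden(alerts, unique(windows$patient_id))
  timing <- timeliness(alerts, responses, policy$schedule)
  chart <- run_chart(checkins, tz)

  n_ep <- nrow(episodes)
  n_act <- sum(outcomes$actionable)
  action_counts <- table(factor(outcomes$action, levels = ACTION_LEVELS))
  escalation <- lapply(setdiff(ACTION_LEVELS, "none"), function(a) {
    n <- as.integer(action_counts[[a]])
    list(action = a, n = n,
         pct_of_actionable = if (n_act > 0) round_half_up(100 * n / n_act, 1) else NA_real_,
         pct_of_all = if (n_ep > 0) round_half_up(100 * n / n_ep, 1) else NA_real_)
  })

  stats <- if (n_ep > 0) episode_stats(episodes) else NULL
  list(
    engagement = list(completed = eng$completed, expected = eng$expected,
                      pct = eng$pct_1dp),
    alert_distribution = lapply(seq_len(nrow(dist)), function(i) {
      list(tier = as.character(dist$tier[i]), n = dist$n[i], pct = dist$pct_1dp[i])
    }),
    red_burden = list(
      roster_size = burden$roster_size,
      n_zero = sum(burden$per_patient$n_red == 0),
      zero_fraction_pct = burden$zero_fraction_pct_1dp,
      n_ge10 = sum(burden$per_patient$n_red >= 10),
      ge10_fraction_pct = burden$ge10_fraction_pct_1dp),
    episodes = list(
      n_alerts_in = if (is.null(stats)) 0L else stats$n_alerts_in,
      n_episodes = n_ep,
      mean_alerts_per_episode =
        if (is.null(stats)) NA_real_ else round_half_up(stats$mean_alerts_per_episode, 1),
      consolidation_factor =
        if (is.null(stats)) NA_real_ else round_half_up(stats$consolidation_factor, 1),
      n_actionable = n_act,
      actionable_pct = if (n_ep > 0) round_half_up(100 * n_act / n_ep, 1) else NA_real_),
    escalation = escalation,
    timeliness = timing[c("n_red", "n_in_hours", "n_out_of_hours",
                          "n_responded", "n_unreviewed", "median_minutes",
                          "min_minutes", "max_minutes", "same_day_n",
                          "same_day_pct_1dp")],
    run_chart = list(dates = as.character(chart$date), n = chart$n,
                     median = attr(chart, "median"))
  )
}
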