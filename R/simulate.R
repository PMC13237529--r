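#' Synthetic cohort simulation configuration
#'
#' Defaults emulate a ~10-week monitored outpatient cohort on systemic
#' anticancer therapy: 32 patients enrolled on staggered start dates over the
#' first three weeks, ~92% daily check-in adherence, a ~75/16/9
#' green/amber/red alert split, toxicity peaking mid-cycle (day 8 of a
#' 21-day cycle), a right-skewed per-patient red-alert burden driven by a
#' log-normal patient frailty, and first-response delays with median 47
#' minutes on the observed 12 min - 6 h range.
#'
#' Tier emission is two-stage: each adhered patient-day receives tier
#' probabilities equal to the configured `tier_mix` tilted multiplicatively
#' by the patient's frailty and the day's cycle-phase weight, renormalised so
#' the cohort-level expected mix equals `tier_mix` exactly; symptom scores
#' are then drawn consistent with the drawn tier under the default triage
#' policy (one score-2 symptom for amber; one score-3 symptom or two score-2
#' symptoms for red; all scores at most 1 for green).
#'
#' @param n_patients Number of enrolled patients.
#' @param duration_days Study duration in days.
#' @param start_date First study day (Date or "YYYY-MM-DD").
#' @param enrollment_stagger_days Patients enrol uniformly over the first
#'   this-many days, so expected patient-days < n_patients x duration_days.
#' @param cycle_length_days Treatment cycle length.
#' @param cycle_peak_day Day-in-cycle where toxicity peaks.
#' @param cycle_effect Size of the mid-cycle multiplicative bump (0 = none).
#' @param adherence_p Daily probability a check-in is submitted.
#' @param frailty_sdlog SD (log scale) of the per-patient toxicity
#'   multiplier; location is set so the multiplier has mean 1.
#' @param tier_mix Named probabilities `green`, `amber`, `red` summing to 1:
#'   the cohort-level alert mix the generator is calibrated to.
#' @param symptom_weights Named probabilities over the 11 symptoms: which
#'   symptom goes severe on an amber/red day.
#' @param symptom_persistence Probability a severe day uses the patient's
#'   dominant toxicity rather than a fresh draw (drives domain continuity).
#' @param red_single_severe_p Probability a red day is one score-3 symptom
#'   (otherwise two score-2 symptoms, exercising the multi-amber rule).
#' @param minor_symptom_p Per-symptom probability of a background score of 1.
#' @param checkin_hour_mean,checkin_hour_sd Check-in clock time model
#'   (Gaussian hours, truncated to `[6, 23)`); the default puts roughly half
#'   of red alerts inside weekday staffed hours.
#' @param response_delay_median_min Target median first-response delay for
#'   in-hours red alerts (minutes).
#' @param response_delay_sdlog Log-scale SD of the delay distribution.
#' @param response_delay_range Truncation range in minutes.
#' @param actionability_p_by_tier Named probabilities (`AMBER`, `RED`) that an
#'   episode with that max tier is clinically actionable.
#' @param action_mix Named probabilities over actions given actionable.
#' @param intraday_event_rate Per green patient-day probability of an acute
#'   encounter later the same day (exercises safety case-finding).
#' @param seed Integer RNG seed; identical configs give identical cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 32,
                              duration_days = 70,
                              start_date = "2025-07-11",
                              enrollment_stagger_days = 21,
                              cycle_length_days = 21,
                              cycle_peak_day = 8,
                              cycle_effect = 1.0,
                              adherence_p = 0.917,
                              frailty_sdlog = 1.2,
                              tier_mix = c(green = 0.749, amber = 0.158, red = 0.093),
                              symptom_weights = c(
                                fatigue = 0.20, nausea_vomiting = 0.15,
                                diarrhea = 0.12, pain = 0.12,
                                temperature = 0.08, constipation = 0.07,
                                oral_mucositis = 0.07,
                                peripheral_neuropathy = 0.06,
                                skin_rash = 0.05, dyspnea = 0.04,
                                bleeding_bruising = 0.04),
                              symptom_persistence = 0.7,
                              red_single_severe_p = 0.7,
                              minor_symptom_p = 0.15,
                              checkin_hour_mean = 10.5,
                              checkin_hour_sd = 2.5,
                              response_delay_median_min = 47,
                              response_delay_sdlog = 0.7,
                              response_delay_range = c(12, 360),
                              actionability_p_by_tier = c(AMBER = 0.25, RED = 0.55),
                              action_mix = c(telephone_advice = 0.50,
                                             OHAU_assessment = 0.375,
                                             ED_referral = 0.083,
                                             admission = 0.042),
                              intraday_event_rate = 0.0015,
                              seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    duration_days = as.integer(duration_days),
    start_date = as.Date(start_date),
    enrollment_stagger_days = as.integer(enrollment_stagger_days),
    cycle_length_days = as.integer(cycle_length_days),
    cycle_peak_day = cycle_peak_day,
    cycle_effect = cycle_effect,
    adherence_p = adherence_p,
    frailty_sdlog = frailty_sdlog,
    tier_mix = tier_mix,
    symptom_weights = symptom_weights,
    symptom_persistence = symptom_persistence,
    red_single_severe_p = red_single_severe_p,
    minor_symptom_p = minor_symptom_p,
    checkin_hour_mean = checkin_hour_mean,
    checkin_hour_sd = checkin_hour_sd,
    response_delay_median_min = response_delay_median_min,
    response_delay_sdlog = response_delay_sdlog,
    response_delay_range = response_delay_range,
    actionability_p_by_tier = actionability_p_by_tier,
    action_mix = action_mix,
    intraday_event_rate = intraday_event_rate,
    seed = as.integer(seed)
  )
  probs <- c(cfg$adherence_p, cfg$tier_mix, cfg$symptom_persistence,
             cfg$red_single_severe_p, cfg$minor_symptom_p,
             cfg$actionability_p_by_tier, cfg$action_mix,
             cfg$intraday_event_rate)
  if (any(probs < 0 | probs > 1)) {
    stop_invalid_config("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$tier_mix) - 1) > 1e-8) {
    stop_invalid_config("tier_mix must sum to 1")
  }
  if (!setequal(names(cfg$tier_mix), c("green", "amber", "red"))) {
    stop_invalid_config("tier_mix needs names green, amber, red")
  }
  if (!setequal(names(cfg$symptom_weights), symptom_names())) {
    stop_invalid_config("symptom_weights must cover the 11 symptoms")
  }
  if (cfg$n_patients < 1 || cfg$duration_days < 1 || cfg$cycle_length_days < 1) {
    stop_invalid_config("n_patients, duration_days, cycle_length_days must be positive")
  }
  if (cfg$enrollment_stagger_days < 1 ||
      cfg$enrollment_stagger_days > cfg$duration_days) {
    stop_invalid_config("enrollment_stagger_days must be in 1..duration_days")
  }
  if (cfg$response_delay_range[1] <= 0 ||
      cfg$response_delay_range[1] >= cfg$response_delay_range[2]) {
    stop_invalid_config("response_delay_range must be increasing and positive")
  }
  structure(cfg, class = "simulation_config")
}

# scale p_raw so that mean(pmin(p_raw * s, cap)) == target_mean, by a short
# fixed-point iteration; keeps the cohort-level expected tier mix exactly on
# target even when extreme frailty x cycle tilts would push probabilities
# past the cap.
rescale_capped <- function(p_raw, target_mean, cap) {
  if (target_mean == 0 || length(p_raw) == 0) return(rep(0, length(p_raw)))
  s <- target_mean / mean(p_raw)
  for (k in 1:25) {
    p <- pmin(p_raw * s, cap)
    m <- mean(p)
    if (abs(m - target_mean) < 1e-12) break
    s <- s * target_mean / m
  }
  pmin(p_raw * s, cap)
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- out < lower | out >= upper
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lower | out >= upper
  }
  out
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  out <- rlnorm(n, meanlog, sdlog)
  bad <- out < lower | out > upper
  while (any(bad)) {
    out[bad] <- rlnorm(sum(bad), meanlog, sdlog)
    bad <- out < lower | out > upper
  }
  out
}

#' Simulate a synthetic monitored cohort
#'
#' Generates a complete, internally consistent bundle: patients (with
#' frailties), enrollment windows, daily check-ins, the alerts they triage
#' to under `policy`, first-response log for in-hours red alerts, episodes,
#' an episode review log with actions, and acute-care encounters (downstream
#' of actionable episodes, plus rare same-day events after a green check-in).
#' Identical `config` (including `seed`) gives identical output.
#'
#' @param config A [simulation_config()].
#' @param policy A [triage_policy()]; tier calibration assumes the default
#'   policy's score cutpoints.
#' @return List of tibbles: `patients`, `windows`, `checkins`, `alerts`,
#'   `responses`, `episodes`, `review_log`, `encounters`, plus `config`.
#' @export
#' @examples
#' bundle <- simulate_cohort(simulation_config(n_patients = 4,
#'                                             duration_days = 14, seed = 7))
#' nrow(bundle$checkins)
simulate_cohort <- function(config = simulation_config(),
                            policy = triage_policy()) {
  stopifnot(inherits(config, "simulation_config"))
  tz <- policy$schedule$timezone
  set.seed(config$seed)
  syms <- symptom_names()

  pid <- sprintf("P%03d", seq_len(config$n_patients))
  frailty <- rlnorm(config$n_patients,
                    meanlog = -config$frailty_sdlog^2 / 2,
                    sdlog = config$frailty_sdlog)
  dominant <- sample(syms, config$n_patients, replace = TRUE,
                     prob = config$symptom_weights[syms])
  patients <- tibble(patient_id = pid, frailty = frailty,
                     dominant_symptom = dominant)

  start_offset <- floor(runif(config$n_patients,
                              0, config$enrollment_stagger_days))
  windows <- tibble(
    patient_id = pid,
    enrolled_from = config$start_date + start_offset,
    enrolled_to = config$start_date + config$duration_days - 1
  )

  # patient-day grid over enrollment windows
  grid <- tidyr::uncount(
    tibble(patient_id = pid, from = windows$enrolled_from,
           frailty = frailty, dominant = dominant,
           ndays = as.integer(windows$enrolled_to - windows$enrolled_from) + 1L),
    weights = .data$ndays, .id = "day_idx")
  grid$date <- grid$from + grid$day_idx - 1L
  # cycle phase counted from each patient's enrollment (cycle 1 day 1)
  phase <- ((grid$day_idx - 1L) %% config$cycle_length_days) + 1L
  grid$cycle_w <- 1 + config$cycle_effect *
    exp(-((phase - config$cycle_peak_day)^2) / (2 * 2.5^2))

  # adherence: one Bernoulli per expected patient-day
  grid <- grid[runif(nrow(grid)) < config$adherence_p, , drop = FALSE]
  n <- nrow(grid)

  if (n > 0) {
    tilt <- grid$frailty * grid$cycle_w
    tilt <- tilt / mean(tilt)
    p_red <- rescale_capped(config$tier_mix[["red"]] * tilt,
                            config$tier_mix[["red"]], cap = 0.90)
    amber_cap <- pmax(0.97 - p_red, 0)
    p_amber <- rescale_capped(config$tier_mix[["amber"]] * tilt,
                              config$tier_mix[["amber"]], cap = amber_cap)
    u <- runif(n)
    tier <- ifelse(u < p_red, "RED", ifelse(u < p_red + p_amber, "AMBER", "GREEN"))

    # background minor symptoms (score 1) never change the tier
    scores <- matrix(
      as.integer(runif(n * length(syms)) < config$minor_symptom_p),
      nrow = n, dimnames = list(NULL, syms))

    pick_severe <- function(rows) {
      use_dom <- runif(length(rows)) < config$symptom_persistence
      out <- grid$dominant[rows]
      k <- sum(!use_dom)
      if (k > 0) out[!use_dom] <- sample(syms, k, replace = TRUE,
                                         prob = config$symptom_weights[syms])
      out
    }
    col_of <- function(s) match(s, syms)
    amber_rows <- which(tier == "AMBER")
    if (length(amber_rows) > 0) {
      scores[cbind(amber_rows, col_of(pick_severe(amber_rows)))] <- 2L
    }
    red_rows <- which(tier == "RED")
    if (length(red_rows) > 0) {
      single <- runif(length(red_rows)) < config$red_single_severe_p
      s1 <- pick_severe(red_rows)
      scores[cbind(red_rows[single], col_of(s1[single]))] <- 3L
      multi <- red_rows[!single]
      if (length(multi) > 0) {
        first <- s1[!single]
        second <- vapply(first, function(s) {
          sample(setdiff(syms, s), 1, prob = config$symptom_weights[setdiff(syms, s)])
        }, character(1))
        scores[cbind(multi, col_of(first))] <- 2L
        scores[cbind(multi, col_of(second))] <- 2L
      }
    }

    hour <- rtrunc_norm(n, config$checkin_hour_mean, config$checkin_hour_sd,
                        6, 23)
    secs <- round(hour * 3600)
    submitted_at <- lubridate::force_tz(
      as.POSIXct(grid$date, tz = "UTC"), tz) + secs

    checkins <- tibble(
      checkin_id = sprintf("C%06d", seq_len(n)),
      patient_id = grid$patient_id,
      submitted_at = submitted_at
    )
    checkins <- dplyr::bind_cols(checkins, as_tibble(scores))
    checkins <- checkins[order(checkins$patient_id, checkins$submitted_at,
                               checkins$checkin_id), ]
  } else {
    checkins <- tibble(checkin_id = character(), patient_id = character(),
                       submitted_at = parse_timestamp(character(), tz))
    checkins[syms] <- integer(0)
  }

  alerts <- triage_checkins(checkins, policy)

  # first clinical response for in-hours red alerts
  in_reds <- alerts[alerts$tier == "RED" & alerts$in_hours, , drop = FALSE]
  if (nrow(in_reds) > 0) {
    delay_min <- rtrunc_lnorm(nrow(in_reds),
                              meanlog = log(config$response_delay_median_min),
                              sdlog = config$response_delay_sdlog,
                              lower = config$response_delay_range[1],
                              upper = config$response_delay_range[2])
    responses <- tibble(alert_id = in_reds$alert_id,
                        responded_at = in_reds$raised_at + round(delay_min * 60))
  } else {
    responses <- tibble(alert_id = character(),
                        responded_at = parse_timestamp(character(), tz))
  }

  episodes <- build_episodes(alerts, policy)

  # episode review log: actionability by max tier, action mix as configured
  if (nrow(episodes) > 0) {
    p_act <- config$actionability_p_by_tier[as.character(episodes$max_tier)]
    actionable <- runif(nrow(episodes)) < p_act
    acted <- which(actionable)
    review_log <- tibble(
      episode_id = episodes$episode_id[acted],
      responded_at = episodes$last_alert_at[acted] +
        round(runif(length(acted), 1, 6) * 3600),
      action = if (length(acted) > 0) {
        sample(names(config$action_mix), length(acted), replace = TRUE,
               prob = config$action_mix)
      } else character(0)
    )
  } else {
    review_log <- tibble(episode_id = character(),
                         responded_at = parse_timestamp(character(), tz),
                         action = character())
  }

  # acute-care encounters downstream of actionable episodes
  setting_by_action <- c(OHAU_assessment = "OHAU", ED_referral = "ED",
                         admission = "admission")
  esc <- review_log[review_log$action %in% names(setting_by_action), , drop = FALSE]
  enc_list <- list()
  if (nrow(esc) > 0) {
    ep_pid <- setNames(episodes$patient_id, episodes$episode_id)
    enc_list[[1]] <- tibble(
      patient_id = unname(ep_pid[esc$episode_id]),
      occurred_at = esc$responded_at + 2 * 3600,
      setting = unname(setting_by_action[esc$action]),
      reason = "escalation after episode review"
    )
  }
  # rare intraday deterioration after a green check-in (no preceding
  # amber/red) — the case safety case-finding exists to surface
  greens <- alerts[alerts$tier == "GREEN", , drop = FALSE]
  if (nrow(greens) > 0) {
    hit <- runif(nrow(greens)) < config$intraday_event_rate
    if (any(hit)) {
      g <- greens[hit, , drop = FALSE]
      enc_list[[length(enc_list) + 1]] <- tibble(
        patient_id = g$patient_id,
        occurred_at = g$raised_at + round(runif(nrow(g), 6, 10) * 3600),
        setting = sample(ENCOUNTER_SETTINGS, nrow(g), replace = TRUE,
                         prob = c(0.5, 0.35, 0.15)),
        reason = "acute intraday deterioration"
      )
    }
  }
  if (length(enc_list) > 0) {
    encounters <- dplyr::bind_rows(enc_list)
    encounters <- encounters[order(encounters$occurred_at,
                                   encounters$patient_id), ]
    encounters <- dplyr::bind_cols(
      tibble(encounter_id = sprintf("E%04d", seq_len(nrow(encounters)))),
      encounters)
  } else {
    encounters <- tibble(encounter_id = character(), patient_id = character(),
                         occurred_at = parse_timestamp(character(), tz),
                         setting = character(), reason = character())
  }

  list(patients = patients, windows = windows, checkins = checkins,
       alerts = alerts, responses = responses, episodes = episodes,
       review_log = review_log, encounters = encounters, config = config)
}

#' Write a simulated bundle as the pipeline's file formats
#'
#' Emits the exact CSV dialects the readers in this package consume
#' (UTF-8, comma-separated, header row, ISO 8601 timestamps with offsets),
#' so write-then-read is lossless. Reruns with the same bundle are
#' byte-identical.
#'
#' @param bundle Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- function(df) {
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_timestamp(df[[col]])
      if (is.factor(df[[col]])) df[[col]] <- as.character(df[[col]])
    }
    df
  }
  paths <- c(patients = "patients.csv", windows = "windows.csv",
             checkins = "checkins.csv", alerts = "alerts.csv",
             responses = "responses.csv", episodes = "episodes.csv",
             review_log = "review_log.csv", encounters = "encounters.csv")
  out <- character(0)
  for (nm in names(paths)) {
    df <- bundle[[nm]]
    if (nm == "patients") df <- df[c("patient_id")] # frailty is latent
    p <- file.path(dir, paths[[nm]])
    readr::write_csv(stamp(as_tibble(df)), p, progress = FALSE)
    out[nm] <- p
  }
  invisible(out)
}
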