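#' Consolidate amber/red alerts into episode-level review events
#'
#' Implements the rolling-window, domain-continuity grouping rule. Green
#' alerts are ignored. Per patient, alerts are processed in chronological
#' order (ties broken by `checkin_id`); an alert joins an existing open
#' episode when it falls within `episode_window_hours` (inclusive) of that
#' episode's most recent alert AND shares at least one symptom domain with
#' the episode's cumulative domain set. Otherwise it starts a new episode,
#' so one patient may hold several concurrent open episodes with distinct
#' symptom patterns. When an alert is eligible for more than one episode it
#' joins the one with the most recent last alert, ties broken by larger
#' domain intersection, then by earlier episode start; episodes are never
#' merged. The result is a deterministic partition of the amber/red alerts,
#' invariant to input row order.
#'
#' @param alerts Alert tibble from [triage_checkins()] (green rows allowed,
#'   they are dropped).
#' @param policy A [triage_policy()] supplying `episode_window_hours`.
#' @return Tibble of episodes: `episode_id`, `patient_id`, `alert_ids`
#'   (semicolon-joined, chronological), `n_alerts`, `domain_set`
#'   (semicolon-joined cumulative union), `started_at`, `last_alert_at`,
#'   `max_tier`.
#' @export
build_episodes <- function(alerts, policy = triage_policy()) {
  stopifnot(is.data.frame(alerts))
  window_h <- policy$episode_window_hours
  active <- alerts[alerts$tier != "GREEN", , drop = FALSE]
  active <- active[order(active$patient_id, active$raised_at, active$checkin_id), ]

  episodes <- list()
  for (pid in unique(active$patient_id)) {
    pa <- active[active$patient_id == pid, , drop = FALSE]
    pa_domains <- split_set(pa$domains)
    open <- list() # each: ids, domain_set, started_at, last_at, max_rank
    for (i in seq_len(nrow(pa))) {
      a_dom <- pa_domains[[i]]
      a_time <- pa$raised_at[i]
      a_rank <- match(as.character(pa$tier[i]), TIER_LEVELS)

      eligible <- integer(0)
      for (j in seq_along(open)) {
        gap_h <- as.numeric(difftime(a_time, open[[j]]$last_at, units = "hours"))
        if (gap_h <= window_h && length(intersect(a_dom, open[[j]]$domain_set)) > 0) {
          eligible <- c(eligible, j)
        }
      }

      if (length(eligible) == 0) {
        open[[length(open) + 1]] <- list(
          ids = pa$alert_id[i], domain_set = a_dom,
          started_at = a_time, last_at = a_time, max_rank = a_rank)
      } else {
        if (length(eligible) > 1) {
          last_ats <- vapply(open[eligible], function(e) as.numeric(e$last_at), 0)
          inter <- vapply(open[eligible],
                          function(e) length(intersect(a_dom, e$domain_set)), 0L)
          starts <- vapply(open[eligible], function(e) as.numeric(e$started_at), 0)
          ord <- order(-last_ats, -inter, starts)
          eligible <- eligible[ord[1]]
        }
        j <- eligible
        open[[j]]$ids <- c(open[[j]]$ids, pa$alert_id[i])
        open[[j]]$domain_set <- union(open[[j]]$domain_set, a_dom)
        open[[j]]$last_at <- a_time
        open[[j]]$max_rank <- max(open[[j]]$max_rank, a_rank)
      }
    }
    for (e in open) {
      episodes[[length(episodes) + 1]] <- tibble(
        patient_id = pid,
        alert_ids = paste(e$ids, collapse = ";"),
        n_alerts = length(e$ids),
        domain_set = paste(sort(e$domain_set), collapse = ";"),
        started_at = e$started_at,
        last_alert_at = e$last_at,
        max_tier = as_tier(TIER_LEVELS[e$max_rank])
      )
    }
  }

  if (length(episodes) == 0) {
    return(tibble(episode_id = character(), patient_id = character(),
                  alert_ids = character(), n_alerts = integer(),
                  domain_set = character(),
                  started_at = active$raised_at[0],
                  last_alert_at = active$raised_at[0],
                  max_tier = as_tier(character())))
  }
  out <- dplyr::bind_rows(episodes)
  out <- out[order(out$patient_id, out$started_at, out$alert_ids), ]
  out <- dplyr::bind_cols(
    tibble(episode_id = sprintf("EP%04d", seq_len(nrow(out)))), out)
  if (anyNA(out$patient_id)) {
    abort_data("episode with missing patient id",
               "oncotriage_error_mixed_patient_episode")
  }
  out
}

#' Attach review outcomes to episodes
#'
#' A review log records clinical actions taken against episodes. Each episode
#' receives its highest-severity recorded action under the ordering
#' none < telephone_advice < OHAU_assessment < ED_referral < admission;
#' episodes absent from the log get `none`. An episode is actionable iff its
#' action is not `none`.
#'
#' @param episodes Episode tibble from [build_episodes()].
#' @param review_log Data frame with columns `episode_id`, `responded_at`,
#'   `action` (one of the ordering above, excluding `none` for recorded
#'   events).
#' @return Tibble: `episode_id`, `actionable`, `action` (ordered factor).
#' @export
attach_outcomes <- function(episodes, review_log) {
  stopifnot(is.data.frame(episodes), is.data.frame(review_log))
  if (nrow(review_log) > 0) {
    unknown <- setdiff(review_log$episode_id, episodes$episode_id)
    if (length(unknown) > 0) {
      abort_data(paste0("Review log references unknown episode(s): ",
                        paste(unknown, collapse = ", ")),
                 "oncotriage_error_unknown_episode_reference")
    }
    if (!all(review_log$action %in% ACTION_LEVELS)) {
      stop_invalid_config(paste0(
        "unknown action '",
        review_log$action[!review_log$action %in% ACTION_LEVELS][1], "'"))
    }
  }
  best <- rep("none", nrow(episodes))
  names(best) <- episodes$episode_id
  for (i in seq_len(nrow(review_log))) {
    eid <- review_log$episode_id[i]
    if (match(review_log$action[i], ACTION_LEVELS) > match(best[eid], ACTION_LEVELS)) {
      best[eid] <- review_log$action[i]
    }
  }
  tibble(episode_id = episodes$episode_id,
         actionable = unname(best) != "none",
         action = as_action(unname(best)))
}

#' Episode-level workload statistics
#'
#' Summarises how many discrete review events the episode grouping produces
#' from the raw amber/red alert stream. The consolidation factor — alerts in
#' divided by episodes out — is the fold-reduction in review workload.
#'
#' @param episodes Episode tibble from [build_episodes()]; must be nonempty.
#' @return List with `n_alerts_in`, `n_episodes`, `mean_alerts_per_episode`,
#'   `alerts_per_episode_range` (min, max), `episodes_per_patient_median`,
#'   `episodes_per_patient_range`, `consolidation_factor`.
#' @export
episode_stats <- function(episodes) {
  if (nrow(episodes) == 0) {
    stop_empty_input("no episodes; per-episode means are undefined")
  }
  per_patient <- table(episodes$patient_id)
  list(
    n_alerts_in = sum(episodes$n_alerts),
    n_episodes = nrow(episodes),
    mean_alerts_per_episode = sum(episodes$n_alerts) / nrow(episodes),
    alerts_per_episode_range = c(min(episodes$n_alerts), max(episodes$n_alerts)),
    episodes_per_patient_median = median(as.numeric(per_patient)),
    episodes_per_patient_range = c(min(per_patient), max(per_patient)),
    consolidation_factor = sum(episodes$n_alerts) / nrow(episodes)
  )
}
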