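# Shared fixture builders. All fixtures are constructed in code; timestamps
# use the service timezone (Europe/London) via explicit offsets.

default_policy <- triage_policy()

# one raw check-in record with all scores 0 unless overridden
make_raw_checkin <- function(checkin_id = "c1", patient_id = "p1",
                             submitted_at = "2025-07-15T10:00:00+01:00", ...) {
  rec <- as.list(setNames(rep(0L, 11), symptom_names()))
  over <- list(...)
  rec[names(over)] <- over
  tibble::as_tibble(c(list(checkin_id = checkin_id, patient_id = patient_id,
                           submitted_at = submitted_at), rec))
}

# a batch of raw check-ins with a score matrix (rows = records)
make_raw_batch <- function(scores, patient_id = "p1",
                           t0 = "2025-07-15T10:00:00+01:00", step_hours = 24) {
  stopifnot(ncol(scores) == 11)
  colnames(scores) <- symptom_names()
  t0 <- oncotriage::parse_timestamp(t0)
  dplyr::bind_cols(
    tibble::tibble(
      checkin_id = sprintf("c%04d", seq_len(nrow(scores))),
      patient_id = rep_len(patient_id, nrow(scores)),
      submitted_at = format_timestamp(t0 + (seq_len(nrow(scores)) - 1) * step_hours * 3600)
    ),
    tibble::as_tibble(scores))
}

# synthetic amber/red alert stream for episode tests
make_alerts <- function(patient_id, times, domains,
                        tiers = rep("AMBER", length(times)),
                        t0 = "2025-07-14T10:00:00+01:00") {
  t0 <- oncotriage::parse_timestamp(t0)
  tibble::tibble(
    alert_id = sprintf("%s-a%03d", patient_id[1], seq_along(times)),
    checkin_id = sprintf("%s-c%03d", patient_id[1], seq_along(times)),
    patient_id = rep_len(patient_id, length(times)),
    raised_at = t0 + times * 3600,
    tier = factor(tiers, levels = c("GREEN", "AMBER", "RED"), ordered = TRUE),
    contributing_symptoms = "",
    domains = domains,
    guidance = ifelse(tiers == "RED", "urgent_contact",
                      ifelse(tiers == "AMBER", "monitor_await_review", "reassurance")),
    in_hours = classify_coverage(t0 + times * 3600, triage_policy()$schedule)
  )
}

# brute-force 48h-gap chain clustering for a single-domain alert stream:
# sort times, start a new chain whenever the gap to the previous alert
# exceeds the window
oracle_chain_sizes <- function(times_hours, window = 48) {
  ts <- sort(times_hours)
  if (length(ts) == 0) return(integer(0))
  sizes <- integer(0)
  cur <- 1L
  for (i in seq_along(ts)[-1]) {
    if (ts[i] - ts[i - 1] <= window) cur <- cur + 1L
    else { sizes <- c(sizes, cur); cur <- 1L }
  }
  c(sizes, cur)
}

# random valid check-in batch for property tests
random_checkins <- function(n, seed) {
  withr::with_seed(seed, {
    scores <- matrix(sample(0:3, n * 11, replace = TRUE,
                            prob = c(0.7, 0.15, 0.1, 0.05)), ncol = 11)
    make_raw_batch(scores)
  })
}
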