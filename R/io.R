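# Strict table readers. Each enforces its declared schema: missing columns
# fail with a schema error, unknown columns warn, timestamps must carry an
# explicit UTC offset. CSV is the canonical dialect; check-ins may also be
# JSON Lines (one object per line).

read_strict <- function(path, required, tz, ts_cols, jsonl_ok = FALSE) {
  if (!file.exists(path)) {
    abort_data(paste0("Input file not found: ", path), "oncotriage_error_io")
  }
  df <- if (jsonl_ok && grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) stop_schema_mismatch(path, missing)
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    rlang::warn(paste0("Ignoring unknown column(s) in ", path, ": ",
                       paste(extra, collapse = ", ")))
  }
  df <- df[required]
  for (col in ts_cols) df[[col]] <- parse_timestamp(df[[col]], tz)
  df
}

#' Read pipeline input files
#'
#' Strict, schema-checked readers for every artifact the pipeline consumes.
#' `read_checkins()` accepts CSV or JSON Lines (by extension) and returns
#' validated check-ins; the others return tibbles with timestamps parsed into
#' the policy's service timezone.
#'
#' @param path Input file path.
#' @param policy A [triage_policy()] (service timezone and validation rules).
#' @return A tibble of the corresponding records.
#' @export
read_checkins <- function(path, policy = triage_policy()) {
  df <- read_strict(path,
                    c("checkin_id", "patient_id", "submitted_at", symptom_names()),
                    policy$schedule$timezone, character(0), jsonl_ok = TRUE)
  validate_checkins(df, policy)
}

#' @rdname read_checkins
#' @export
read_alerts <- function(path, policy = triage_policy()) {
  df <- read_strict(path,
                    c("alert_id", "checkin_id", "patient_id", "raised_at",
                      "tier", "contributing_symptoms", "domains", "guidance",
                      "in_hours"),
                    policy$schedule$timezone, "raised_at")
  if (!all(df$tier %in% TIER_LEVELS)) {
    stop_schema_mismatch(path, "tier (values must be GREEN/AMBER/RED)")
  }
  df$tier <- as_tier(df$tier)
  df$in_hours <- as.logical(df$in_hours)
  df
}

#' @rdname read_checkins
#' @export
read_responses <- function(path, policy = triage_policy()) {
  read_strict(path, c("alert_id", "responded_at"),
              policy$schedule$timezone, "responded_at")
}

#' @rdname read_checkins
#' @export
read_encounters <- function(path, policy = triage_policy()) {
  df <- read_strict(path, c("encounter_id", "patient_id", "occurred_at",
                            "setting", "reason"),
                    policy$schedule$timezone, "occurred_at")
  if (!all(df$setting %in% ENCOUNTER_SETTINGS)) {
    stop_schema_mismatch(path, "setting (values must be OHAU/ED/admission)")
  }
  df
}

#' @rdname read_checkins
#' @export
read_review_log <- function(path, policy = triage_policy()) {
  read_strict(path, c("episode_id", "responded_at", "action"),
              policy$schedule$timezone, "responded_at")
}

#' @rdname read_checkins
#' @export
read_windows <- function(path, policy = triage_policy()) {
  df <- read_strict(path, c("patient_id", "enrolled_from", "enrolled_to"),
                    policy$schedule$timezone, character(0))
  df$enrolled_from <- as.Date(df$enrolled_from)
  df$enrolled_to <- as.Date(df$enrolled_to)
  if (anyNA(df$enrolled_from) || anyNA(df$enrolled_to)) {
    stop_schema_mismatch(path, "enrolled_from/enrolled_to (dates)")
  }
  df
}

#' Write a record table as CSV
#'
#' POSIXct columns are serialised as ISO 8601 with offset; factors as
#' character. The inverse of the `read_*` family.
#'
#' @param records A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  df <- as_tibble(records)
  df <- df[!vapply(df, is.list, logical(1))]
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_timestamp(df[[col]])
    if (is.factor(df[[col]])) df[[col]] <- as.character(df[[col]])
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
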