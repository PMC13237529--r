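# Classed conditions so callers (and the CLI) can distinguish data errors
# from usage errors. Every data-validation failure inherits from
# "oncotriage_error".

abort_data <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "oncotriage_error"), ...)
}

stop_missing_symptom <- function(symptom, checkin_id = NULL) {
  where <- if (is.null(checkin_id)) "" else paste0(" in check-in ", checkin_id)
  abort_data(
    paste0("Symptom score missing for '", symptom, "'", where, "."),
    "oncotriage_error_missing_symptom"
  )
}

stop_score_out_of_range <- function(symptom, value, checkin_id = NULL) {
  where <- if (is.null(checkin_id)) "" else paste0(" (check-in ", checkin_id, ")")
  abort_data(
    paste0("Score for '", symptom, "' is ", value, where,
           "; severities must be integers in 0-3."),
    "oncotriage_error_score_out_of_range"
  )
}

stop_bad_timestamp <- function(what) {
  abort_data(
    paste0("Bad timestamp: ", what,
           ". Timestamps must be ISO 8601 with an explicit UTC offset."),
    "oncotriage_error_bad_timestamp"
  )
}

stop_duplicate_checkin <- function(ids) {
  abort_data(
    paste0("Duplicate checkin_id: ", paste(unique(ids), collapse = ", ")),
    "oncotriage_error_duplicate_checkin_id"
  )
}

stop_schema_mismatch <- function(path, missing) {
  abort_data(
    paste0("File '", path, "' is missing required column(s): ",
           paste(missing, collapse = ", ")),
    "oncotriage_error_schema_mismatch"
  )
}

stop_empty_input <- function(what) {
  abort_data(paste0("Empty input: ", what), "oncotriage_error_empty_input")
}

stop_invalid_config <- function(what) {
  abort_data(paste0("Invalid configuration: ", what),
             "oncotriage_error_invalid_config")
}
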