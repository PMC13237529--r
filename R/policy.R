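#' The eleven monitored symptoms
#'
#' Closed enumeration of the daily check-in items. Every check-in must score
#' all eleven on the 0-3 ordinal severity scale; unknown symptom names are
#' rejected at parse time.
#'
#' @return Character vector of the 11 symptom names.
#' @export
#' @examples
#' symptom_names()
symptom_names <- function() {
  c("temperature", "dyspnea", "nausea_vomiting", "diarrhea", "constipation",
    "pain", "bleeding_bruising", "fatigue", "skin_rash",
    "peripheral_neuropathy", "oral_mucositis")
}

#' The nine symptom domains
#'
#' Closed enumeration of the clinical domains used for episode continuity:
#' two alerts belong to the same episode only if, among other conditions,
#' their contributing symptoms share at least one domain.
#'
#' @return Character vector of the 9 domain names.
#' @export
symptom_domain_names <- function() {
  c("gastrointestinal", "respiratory", "fever_temperature", "pain",
    "mucositis", "neuropathy", "fatigue_wellbeing", "bleeding_bruising",
    "skin")
}

#' Default symptom-to-domain mapping
#'
#' @return Named character vector: names are symptoms, values are domains.
#' @export
default_domain_map <- function() {
  c(temperature           = "fever_temperature",
    dyspnea               = "respiratory",
    nausea_vomiting       = "gastrointestinal",
    diarrhea              = "gastrointestinal",
    constipation          = "gastrointestinal",
    pain                  = "pain",
    bleeding_bruising     = "bleeding_bruising",
    fatigue               = "fatigue_wellbeing",
    skin_rash             = "skin",
    peripheral_neuropathy = "neuropathy",
    oral_mucositis        = "mucositis")
}

#' Monitoring schedule (staffed dashboard hours)
#'
#' Defines when the clinician dashboard is actively monitored. Alerts raised
#' inside the window are "in hours"; the window is half-open, so an alert at
#' exactly the end time is out of hours.
#'
#' @param staffed_weekdays Integer weekday indices, 1 = Monday ... 7 = Sunday.
#' @param start,end Clock times "HH:MM"; the staffed window is `[start, end)`.
#' @param timezone IANA timezone of the service.
#' @return An object of class `monitoring_schedule`.
#' @export
#' @examples
#' monitoring_schedule() # weekdays 09:00-17:00, Europe/London
monitoring_schedule <- function(staffed_weekdays = 1:5,
                                start = "09:00", end = "17:00",
                                timezone = "Europe/London") {
  parse_clock <- function(x) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop_invalid_config(paste0("bad clock time '", x, "'"))
    as.integer(parts[1]) * 60L + as.integer(parts[2])
  }
  if (!all(staffed_weekdays %in% 1:7)) {
    stop_invalid_config("staffed_weekdays must be in 1 (Mon) .. 7 (Sun)")
  }
  if (!timezone %in% OlsonNames()) {
    stop_invalid_config(paste0("unknown timezone '", timezone, "'"))
  }
  start_min <- parse_clock(start)
  end_min <- parse_clock(end)
  if (start_min >= end_min) stop_invalid_config("staffed window start must precede end")
  structure(
    list(staffed_weekdays = as.integer(staffed_weekdays),
         start = start, end = end,
         start_min = start_min, end_min = end_min,
         timezone = timezone),
    class = "monitoring_schedule"
  )
}

default_tier_map <- function() {
  m <- matrix("GREEN", nrow = length(symptom_names()), ncol = 4,
              dimnames = list(symptom_names(), as.character(0:3)))
  m[, "2"] <- "AMBER"
  m[, "3"] <- "RED"
  m
}

#' Triage policy
#'
#' Bundles everything the triage and episode rules are parameterised by:
#' the per-symptom score-to-tier map, the multi-amber escalation rule, the
#' symptom-to-domain map, the staffed monitoring schedule, and the episode
#' window.
#'
#' The default score-to-tier map is 0,1 -> GREEN, 2 -> AMBER, 3 -> RED for
#' every symptom, and by default two or more individually-amber symptoms on
#' one check-in upgrade the alert to RED (the multi-amber rule used by
#' oncology triage toolkits). Both are configurable per symptom / switchable
#' off.
#'
#' @param symptom_tier_map Character matrix, rows = the 11 symptoms, columns
#'   `"0"`..`"3"`, entries in `GREEN/AMBER/RED`; per symptom the tier must be
#'   non-decreasing in score.
#' @param multi_amber_upgrade Logical; upgrade to RED when at least
#'   `multi_amber_threshold` symptoms individually map to AMBER.
#' @param multi_amber_threshold Integer >= 2.
#' @param domain_map Named character vector mapping each symptom to one of the
#'   nine domains.
#' @param schedule A [monitoring_schedule()].
#' @param episode_window_hours Rolling window (hours) linking successive
#'   amber/red alerts into one episode; default 48.
#' @return An object of class `triage_policy`.
#' @export
#' @examples
#' pol <- triage_policy()
#' pol$episode_window_hours
triage_policy <- function(symptom_tier_map = default_tier_map(),
                          multi_amber_upgrade = TRUE,
                          multi_amber_threshold = 2L,
                          domain_map = default_domain_map(),
                          schedule = monitoring_schedule(),
                          episode_window_hours = 48) {
  syms <- symptom_names()
  if (!is.matrix(symptom_tier_map) ||
      !setequal(rownames(symptom_tier_map), syms) ||
      !identical(sort(colnames(symptom_tier_map)), as.character(0:3))) {
    stop_invalid_config("symptom_tier_map must cover all 11 symptoms x scores 0-3")
  }
  symptom_tier_map <- symptom_tier_map[syms, as.character(0:3), drop = FALSE]
  if (!all(symptom_tier_map %in% TIER_LEVELS)) {
    stop_invalid_config("symptom_tier_map entries must be GREEN/AMBER/RED")
  }
  ranks <- matrix(match(symptom_tier_map, TIER_LEVELS), nrow = nrow(symptom_tier_map))
  if (any(apply(ranks, 1, function(r) any(diff(r) < 0)))) {
    stop_invalid_config("per symptom, tier must be non-decreasing in score")
  }
  if (!setequal(names(domain_map), syms)) {
    stop_invalid_config("domain_map must be total over the 11 symptoms")
  }
  if (!setequal(unique(unname(domain_map)), symptom_domain_names())) {
    stop_invalid_config("domain_map codomain must equal the 9 symptom domains")
  }
  if (!inherits(schedule, "monitoring_schedule")) {
    stop_invalid_config("schedule must be a monitoring_schedule()")
  }
  if (!is.numeric(episode_window_hours) || episode_window_hours <= 0) {
    stop_invalid_config("episode_window_hours must be positive")
  }
  multi_amber_threshold <- as.integer(multi_amber_threshold)
  if (isTRUE(multi_amber_upgrade) && multi_amber_threshold < 2L) {
    stop_invalid_config("multi_amber_threshold must be >= 2")
  }
  structure(
    list(symptom_tier_map = symptom_tier_map,
         multi_amber_upgrade = isTRUE(multi_amber_upgrade),
         multi_amber_threshold = multi_amber_threshold,
         domain_map = domain_map[syms],
         schedule = schedule,
         episode_window_hours = as.numeric(episode_window_hours)),
    class = "triage_policy"
  )
}

#' @export
print.triage_policy <- function(x, ...) {
  cat("<triage_policy>\n")
  cat("  tiers: GREEN < AMBER < RED; multi-amber upgrade:",
      if (x$multi_amber_upgrade) paste0("ON (>= ", x$multi_amber_threshold, " ambers -> RED)") else "off",
      "\n")
  cat("  episode window:", x$episode_window_hours, "hours\n")
  cat("  staffed:", paste(c("Mon","Tue","Wed","Thu","Fri","Sat","Sun")[x$schedule$staffed_weekdays],
                          collapse = " "),
      paste0("[", x$schedule$start, ", ", x$schedule$end, ") "),
      x$schedule$timezone, "\n")
  invisible(x)
}

#' Read / write a triage policy configuration
#'
#' Policies serialise to YAML or JSON (by file extension). Only the fields
#' present in the file override the defaults, so a config may specify e.g.
#' just `episode_window_hours`.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_policy()` returns a [triage_policy()]; `write_policy()`
#'   returns `path` invisibly.
#' @export
read_policy <- function(path) {
  if (!file.exists(path)) {
    abort_data(paste0("Policy file not found: ", path), "oncotriage_error_io")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tier_map <- default_tier_map()
  if (!is.null(raw$symptom_tier_map)) {
    for (sym in names(raw$symptom_tier_map)) {
      entry <- raw$symptom_tier_map[[sym]]
      if (!sym %in% symptom_names()) {
        stop_invalid_config(paste0("unknown symptom '", sym, "' in symptom_tier_map"))
      }
      tier_map[sym, ] <- toupper(unlist(entry))
    }
  }
  domain_map <- default_domain_map()
  if (!is.null(raw$domain_map)) {
    overrides <- unlist(raw$domain_map)
    domain_map[names(overrides)] <- overrides
  }
  sched_raw <- raw$schedule
  schedule <- monitoring_schedule(
    staffed_weekdays = sched_raw$staffed_weekdays %||% 1:5,
    start = sched_raw$start %||% "09:00",
    end = sched_raw$end %||% "17:00",
    timezone = sched_raw$timezone %||% "Europe/London"
  )
  triage_policy(
    symptom_tier_map = tier_map,
    multi_amber_upgrade = raw$multi_amber_upgrade %||% TRUE,
    multi_amber_threshold = raw$multi_amber_threshold %||% 2L,
    domain_map = domain_map,
    schedule = schedule,
    episode_window_hours = raw$episode_window_hours %||% 48
  )
}

#' @rdname read_policy
#' @param policy A [triage_policy()].
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "triage_policy"))
  tm <- policy$symptom_tier_map
  out <- list(
    symptom_tier_map = setNames(
      lapply(rownames(tm), function(s) unname(as.list(tm[s, ]))), rownames(tm)),
    multi_amber_upgrade = policy$multi_amber_upgrade,
    multi_amber_threshold = policy$multi_amber_threshold,
    domain_map = as.list(policy$domain_map),
    schedule = list(staffed_weekdays = policy$schedule$staffed_weekdays,
                    start = policy$schedule$start,
                    end = policy$schedule$end,
                    timezone = policy$schedule$timezone),
    episode_window_hours = policy$episode_window_hours
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
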