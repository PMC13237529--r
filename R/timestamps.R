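# Timestamp handling. All external timestamps must be ISO 8601 with an
# explicit UTC offset ("2025-07-14T09:30:00+01:00" or "...Z"); internally
# everything is POSIXct in the service timezone.

HAS_OFFSET_RE <- "(Z|[+-][0-9]{2}:?[0-9]{2})$"

#' Parse ISO 8601 timestamps that carry an explicit offset
#'
#' Strings without a trailing `Z` or `+hh:mm` offset are rejected: a clinical
#' timestamp whose timezone must be guessed is treated as corrupt.
#'
#' @param x Character vector of ISO 8601 timestamps.
#' @param tz Service timezone the result is expressed in.
#' @return POSIXct vector in `tz`.
#' @export
#' @examples
#' parse_timestamp("2025-07-14T09:30:00+01:00")
parse_timestamp <- function(x, tz = "Europe/London") {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, tz))
  x <- as.character(x)
  bad <- is.na(x) | !grepl(HAS_OFFSET_RE, trimws(x))
  if (any(bad)) {
    stop_bad_timestamp(paste0("'", x[which(bad)[1]], "' (row ", which(bad)[1],
                              ") lacks a UTC offset or is missing"))
  }
  out <- lubridate::ymd_hms(x, quiet = TRUE)
  if (anyNA(out)) {
    stop_bad_timestamp(paste0("could not parse '", x[which(is.na(out))[1]], "'"))
  }
  lubridate::with_tz(out, tz)
}

#' Format timestamps as ISO 8601 with offset
#'
#' @param x POSIXct vector.
#' @return Character vector like `"2025-07-14T09:30:00+0100"`.
#' @export
format_timestamp <- function(x) {
  stopifnot(inherits(x, "POSIXct"))
  format(x, "%Y-%m-%dT%H:%M:%S%z")
}

#' Round half-up to a fixed number of decimals
#'
#' Service reports render percentages and medians to one decimal place with
#' conventional half-up rounding (so 34.375 -> 34.4), rather than R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
#' @examples
#' round_half_up(34.375, 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

local_date <- function(ts, tz) {
  as.Date(ts, tz = tz)
}
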