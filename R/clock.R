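#' Clock-time helpers on the eating-day scale
#'
#' Eating behaviour is scored over an "eating day" that runs wake-to-wake,
#' approximated as 04:00--04:00 local time, so that post-midnight intake
#' belongs to the preceding day's eating window. Clock times are represented
#' as minutes since midnight of the eating day, which means values of 1440
#' or more are legal and denote post-midnight times (e.g. 01:30 the next
#' calendar morning is 1530 minutes, printed as "25:30").
#'
#' @param x For `parse_clock()`, a character vector of "HH:MM" times (hours
#'   may exceed 23 for post-midnight times); for `format_clock()`, a numeric
#'   vector of minutes since midnight of the eating day.
#' @return `parse_clock()` returns minutes as a numeric vector;
#'   `format_clock()` returns "HH:MM" strings.
#' @examples
#' parse_clock(c("08:00", "25:30"))
#' format_clock(c(480, 1530))
#' @export
parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-5][0-9])$", x))
  bad <- lengths(m) != 3L & !is.na(x)
  if (any(bad)) {
    stop("unparseable clock time(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  vapply(m, function(p) {
    if (length(p) != 3L) return(NA_real_)
    as.numeric(p[2L]) * 60 + as.numeric(p[3L])
  }, numeric(1))
}

#' @rdname parse_clock
#' @export
format_clock <- function(x) {
  m <- round(x)  # whole minutes
  ifelse(is.na(m), NA_character_, sprintf("%02d:%02d", m %/% 60, m %% 60))
}

# Start of the eating day, minutes after midnight (04:00).
EATING_DAY_START <- 240

#' Assign timestamps to eating days
#'
#' Maps a POSIXct timestamp to the date of the eating day it belongs to
#' (04:00--04:00 convention) and to minutes since midnight of that eating
#' day, so a reading at 01:30 on March 2nd belongs to the March 1st eating
#' day at 1530 minutes.
#'
#' @param ts POSIXct vector.
#' @return `eating_day_of()`: a Date vector; `eating_day_minutes()`: numeric
#'   minutes since midnight of the assigned eating day (range [240, 1680)).
#' @export
eating_day_of <- function(ts) {
  as.Date(ts - EATING_DAY_START * 60, tz = "UTC")
}

#' @rdname eating_day_of
#' @export
eating_day_minutes <- function(ts) {
  day <- eating_day_of(ts)
  midnight <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
  as.numeric(difftime(ts, midnight, units = "mins"))
}

# round-half-up at `digits` decimals; base round() is half-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
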