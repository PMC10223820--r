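DIARY_CATEGORIES <- c("breakfast", "lunch", "dinner", "snack", "drink")

#' Read a time-stamped diet diary
#'
#' Parses app-style diary exports with one eating/drinking event per row.
#' Events logged between midnight and 04:00 are assigned to the previous
#' day's eating window under the 04:00--04:00 eating-day convention, with
#' their clock time carried past 24:00 (01:30 becomes 1530 minutes, i.e.
#' "25:30").
#'
#' @param path Delimited text file with header
#'   `participant,date,time,category,item,caloric`; `date` ISO-8601,
#'   `time` 24 h "HH:MM", `category` one of breakfast/lunch/dinner/snack/
#'   drink, `caloric` logical.
#' @return A tibble of events sorted by participant then time, with
#'   `eating_day` (Date) and `time_min` (minutes since midnight of the
#'   eating day) alongside the raw columns.
#' @export
read_diary <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant = readr::col_character(),
                           date = readr::col_date(),
                           time = readr::col_character(),
                           category = readr::col_character(),
                           item = readr::col_character(),
                           caloric = readr::col_logical()
                         ))
  if (nrow(raw) == 0) stop("diary file is empty: ", path, call. = FALSE)
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad_cat <- !raw$category %in% DIARY_CATEGORIES
  if (any(bad_cat)) {
    stop("unknown diary category at line(s) ",
         paste(line_no[bad_cat], collapse = ", "), ": ",
         paste(unique(raw$category[bad_cat]), collapse = ", "), call. = FALSE)
  }
  time_min <- parse_clock(raw$time)
  bad_time <- is.na(time_min) | is.na(raw$date)
  if (any(bad_time)) {
    stop("malformed date/time at line(s) ",
         paste(line_no[bad_time], collapse = ", "), call. = FALSE)
  }
  as_diary_events(raw)
}

#' Convert raw diary rows to eating-day events
#'
#' Applies the 04:00 eating-day convention to a data frame already in the
#' diary file dialect (`participant,date,time,category,item,caloric`):
#' rows logged before 04:00 move to the previous eating day with their
#' time carried past 24:00.
#'
#' @param raw Data frame in the diary file dialect (`date` as Date,
#'   `time` as "HH:MM").
#' @return Event tibble sorted by participant then time, with
#'   `eating_day` and `time_min` columns.
#' @export
as_diary_events <- function(raw) {
  time_min <- parse_clock(raw$time)
  post_midnight <- time_min < EATING_DAY_START
  events <- tibble::tibble(
    participant = raw$participant,
    eating_day = as.Date(raw$date) - as.integer(post_midnight),
    time_min = time_min + ifelse(post_midnight, 1440, 0),
    category = raw$category,
    item = raw$item,
    caloric = raw$caloric
  )
  dplyr::arrange(events, .data$participant, .data$eating_day, .data$time_min)
}

#' Keep only events that count as energy intake
#'
#' Permitted fasting drinks (water, black tea and coffee, sugar-free
#' drinks) do not open or close the eating window. Drink events are kept
#' only when flagged caloric; all food categories count as intake
#' regardless of the flag.
#'
#' @param events Diary event tibble as returned by [read_diary()].
#' @return The caloric subset of `events`.
#' @export
caloric_events <- function(events) {
  dplyr::filter(events, .data$category != "drink" | .data$caloric)
}

#' Per-day eating windows from diary events
#'
#' For each participant and eating day with at least one caloric event,
#' the eating window runs from the earliest to the latest caloric intake.
#' Days present in `events` but containing only non-caloric drinks yield
#' no row (no diary evidence of intake is distinct from a zero-length
#' window).
#'
#' @param events Diary event tibble; non-caloric drinks are removed
#'   internally via [caloric_events()].
#' @return A tibble with one row per participant and eating day:
#'   `first_min`, `last_min` (minutes on the eating-day scale),
#'   `duration_hr`, and `n_events`.
#' @examples
#' ev <- tibble::tibble(
#'   participant = "P01", eating_day = as.Date("2022-03-01"),
#'   time_min = c(480, 780, 1230), category = c("breakfast", "lunch", "dinner"),
#'   item = NA_character_, caloric = TRUE
#' )
#' daily_windows(ev)
#' @export
daily_windows <- function(events) {
  kept <- caloric_events(events)
  if (nrow(kept) == 0) {
    return(tibble::tibble(participant = character(),
                          eating_day = as.Date(character()),
                          first_min = numeric(), last_min = numeric(),
                          duration_hr = numeric(), n_events = integer()))
  }
  kept |>
    dplyr::group_by(.data$participant, .data$eating_day) |>
    dplyr::summarise(
      first_min = min(.data$time_min),
      last_min = max(.data$time_min),
      duration_hr = (max(.data$time_min) - min(.data$time_min)) / 60,
      n_events = dplyr::n(),
      .groups = "drop"
    )
}

#' Mean eating times across recorded days
#'
#' Arithmetic means of first-intake time, last-intake time and window
#' duration on the minutes-since-midnight scale. Post-midnight last
#' intakes (values > 1440) enter the mean as-is; the 04:00 eating-day cut
#' keeps each endpoint on one continuous span, so arithmetic (rather than
#' circular) means are valid.
#'
#' @param windows Per-day window tibble from [daily_windows()]; may hold
#'   several participants.
#' @return One row per participant: `mean_first`, `mean_last`,
#'   `mean_duration_hr`, `n_days`.
#' @export
mean_times <- function(windows) {
  if (nrow(windows) == 0) stop("no eating windows to average", call. = FALSE)
  windows |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      mean_first = mean(.data$first_min),
      mean_last = mean(.data$last_min),
      mean_duration_hr = mean(.data$duration_hr),
      n_days = dplyr::n(),
      .groups = "drop"
    )
}
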