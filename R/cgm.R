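#' Read a CGM sensor export
#'
#' Parses flash-monitor-style exports with one interstitial glucose
#' reading per row at a nominal 15-min cadence. Rows are sorted by time,
#' duplicate timestamps are collapsed to their mean reading, and rows with
#' non-positive glucose are dropped with a warning naming their line
#' numbers. Sensor gaps are not stored; they are derived downstream from
#' the timestamp spacing.
#'
#' @param path Delimited text file with header
#'   `participant,timestamp,glucose_mmol_l`; timestamps ISO-8601 with
#'   minutes ("YYYY-MM-DD HH:MM").
#' @return A tibble `participant,timestamp,glucose` sorted by participant
#'   then timestamp (POSIXct, UTC).
#' @export
read_cgm <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant = readr::col_character(),
                           timestamp = readr::col_character(),
                           glucose_mmol_l = readr::col_double()
                         ))
  if (nrow(raw) == 0) stop("CGM file is empty: ", path, call. = FALSE)
  formats <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
               "%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M")
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01", tz = "UTC")
  for (fmt in formats) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(raw$timestamp[miss], tz = "UTC", format = fmt)
  }
  line_no <- seq_len(nrow(raw)) + 1L
  if (anyNA(ts)) {
    stop("unparseable timestamp at line(s) ",
         paste(line_no[is.na(ts)], collapse = ", "), call. = FALSE)
  }
  bad_glu <- is.na(raw$glucose_mmol_l) | raw$glucose_mmol_l <= 0
  if (any(bad_glu)) {
    warning("dropping ", sum(bad_glu), " row(s) with non-positive glucose at line(s) ",
            paste(line_no[bad_glu], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(participant = raw$participant[!bad_glu],
                 timestamp = ts[!bad_glu],
                 glucose = raw$glucose_mmol_l[!bad_glu]) |>
    dplyr::group_by(.data$participant, .data$timestamp) |>
    dplyr::summarise(glucose = mean(.data$glucose), .groups = "drop") |>
    dplyr::arrange(.data$participant, .data$timestamp)
}

#' Detect sustained glucose excursions marking eating occasions
#'
#' An eating occasion is identified when glucose rises at least
#' `glucose_threshold` (default 1 mmol/L) above a local pre-rise reference
#' and stays there for at least `min_elevation_duration` (default 60 min).
#' The reference for a candidate onset is the minimum reading over the 30
#' minutes preceding it (truncated at the trace start; a sample with no
#' earlier reading inside that window cannot anchor an onset). The
#' sustained stretch must be continuous: no reading below the elevated
#' level and no sensor gap longer than 30 min. Overlapping or abutting
#' qualifying stretches are merged into a single excursion.
#'
#' Elevation is relative, so the detector is invariant to adding a
#' constant to the whole trace; the short reference window lets it track
#' slow circadian drift without absorbing the meal rise itself.
#'
#' @param trace Tibble with `timestamp` (POSIXct) and `glucose` (mmol/L)
#'   for a single participant, sorted by time.
#' @param targets A [derive_protocol_targets()] row (only the excursion
#'   constants are used); defaults supply the standard rule.
#' @return A tibble of excursions sorted by onset: `onset`, `end`
#'   (POSIXct), `reference`, `peak` (mmol/L), `sustained_minutes`.
#' @export
detect_excursions <- function(trace, targets = NULL) {
  thr <- if (is.null(targets)) 1 else targets$glucose_threshold
  min_dur <- if (is.null(targets)) 60 else targets$min_elevation_duration
  ref_window <- 30
  max_gap <- 30

  empty <- tibble::tibble(onset = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          reference = numeric(), peak = numeric(),
                          sustained_minutes = numeric())
  n <- nrow(trace)
  if (n < 2) return(empty)
  t_min <- as.numeric(trace$timestamp) / 60
  g <- trace$glucose
  gap_ok <- c(TRUE, diff(t_min) <= max_gap)

  # maximal elevated stretch for each anchored candidate onset
  starts <- integer(0); ends <- integer(0); refs <- numeric(0)
  lo <- 1L
  for (i in seq_len(n)) {
    while (t_min[lo] < t_min[i] - ref_window) lo <- lo + 1L
    if (lo >= i) next  # no earlier reading inside the reference window
    ref <- min(g[lo:(i - 1L)])
    if (g[i] < ref + thr) next
    j <- i
    while (j < n && gap_ok[j + 1L] && g[j + 1L] >= ref + thr) j <- j + 1L
    if (t_min[j] - t_min[i] >= min_dur) {
      starts <- c(starts, i); ends <- c(ends, j); refs <- c(refs, ref)
    }
  }
  if (!length(starts)) return(empty)

  # merge overlapping or abutting stretches
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]; refs <- refs[ord]
  grp <- cumsum(c(TRUE, starts[-1L] > cummax(ends)[-length(ends)] + 1L))
  out <- lapply(split(seq_along(starts), grp), function(idx) {
    s <- min(starts[idx]); e <- max(ends[idx])
    tibble::tibble(onset = trace$timestamp[s], end = trace$timestamp[e],
                   reference = refs[idx][which.min(starts[idx])],
                   peak = max(g[s:e]),
                   sustained_minutes = t_min[e] - t_min[s])
  })
  dplyr::bind_rows(out)
}

#' Summarise detected excursions per eating day
#'
#' For each eating day spanned by the trace, records the onsets of the
#' first and last excursions inside the 04:00--04:00 span, the excursion
#' count, and the fraction of expected sensor readings present. Days with
#' coverage below `min_coverage` are flagged unavailable: adherence
#' cannot be certified from a mostly-missing sensor day.
#'
#' @param trace Single-participant CGM tibble (`timestamp`, `glucose`).
#' @param excursions Output of [detect_excursions()] on that trace.
#' @param days Optional Date vector of eating days to report (defaults to
#'   the days spanned by the trace).
#' @param cadence Nominal sensor cadence in minutes (default 15).
#' @param min_coverage Minimum coverage fraction for a day to count as
#'   having CGM data (default 0.5).
#' @return A tibble per eating day: `eating_day`, `first_onset_min`,
#'   `last_onset_min` (minutes on the eating-day scale, NA when no
#'   excursion), `n_excursions`, `coverage_fraction`, `cgm_available`.
#' @export
daily_glucose_events <- function(trace, excursions, days = NULL,
                                 cadence = 15, min_coverage = 0.5) {
  if (is.null(days)) {
    if (nrow(trace) == 0) {
      stop("no trace samples and no explicit days to report", call. = FALSE)
    }
    days <- sort(unique(eating_day_of(trace$timestamp)))
  }
  expected <- (24 * 60) / cadence
  sample_day <- if (nrow(trace)) eating_day_of(trace$timestamp) else as.Date(character())
  onset_day <- if (nrow(excursions)) eating_day_of(excursions$onset) else as.Date(character())
  onset_min <- if (nrow(excursions)) eating_day_minutes(excursions$onset) else numeric()

  purrr::map_dfr(days, function(d) {
    cov <- sum(sample_day == d) / expected
    on_d <- sort(onset_min[onset_day == d])
    tibble::tibble(
      eating_day = d,
      first_onset_min = if (length(on_d)) on_d[1L] else NA_real_,
      last_onset_min = if (length(on_d)) on_d[length(on_d)] else NA_real_,
      n_excursions = length(on_d),
      coverage_fraction = min(cov, 1),
      cgm_available = cov >= min_coverage
    )
  })
}
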