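#' Score one 24 h period for a TRE-group participant
#'
#' A TRE intervention day is adherent when all applicable criteria hold:
#' (i) the reported eating window is reduced by the required 3 h (within
#' the 30 min allowance) relative to the participant's baseline mean
#' window, and is at most 12 h in total (the two clauses are stored as
#' separate booleans, both required); (ii) the reported first and last
#' intake times fall within +/-30 min of the derived targets; (iii) the
#' first and last CGM excursion onsets fall within +/-30 min of the
#' reported first and last intake times. Criteria lacking their inputs are
#' NA and the day's adherence is then missing rather than false.
#'
#' @param window One row of [daily_windows()] for the day, or `NULL` when
#'   there is no diary record.
#' @param targets The participant's [derive_protocol_targets()] row.
#' @param events One row of [daily_glucose_events()] for the day, or
#'   `NULL` when the sensor recorded nothing.
#' @return A one-row tibble with the four criterion booleans, `adherent`
#'   (logical, NA when not scorable) and the two availability flags.
#' @export
score_tre_day <- function(window, targets, events = NULL) {
  tol <- targets$window_tolerance
  gtol <- targets$glucose_match_tolerance
  baseline_window <- targets$baseline_last - targets$baseline_first

  diary_ok <- !is.null(window) && nrow(window) == 1 && !is.na(window$first_min)
  cgm_ok <- !is.null(events) && nrow(events) == 1 && isTRUE(events$cgm_available)

  c_reduced <- c_le12 <- c_shifted <- c_glucose <- NA
  if (diary_ok) {
    dur_min <- window$last_min - window$first_min
    c_reduced <- (baseline_window - dur_min) >= (targets$required_reduction - tol)
    c_le12 <- dur_min <= targets$max_window
    c_shifted <- abs(window$first_min - targets$target_first) <= tol &&
      abs(window$last_min - targets$target_last) <= tol
    if (cgm_ok) {
      # a covered day with no detected onset contradicts reported intake
      c_glucose <- !is.na(events$first_onset_min) &&
        abs(events$first_onset_min - window$first_min) <= gtol &&
        abs(events$last_onset_min - window$last_min) <= gtol
    }
  }
  adherent <- if (diary_ok && cgm_ok) {
    c_reduced && c_le12 && c_shifted && c_glucose
  } else NA
  tibble::tibble(
    criterion_window_reduced = c_reduced,
    criterion_window_le_12h = c_le12,
    criterion_times_shifted = c_shifted,
    criterion_glucose_match = c_glucose,
    adherent = adherent,
    cgm_available = cgm_ok,
    diary_available = diary_ok
  )
}

#' Score one 24 h period for a control-group participant
#'
#' Controls are asked to keep their habitual (>= 12 h) eating pattern and
#' are coded non-adherent on days whose reported eating window is under
#' 12 h. Days without a diary record are missing, not false.
#'
#' @param window One row of [daily_windows()], or `NULL`.
#' @param max_window The 12 h boundary in minutes (default 720).
#' @return A one-row tibble matching [score_tre_day()]'s columns (the
#'   TRE-only criteria are NA).
#' @export
score_control_day <- function(window, max_window = 720) {
  diary_ok <- !is.null(window) && nrow(window) == 1 && !is.na(window$first_min)
  adherent <- if (diary_ok) {
    (window$last_min - window$first_min) >= max_window
  } else NA
  tibble::tibble(
    criterion_window_reduced = NA, criterion_window_le_12h = NA,
    criterion_times_shifted = NA, criterion_glucose_match = NA,
    adherent = adherent, cgm_available = NA, diary_available = diary_ok
  )
}

#' Percentage of available days scored adherent
#'
#' Implements the study's formula: (days adherent / intervention days) x
#' 100, where the denominator counts only days whose adherence could be
#' determined — when sensor data are missing the number of available days
#' is recalculated rather than counting those days as non-adherent.
#'
#' @param adherent Logical vector of day-level outcomes (NA = missing) or
#'   a records tibble containing an `adherent` column.
#' @return Percent in [0, 100]; NA (with a warning) when no day is
#'   scorable.
#' @examples
#' adherence_percent(c(rep(TRUE, 22), rep(FALSE, 13)))  # 62.857
#' @export
adherence_percent <- function(adherent) {
  if (is.data.frame(adherent)) adherent <- adherent$adherent
  available <- sum(!is.na(adherent))
  if (available == 0) {
    warning("no scorable days: adherence percent undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(adherent, na.rm = TRUE) / available
}

#' Per-participant adherence summary for one study phase
#'
#' @param records Day-level records with `participant`, `group`,
#'   `day_index` and `adherent` columns.
#' @param phase One of "W0" (last baseline week), "W2" (intervention days
#'   1--14) or "W5" (days 15--35).
#' @return A tibble per participant: `adherent_days`, `available_days`,
#'   `percent`, `days_per_week` (7 x adherent / available). Participants
#'   with no scorable day in the phase get NA percent.
#' @export
phase_summary <- function(records, phase) {
  ph <- study_phases()
  ph <- ph[ph$phase == phase, ]
  if (nrow(ph) != 1) stop("unknown phase: ", phase, call. = FALSE)
  records |>
    dplyr::filter(.data$day_index >= ph$start_day,
                  .data$day_index <= ph$end_day) |>
    dplyr::group_by(.data$participant, .data$group) |>
    dplyr::summarise(
      phase = .env$phase,
      adherent_days = sum(.data$adherent, na.rm = TRUE),
      available_days = sum(!is.na(.data$adherent)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent = ifelse(.data$available_days > 0,
                       100 * .data$adherent_days / .data$available_days, NA_real_),
      days_per_week = ifelse(.data$available_days > 0,
                             7 * .data$adherent_days / .data$available_days, NA_real_)
    )
}

#' Combine the two intervention-phase adherence rates
#'
#' The study-level adherence rate is the unweighted arithmetic mean of
#' the W2 and W5 phase rates, which is how the summary table's "Mean"
#' column is formed. A day-weighted variant (weights 14 and 21, the phase
#' lengths) is available for sensitivity analysis.
#'
#' @param w2,w5 Phase adherence percents (vectorised).
#' @param weights `NULL` for the unweighted mean, or a length-2 numeric
#'   weight vector such as `c(14, 21)`.
#' @return The combined percent; NA propagates from either input.
#' @examples
#' combine_phases(60.1, 65.2)  # 62.65, printed 62.7
#' @export
combine_phases <- function(w2, w5, weights = NULL) {
  if (is.null(weights)) return((w2 + w5) / 2)
  stopifnot(length(weights) == 2, all(weights > 0))
  (weights[1] * w2 + weights[2] * w5) / sum(weights)
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Group-by-phase adherence table
#'
#' Aggregates per-participant phase summaries to the reporting layout of
#' the study's adherence table: mean percent and SEM per group and phase,
#' plus the combined W2/W5 mean.
#'
#' @param records Day-level adherence records (see [score_study()]).
#' @param weights Passed to [combine_phases()] for the "Mean" row.
#' @return A tibble `group,phase,n,mean_percent,sem,days_per_week` with
#'   phases W0, W2, W5 and "Mean".
#' @export
group_phase_table <- function(records, weights = NULL) {
  per_part <- dplyr::bind_rows(lapply(c("W0", "W2", "W5"),
                                      function(p) phase_summary(records, p)))
  by_phase <- per_part |>
    dplyr::group_by(.data$group, .data$phase) |>
    dplyr::summarise(
      n = sum(!is.na(.data$percent)),
      mean_percent = mean(.data$percent, na.rm = TRUE),
      sem = sem(.data$percent),
      days_per_week = mean(.data$days_per_week, na.rm = TRUE),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(per_part, id_cols = c("participant", "group"),
                             names_from = "phase", values_from = "percent")
  for (ph in c("W0", "W2", "W5")) {
    if (!ph %in% names(wide)) wide[[ph]] <- NA_real_
  }
  combined <- wide |>
    dplyr::mutate(mean_pct = combine_phases(.data$W2, .data$W5, weights)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      phase = "Mean",
      n = sum(!is.na(.data$mean_pct)),
      mean_percent = mean(.data$mean_pct, na.rm = TRUE),
      sem = sem(.data$mean_pct),
      days_per_week = 7 * mean(.data$mean_pct, na.rm = TRUE) / 100,
      .groups = "drop"
    )
  dplyr::bind_rows(by_phase, combined) |>
    dplyr::arrange(.data$group, match(.data$phase, c("W0", "W2", "W5", "Mean")))
}
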