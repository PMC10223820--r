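#' Derive per-participant TRE protocol targets from baseline eating times
#'
#' The intervention prescribes a symmetric 3 h reduction of the habitual
#' eating window: the first energy intake of the day is delayed and the last
#' advanced by 1.5 h each, relative to the mean first/last eating times
#' recorded at baseline. This function derives those target times and
#' carries every protocol constant used downstream (tolerances, the glucose
#' excursion rule, the intervention length), all overridable for
#' sensitivity analysis.
#'
#' @param baseline_first,baseline_last Mean baseline first/last eating
#'   times, either "HH:MM" strings or minutes since midnight of the eating
#'   day (values > 1440 denote post-midnight last intake).
#' @param shift Minutes by which the first intake is delayed and the last
#'   advanced (default 90, i.e. 1.5 h each side).
#' @param window_tolerance Allowance, in minutes, for adjusting the eating
#'   window and for matching target times (default 30).
#' @param required_reduction Required shrinkage of the eating window in
#'   minutes (default 180 = 2 x shift).
#' @param max_window Maximum compliant eating window in minutes
#'   (default 720, the 12 h ceiling; also the control-group floor).
#' @param glucose_threshold Elevation, in mmol/L, above the local
#'   pre-excursion reference that marks an eating-driven excursion
#'   (default 1).
#' @param min_elevation_duration Minimum sustained elevation in minutes for
#'   an excursion to count as an eating occasion (default 60).
#' @param glucose_match_tolerance Agreement window, in minutes, between a
#'   CGM excursion onset and the self-reported eating time (default 30).
#' @param intervention_days Length of the intervention phase (default 35).
#' @return A one-row tibble of class `"protocol_targets"` with the baseline
#'   times, the derived `target_first`/`target_last`, and all constants.
#' @examples
#' derive_protocol_targets("08:00", "21:00")
#' @export
derive_protocol_targets <- function(baseline_first, baseline_last,
                                    shift = 90,
                                    window_tolerance = 30,
                                    required_reduction = 180,
                                    max_window = 720,
                                    glucose_threshold = 1,
                                    min_elevation_duration = 60,
                                    glucose_match_tolerance = 30,
                                    intervention_days = 35) {
  if (is.character(baseline_first)) baseline_first <- parse_clock(baseline_first)
  if (is.character(baseline_last)) baseline_last <- parse_clock(baseline_last)
  stopifnot(length(baseline_first) == 1, length(baseline_last) == 1)
  durs <- c(shift = shift, window_tolerance = window_tolerance,
            required_reduction = required_reduction, max_window = max_window,
            glucose_threshold = glucose_threshold,
            min_elevation_duration = min_elevation_duration,
            glucose_match_tolerance = glucose_match_tolerance,
            intervention_days = intervention_days)
  if (any(durs <= 0)) {
    stop("protocol constants must be positive: ",
         paste(names(durs)[durs <= 0], collapse = ", "), call. = FALSE)
  }
  baseline_window <- baseline_last - baseline_first
  if (baseline_window < required_reduction) {
    stop("baseline eating window (", round(baseline_window / 60, 2),
         " h) is shorter than the required reduction (",
         required_reduction / 60, " h); targets would invert", call. = FALSE)
  }
  out <- tibble::tibble(
    baseline_first = baseline_first,
    baseline_last = baseline_last,
    target_first = baseline_first + shift,
    target_last = baseline_last - shift,
    shift = shift,
    window_tolerance = window_tolerance,
    required_reduction = required_reduction,
    max_window = max_window,
    glucose_threshold = glucose_threshold,
    min_elevation_duration = min_elevation_duration,
    glucose_match_tolerance = glucose_match_tolerance,
    intervention_days = intervention_days
  )
  class(out) <- c("protocol_targets", class(out))
  out
}

# The five screening predicates, named as reported in eligibility output.
eligibility_rules <- list(
  bmi          = function(p) p$bmi >= 18.5 & p$bmi <= 29.9,
  age          = function(p) p$age >= 18 & p$age <= 50,
  systolic     = function(p) p$sbp < 140,
  diastolic    = function(p) p$dbp < 90,
  eating_window = function(p) p$baseline_window >= 12
)

#' Screen participants for trial eligibility
#'
#' Applies the recruitment criteria: non-obese BMI (18.5--29.9 kg/m^2),
#' age 18--50 y, normotensive blood pressure (< 140/90 mmHg), and a
#' habitual eating window of at least 12 h.
#'
#' @param profiles A data frame with one row per participant and columns
#'   `bmi` (kg/m^2), `age` (years), `sbp`/`dbp` (mmHg) and
#'   `baseline_window` (hours). Other columns are carried through.
#' @return The input as a tibble with `eligible` (logical) and
#'   `failed_rules` (comma-separated rule names, `""` when eligible) added.
#' @examples
#' check_eligibility(data.frame(
#'   id = "P01", bmi = 24.1, age = 28, sbp = 120, dbp = 75,
#'   baseline_window = 13
#' ))
#' @export
check_eligibility <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  needed <- c("bmi", "age", "sbp", "dbp", "baseline_window")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols)) {
    stop("profiles are missing required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in needed) {
    if (anyNA(profiles[[col]])) {
      stop("missing value in required field: ", col, call. = FALSE)
    }
  }
  pass <- purrr::map(eligibility_rules, function(rule) rule(profiles))
  pass_mat <- do.call(cbind, pass)
  profiles$eligible <- apply(pass_mat, 1L, all)
  profiles$failed_rules <- apply(pass_mat, 1L, function(row) {
    paste(names(eligibility_rules)[!row], collapse = ",")
  })
  profiles
}

#' Study phases used for adherence reporting
#'
#' Adherence is summarised over three assessment phases: W0, the last week
#' of the 2-week baseline (day indices -7 to -1 relative to intervention
#' start); W2, the first two intervention weeks (days 1--14); and W5, the
#' final three weeks (days 15--35).
#'
#' @return A tibble with columns `phase`, `start_day`, `end_day`, `n_days`.
#' @export
study_phases <- function() {
  tibble::tibble(
    phase = c("W0", "W2", "W5"),
    start_day = c(-7L, 1L, 15L),
    end_day = c(-1L, 14L, 35L),
    n_days = c(7L, 14L, 21L)
  )
}

#' Read a participant roster file
#'
#' @param path Delimited text file with header
#'   `id,group,sex,age,weight,bmi,sbp,dbp`.
#' @return A tibble with `group` normalised to "TRE"/"CONTROL".
#' @export
read_roster <- function(path) {
  roster <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("id", "group", "sex", "age", "weight", "bmi", "sbp", "dbp")
  missing_cols <- setdiff(needed, names(roster))
  if (length(missing_cols)) {
    stop("roster is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  roster$group <- toupper(roster$group)
  bad <- !roster$group %in% c("TRE", "CONTROL")
  if (any(bad)) {
    stop("unknown group label(s): ", paste(unique(roster$group[bad]), collapse = ", "),
         call. = FALSE)
  }
  roster
}
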