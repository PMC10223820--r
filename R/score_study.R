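day_index_of <- function(eating_day, intervention_start) {
  delta <- as.integer(eating_day - intervention_start)
  ifelse(delta >= 0, delta + 1L, delta)
}

#' Score a whole cohort end to end
#'
#' Runs the full objective-adherence pipeline: per-day eating windows from
#' the diary, baseline mean eating times over the last baseline week,
#' per-participant protocol targets, CGM excursion detection, day-level
#' criterion scoring, and phase/group aggregation.
#'
#' TRE-group days during the intervention are scored against the full
#' criterion set ([score_tre_day()]); TRE baseline days and all control
#' days are scored with the habitual-window rule ([score_control_day()]),
#' since no reduction targets exist for them. For days without a diary
#' record the participant's phase-mean reported window stands in as the
#' "agreed" eating times when `use_mean_window_fallback` is `TRUE`
#' (mirroring scoring against mean reported times); otherwise such days
#' are missing.
#'
#' @param roster Participant roster tibble (`id`, `group`, ...).
#' @param diary Diary events as from [read_diary()].
#' @param cgm CGM readings as from [read_cgm()] (all participants).
#' @param intervention_start Date of intervention day 1.
#' @param targets_args Named list of overrides passed to
#'   [derive_protocol_targets()] (e.g. `list(shift = 120)`).
#' @param use_mean_window_fallback Score diary-less days against the
#'   phase-mean reported window (default TRUE).
#' @param combine_weights Passed to [combine_phases()].
#' @param cadence,min_coverage CGM expectations, see
#'   [daily_glucose_events()].
#' @return An object of class `"tre_adherence"`: a list with `days`
#'   (day-level records), `participants` (per participant x phase),
#'   `groups` (group x phase table), `targets` (per TRE participant) and
#'   `meta`. Use [tidy()][generics::tidy] / [glance()][generics::glance]
#'   to extract tibbles.
#' @export
score_study <- function(roster, diary, cgm, intervention_start,
                        targets_args = list(),
                        use_mean_window_fallback = TRUE,
                        combine_weights = NULL,
                        cadence = 15, min_coverage = 0.5) {
  intervention_start <- as.Date(intervention_start)
  roster <- tibble::as_tibble(roster)
  if (!"time_min" %in% names(diary)) diary <- as_diary_events(diary)
  orphan <- setdiff(unique(diary$participant), roster$id)
  if (length(orphan)) {
    stop("diary participant(s) absent from roster: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(unique(cgm$participant), roster$id)
  if (length(orphan)) {
    stop("CGM participant(s) absent from roster: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }

  windows <- daily_windows(diary) |>
    dplyr::mutate(day_index = day_index_of(.data$eating_day, intervention_start))

  # baseline mean eating times: last 7 baseline days (W0)
  baseline_means <- windows |>
    dplyr::filter(.data$day_index >= -7, .data$day_index <= -1) |>
    mean_times()

  tre_ids <- roster$id[roster$group == "TRE"]
  no_baseline <- setdiff(tre_ids, baseline_means$participant)
  if (length(no_baseline)) {
    stop("no baseline diary data to derive targets for TRE participant(s): ",
         paste(no_baseline, collapse = ", "), call. = FALSE)
  }
  targets_tbl <- baseline_means |>
    dplyr::filter(.data$participant %in% tre_ids) |>
    dplyr::rowwise() |>
    dplyr::mutate(targets = list(do.call(derive_protocol_targets, c(
      list(baseline_first = .data$mean_first, baseline_last = .data$mean_last),
      targets_args
    )))) |>
    dplyr::ungroup()

  default_targets <- do.call(derive_protocol_targets,
                             c(list(baseline_first = 480, baseline_last = 1200),
                               targets_args))
  max_window <- default_targets$max_window

  # phase-mean windows for the fallback
  phase_of_day <- function(day_index) {
    ph <- study_phases()
    lab <- rep(NA_character_, length(day_index))
    for (k in seq_len(nrow(ph))) {
      lab[day_index >= ph$start_day[k] & day_index <= ph$end_day[k]] <- ph$phase[k]
    }
    lab
  }
  phase_means <- windows |>
    dplyr::mutate(phase = phase_of_day(.data$day_index)) |>
    dplyr::filter(!is.na(.data$phase)) |>
    dplyr::group_by(.data$participant, .data$phase) |>
    dplyr::summarise(first_min = mean(.data$first_min),
                     last_min = mean(.data$last_min), .groups = "drop")

  all_days <- tidyr::expand_grid(
    id = roster$id,
    day_index = c(-14:-1, seq_len(default_targets$intervention_days))
  ) |>
    dplyr::mutate(eating_day = intervention_start + ifelse(.data$day_index > 0,
                                                           .data$day_index - 1L,
                                                           .data$day_index))

  records <- purrr::map_dfr(roster$id, function(pid) {
    grp <- roster$group[roster$id == pid]
    targets_pid <- if (pid %in% targets_tbl$participant) {
      targets_tbl$targets[[match(pid, targets_tbl$participant)]]
    } else default_targets
    trace <- cgm[cgm$participant == pid, ]
    exc <- detect_excursions(trace, targets_pid)
    days_pid <- all_days[all_days$id == pid, ]
    events <- daily_glucose_events(trace, exc, days = days_pid$eating_day,
                                   cadence = cadence, min_coverage = min_coverage)
    wins <- windows[windows$participant == pid, ]
    pmeans <- phase_means[phase_means$participant == pid, ]

    recs <- purrr::map_dfr(seq_len(nrow(days_pid)), function(k) {
      d <- days_pid$eating_day[k]
      di <- days_pid$day_index[k]
      w <- wins[wins$eating_day == d, ]
      had_diary <- nrow(w) == 1
      if (!had_diary && use_mean_window_fallback) {
        pm <- pmeans[!is.na(phase_of_day(di)) & pmeans$phase %in% phase_of_day(di), ]
        if (nrow(pm) == 1) w <- pm
      }
      ev <- events[events$eating_day == d, ]
      rec <- if (grp == "TRE" && di >= 1) {
        score_tre_day(if (nrow(w)) w else NULL, targets_pid, ev)
      } else {
        score_control_day(if (nrow(w)) w else NULL, max_window = max_window)
      }
      rec$diary_available <- had_diary
      rec
    })
    dplyr::bind_cols(
      tibble::tibble(participant = pid, group = grp,
                     eating_day = days_pid$eating_day,
                     day_index = days_pid$day_index,
                     phase = phase_of_day(days_pid$day_index)),
      recs
    )
  })

  per_part <- dplyr::bind_rows(lapply(c("W0", "W2", "W5"),
                                      function(p) phase_summary(records, p)))
  out <- list(
    days = records,
    participants = per_part,
    groups = group_phase_table(records, weights = combine_weights),
    targets = targets_tbl,
    meta = list(intervention_start = intervention_start,
                targets_args = targets_args,
                combine_weights = combine_weights,
                protocol = default_targets)
  )
  class(out) <- "tre_adherence"
  out
}

#' @export
print.tre_adherence <- function(x, ...) {
  cat("<tre_adherence> ", length(unique(x$days$participant)), " participants, ",
      nrow(x$days), " participant-days\n\n", sep = "")
  tbl <- x$groups |>
    dplyr::mutate(mean_percent = round_half_up(.data$mean_percent, 1),
                  sem = round_half_up(.data$sem, 1),
                  days_per_week = round_half_up(.data$days_per_week, 1))
  print(as.data.frame(tbl), row.names = FALSE)
  invisible(x)
}

#' Tidy day-level adherence records
#'
#' @param x A [score_study()] result.
#' @param ... Unused.
#' @return The day-level records tibble (one row per participant-day).
#' @method tidy tre_adherence
#' @export
tidy.tre_adherence <- function(x, ...) x$days

#' One-row study-level adherence summary
#'
#' @param x A [score_study()] result.
#' @param ... Unused.
#' @return One row with each group's combined intervention-phase mean
#'   percent and participant count.
#' @method glance tre_adherence
#' @export
glance.tre_adherence <- function(x, ...) {
  m <- x$groups[x$groups$phase == "Mean", ]
  g <- function(grp, col) {
    v <- m[[col]][m$group == grp]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    tre_mean_percent = g("TRE", "mean_percent"),
    tre_sem = g("TRE", "sem"),
    n_tre = g("TRE", "n"),
    control_mean_percent = g("CONTROL", "mean_percent"),
    control_sem = g("CONTROL", "sem"),
    n_control = g("CONTROL", "n")
  )
}
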