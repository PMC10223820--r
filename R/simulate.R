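#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the emulated trial's conditions: 8 TRE and 8 control
#' participants, a 2-week baseline followed by a 35-day intervention,
#' habitual eating windows of 12.2--14 h (the trial recruited windows
#' >= 12 h), a per-day behavioural adherence probability of 0.63 for TRE
#' intervention days (the headline adherence scale) and 0.79 for habitual
#' (baseline/control) days, 15-min CGM cadence, and modest glucose
#' physiology: basal 5 mmol/L, meal responses of 3.0 +/- 0.5 mmol/L
#' (floor 2.2) peaking 45 min after intake, a 0.3 mmol/L circadian ripple (trough
#' ~03:00), a 0.5 mmol/L dawn bump at wake, and 0.2 mmol/L sensor noise.
#'
#' @param n_tre,n_control Group sizes.
#' @param adherence_p Probability a TRE intervention day is behaviourally
#'   adherent.
#' @param baseline_adherence_p,control_adherence_p Probability a habitual
#'   day keeps its >= 12 h window (baseline for both groups; control
#'   intervention days).
#' @param baseline_first_mean,baseline_first_sd,baseline_last_mean,baseline_last_sd
#'   Population distribution of habitual first/last eating times, minutes
#'   since midnight.
#' @param min_habitual_window,max_habitual_window Clamp on the drawn
#'   habitual window, minutes.
#' @param day_jitter Half-width, minutes, of the uniform day-to-day jitter
#'   on reported eating times.
#' @param meal_amplitude_mean,meal_amplitude_sd,meal_amplitude_min Meal
#'   glucose response amplitude, mmol/L.
#' @param meal_tau Time-to-peak of the meal response kernel, minutes.
#' @param meal_duration Truncation of the meal response, minutes.
#' @param basal_glucose,circadian_amplitude,dawn_bump_amplitude,noise_sd
#'   Physiology parameters, mmol/L.
#' @param wake_time,dawn_sd Dawn-bump centre and width, minutes.
#' @param sensor_dropout_p Probability a day's sensor records nothing.
#' @param cadence Sensor cadence, minutes.
#' @param n_baseline_days,intervention_days Study phase lengths.
#' @param violation_mix Named weights for the three violation modes of a
#'   non-adherent TRE day: `early` first intake, `late` last intake,
#'   `unreported` evening intake present in CGM but not the diary.
#' @param start_date Calendar date of intervention day 1.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_tre = 8, n_control = 8,
                              adherence_p = 0.63,
                              baseline_adherence_p = 0.79,
                              control_adherence_p = 0.79,
                              baseline_first_mean = 480, baseline_first_sd = 30,
                              baseline_last_mean = 1275, baseline_last_sd = 30,
                              min_habitual_window = 732,
                              max_habitual_window = 840,
                              day_jitter = 10,
                              meal_amplitude_mean = 3, meal_amplitude_sd = 0.5,
                              meal_amplitude_min = 2.2,
                              meal_tau = 45, meal_duration = 240,
                              basal_glucose = 5, circadian_amplitude = 0.3,
                              dawn_bump_amplitude = 0.5, wake_time = 420,
                              dawn_sd = 30, noise_sd = 0.2,
                              sensor_dropout_p = 0.05, cadence = 15,
                              n_baseline_days = 14, intervention_days = 35,
                              violation_mix = c(early = 1, late = 1,
                                                unreported = 1),
                              start_date = as.Date("2022-03-01")) {
  cfg <- as.list(environment())
  probs <- c(cfg$adherence_p, cfg$baseline_adherence_p, cfg$control_adherence_p,
             cfg$sensor_dropout_p)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$cadence > 0,
            cfg$meal_amplitude_sd >= 0, cfg$noise_sd >= 0,
            all(cfg$violation_mix >= 0), sum(cfg$violation_mix) > 0)
  class(cfg) <- "sim_config"
  cfg
}

meal_kernel <- function(dt, amplitude, tau, duration) {
  y <- ifelse(dt >= 0 & dt <= duration,
              amplitude * (dt / tau) * exp(1 - dt / tau), 0)
  y
}

#' Simulate one day of CGM readings
#'
#' Glucose is basal + a 24 h sinusoid (trough ~03:00) + a Gaussian dawn
#' bump at wake + one gamma-like response per meal (peak = amplitude at
#' `meal_tau` after intake, truncated at `meal_duration`) + Gaussian
#' sensor noise, sampled at the configured cadence over the 04:00--04:00
#' eating day.
#'
#' @param meal_times Minutes (eating-day scale) of each intake.
#' @param config A [simulation_config()].
#' @param eating_day Date the samples belong to.
#' @param amplitudes Optional per-meal amplitudes (mmol/L); drawn from the
#'   configured distribution when omitted.
#' @param seed Optional integer; when given the day is reproducible in
#'   isolation.
#' @return A tibble `timestamp,glucose,time_min`.
#' @export
simulate_glucose_day <- function(meal_times, config,
                                 eating_day = as.Date("2022-03-01"),
                                 amplitudes = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(amplitudes)) {
    amplitudes <- pmax(stats::rnorm(length(meal_times),
                                    config$meal_amplitude_mean,
                                    config$meal_amplitude_sd),
                       config$meal_amplitude_min)
  }
  t_min <- seq(EATING_DAY_START, EATING_DAY_START + 24 * 60 - config$cadence,
               by = config$cadence)
  hours <- t_min / 60
  g <- config$basal_glucose +
    config$circadian_amplitude * sin(2 * pi * (hours - 9) / 24) +
    config$dawn_bump_amplitude *
      exp(-((t_min - config$wake_time)^2) / (2 * config$dawn_sd^2))
  for (k in seq_along(meal_times)) {
    g <- g + meal_kernel(t_min - meal_times[k], amplitudes[k],
                         config$meal_tau, config$meal_duration)
  }
  if (config$noise_sd > 0) g <- g + stats::rnorm(length(g), 0, config$noise_sd)
  midnight <- as.POSIXct(paste(eating_day, "00:00:00"), tz = "UTC")
  tibble::tibble(timestamp = midnight + t_min * 60, glucose = g,
                 time_min = t_min)
}

rtrunc_window <- function(cfg) {
  repeat {
    first <- stats::rnorm(1, cfg$baseline_first_mean, cfg$baseline_first_sd)
    last <- stats::rnorm(1, cfg$baseline_last_mean, cfg$baseline_last_sd)
    w <- last - first
    if (w >= cfg$min_habitual_window && w <= cfg$max_habitual_window) {
      return(c(first = first, last = last))
    }
  }
}

# reported eating times for one day; habitual-pattern day keeps >= 12 h
# with probability p, otherwise the window contracts below 12 h
habitual_day_times <- function(first, last, adherent, jitter) {
  if (adherent) {
    f <- first + stats::runif(1, -jitter, jitter)
    l <- last + stats::runif(1, -jitter, jitter)
    if (l - f < 720) l <- f + 720 + stats::runif(1, 0, 15)
  } else {
    w <- 720 - stats::runif(1, 10, 110)  # 10.2-11.8 h window
    f <- first + ((last - first) - w) / 2 + stats::runif(1, -jitter, jitter)
    l <- f + w
  }
  c(f, l)
}

#' Simulate one participant's diary, CGM trace and ground truth
#'
#' Baseline days follow the participant's habitual (>= 12 h) eating
#' pattern. Each TRE intervention day is behaviourally adherent with
#' probability `adherence_p` — meals placed inside the target window with
#' first/last intake within the allowance of the targets — otherwise one
#' violation mode is drawn: first intake too early, last intake too late,
#' or an unreported late-evening intake that appears in the CGM trace but
#' not in the diary. Control intervention days keep the habitual pattern
#' with probability `control_adherence_p`. Sensor-dropout days emit no
#' CGM rows.
#'
#' The reduction targets a TRE participant follows are derived from their
#' realized baseline diary exactly as the scoring pipeline derives them
#' (mean of the last baseline week's first/last intakes, shifted 1.5 h
#' inward), mirroring a trial in which participants are prescribed targets
#' computed from their recorded baseline.
#'
#' @param config A [simulation_config()].
#' @param group "TRE" or "CONTROL".
#' @param id Participant label.
#' @param seed Integer seed for this participant's stream.
#' @return A list with `diary`, `cgm`, `truth` tibbles and a one-row
#'   `profile`.
#' @export
simulate_participant <- function(config, group, id, seed) {
  set.seed(seed)
  grp <- match.arg(group, c("TRE", "CONTROL"))
  hab <- rtrunc_window(config)
  day_idx <- c(seq(-config$n_baseline_days, -1L),
               seq_len(config$intervention_days))

  # behavioural day plan: baseline first, so targets can be derived from
  # the realized last-week means before intervention days are placed
  plan <- list()
  for (di in seq(-config$n_baseline_days, -1L)) {
    adherent <- stats::runif(1) < config$baseline_adherence_p
    fl <- habitual_day_times(hab["first"], hab["last"], adherent,
                             config$day_jitter)
    plan[[as.character(di)]] <- list(f = fl[1], l = fl[2], adherent = adherent,
                                     violation = NA_character_,
                                     unreported = NA_real_)
  }
  w0 <- vapply(as.character(seq(-7L, -1L)),
               function(k) c(plan[[k]]$f, plan[[k]]$l), numeric(2))
  targets <- c(first = mean(w0[1, ]) + 90, last = mean(w0[2, ]) - 90)

  for (di in seq_len(config$intervention_days)) {
    violation <- NA_character_
    unreported_time <- NA_real_
    if (grp == "TRE") {
      adherent <- stats::runif(1) < config$adherence_p
      f <- targets["first"] + stats::runif(1, -config$day_jitter, config$day_jitter)
      l <- targets["last"] + stats::runif(1, -config$day_jitter, config$day_jitter)
      if (!adherent) {
        violation <- sample(names(config$violation_mix), 1,
                            prob = config$violation_mix)
        if (violation == "early") {
          f <- targets["first"] - 30 - stats::runif(1, 15, 90)
        } else if (violation == "late") {
          l <- targets["last"] + 30 + stats::runif(1, 15, 90)
        } else {  # unreported late-evening intake; diary looks adherent
          unreported_time <- l + stats::runif(1, 210, 300)
        }
      }
    } else {
      adherent <- stats::runif(1) < config$control_adherence_p
      fl <- habitual_day_times(hab["first"], hab["last"], adherent,
                               config$day_jitter)
      f <- fl[1]; l <- fl[2]
    }
    plan[[as.character(di)]] <- list(f = unname(f), l = unname(l),
                                     adherent = adherent,
                                     violation = violation,
                                     unreported = unname(unreported_time))
  }

  diary <- list(); cgm <- list(); truth <- list()
  for (di in day_idx) {
    eating_day <- config$start_date + ifelse(di > 0, di - 1L, di)
    day <- plan[[as.character(di)]]
    f <- day$f; l <- day$l
    adherent <- day$adherent
    violation <- day$violation
    unreported_time <- if (is.na(day$unreported)) NULL else day$unreported

    mid <- f + (l - f) * stats::runif(1, 0.45, 0.6)
    meal_times <- c(f, mid, l)
    reported <- tibble::tibble(
      participant = id,
      date = eating_day + (meal_times >= 1440),
      time = format_clock(meal_times %% 1440),
      category = c("breakfast", "lunch", "dinner"),
      item = c("first meal", "midday meal", "evening meal"),
      caloric = TRUE
    )
    # a permitted fasting drink before the window, most days
    if (stats::runif(1) < 0.8) {
      reported <- dplyr::bind_rows(tibble::tibble(
        participant = id, date = eating_day,
        time = format_clock((f - stats::runif(1, 60, 150)) %% 1440),
        category = "drink", item = "black coffee", caloric = FALSE
      ), reported)
    }
    diary[[length(diary) + 1L]] <- reported

    dropout <- stats::runif(1) < config$sensor_dropout_p
    if (!dropout) {
      cgm_meals <- c(meal_times, unreported_time)
      day_trace <- simulate_glucose_day(cgm_meals, config, eating_day)
      cgm[[length(cgm) + 1L]] <- tibble::tibble(
        participant = id, timestamp = day_trace$timestamp,
        glucose = day_trace$glucose
      )
    }
    truth[[length(truth) + 1L]] <- tibble::tibble(
      participant = id, day = di, eating_day = eating_day,
      true_adherent = adherent,
      violation_type = violation,
      unreported_intake = !is.null(unreported_time),
      sensor_dropout = dropout,
      true_first = unname(f), true_last = unname(l)
    )
  }

  profile <- tibble::tibble(
    id = id, group = grp,
    sex = "F",
    age = round(min(max(stats::rnorm(1, 28, 8), 18), 50)),
    weight = round(stats::rnorm(1, 66.5, 10), 1),
    bmi = round(min(max(stats::rnorm(1, 23.5, 2), 18.6), 29.5), 1),
    sbp = round(min(stats::rnorm(1, 115, 8), 138)),
    dbp = round(min(stats::rnorm(1, 72, 6), 88))
  )
  list(diary = dplyr::bind_rows(diary), cgm = dplyr::bind_rows(cgm),
       truth = dplyr::bind_rows(truth), profile = profile)
}

questionnaire_probs <- list(
  TRE = list(
    ease = c(0.10, 0.20, 0.30, 0.30, 0.10),
    morning_days = c(0.00, 0.10, 0.25, 0.45, 0.20),
    evening_days = c(0.05, 0.15, 0.35, 0.35, 0.10),
    window_days = c(0.02, 0.15, 0.32, 0.36, 0.15),
    plan_days = c(0.12, 0.30, 0.33, 0.20, 0.05),
    realistic_days = c(0.02, 0.03, 0.05, 0.10, 0.20, 0.25, 0.20, 0.15),
    restrict_hours = c(0.05, 0.15, 0.25, 0.30, 0.15, 0.10)
  ),
  CONTROL = list(
    ease = c(0.05, 0.20, 0.30, 0.30, 0.15),
    morning_days = c(0.12, 0.25, 0.30, 0.23, 0.10),
    evening_days = c(0.18, 0.30, 0.30, 0.17, 0.05),
    window_days = c(0.12, 0.30, 0.33, 0.20, 0.05),
    plan_days = c(0.10, 0.25, 0.32, 0.23, 0.10),
    realistic_days = c(0.05, 0.05, 0.10, 0.25, 0.30, 0.15, 0.07, 0.03),
    restrict_hours = c(0.08, 0.20, 0.27, 0.30, 0.10, 0.05)
  )
)

simulate_questionnaire <- function(ids, groups, seed) {
  set.seed(seed)
  purrr::map2_dfr(ids, groups, function(pid, grp) {
    probs <- questionnaire_probs[[grp]]
    purrr::map_dfr(names(probs), function(it) {
      opts <- names(likert_map_for(it))
      tibble::tibble(participant = pid, group = grp, item = it,
                     category = sample(opts, 1, prob = probs[[it]]))
    })
  })
}

#' Simulate a full study cohort
#'
#' Generates roster, diaries, CGM traces, questionnaire responses and the
#' ground-truth table for a cohort, fully determined by the seed (each
#' participant gets an independent substream). Sexes emulate the trial's
#' composition: all-female TRE arm, one male among the controls.
#'
#' @param config A [simulation_config()].
#' @param seed Master integer seed.
#' @param dir Optional directory; when given, the five delimited-text
#'   files (`roster.csv`, `diary.csv`, `cgm.csv`, `questionnaire.csv`,
#'   `ground_truth.csv`) are written there.
#' @return A list (class `"tre_cohort"`) with tibbles `roster`, `diary`,
#'   `cgm`, `questionnaire`, `truth`, and the `config`.
#' @export
simulate_study <- function(config = simulation_config(), seed = 1,
                           dir = NULL) {
  set.seed(seed)
  n <- config$n_tre + config$n_control
  ids <- sprintf("P%02d", seq_len(max(n, 1)))[seq_len(n)]
  groups <- c(rep("TRE", config$n_tre), rep("CONTROL", config$n_control))
  part_seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n + 1L) else integer()

  parts <- purrr::pmap(list(ids, groups, part_seeds[seq_len(n)]),
                       function(pid, grp, s) {
                         simulate_participant(config, grp, pid, s)
                       })
  roster <- dplyr::bind_rows(purrr::map(parts, "profile"))
  if (config$n_control > 0) {
    roster$sex[roster$group == "CONTROL"][1L] <- "M"
  }
  out <- list(
    roster = roster,
    diary = dplyr::bind_rows(purrr::map(parts, "diary")),
    cgm = dplyr::bind_rows(purrr::map(parts, "cgm")),
    questionnaire = if (n > 0) {
      simulate_questionnaire(ids, groups, part_seeds[n + 1L])
    } else {
      tibble::tibble(participant = character(), group = character(),
                     item = character(), category = character())
    },
    truth = dplyr::bind_rows(purrr::map(parts, "truth")),
    config = config
  )
  class(out) <- "tre_cohort"
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a simulated cohort to delimited-text files
#'
#' @param cohort A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$roster, file.path(dir, "roster.csv"))
  readr::write_csv(cohort$diary, file.path(dir, "diary.csv"))
  cgm_out <- cohort$cgm
  if (nrow(cgm_out)) {
    cgm_out <- tibble::tibble(
      participant = cgm_out$participant,
      timestamp = format(cgm_out$timestamp, "%Y-%m-%d %H:%M", tz = "UTC"),
      glucose_mmol_l = round(cgm_out$glucose, 3)
    )
  } else {
    cgm_out <- tibble::tibble(participant = character(),
                              timestamp = character(),
                              glucose_mmol_l = numeric())
  }
  readr::write_csv(cgm_out, file.path(dir, "cgm.csv"))
  readr::write_csv(cohort$questionnaire, file.path(dir, "questionnaire.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
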