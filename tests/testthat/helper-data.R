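# in-code fixture writers (all fixtures are generated at test time)

write_diary_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                               .local_envir = parent.frame())) {
  header <- "participant,date,time,category,item,caloric"
  writeLines(c(header, rows), path)
  path
}

write_cgm_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                             .local_envir = parent.frame())) {
  header <- "participant,timestamp,glucose_mmol_l"
  writeLines(c(header, rows), path)
  path
}

# one-row eating-window tibble on the eating-day minute scale
window_row <- function(first_min, last_min, day = as.Date("2022-03-01")) {
  tibble::tibble(participant = "P01", eating_day = day,
                 first_min = first_min, last_min = last_min,
                 duration_hr = (last_min - first_min) / 60, n_events = 3L)
}

events_row <- function(first_onset, last_onset, n = 2L, coverage = 1,
                       available = TRUE, day = as.Date("2022-03-01")) {
  tibble::tibble(eating_day = day, first_onset_min = first_onset,
                 last_onset_min = last_onset, n_excursions = n,
                 coverage_fraction = coverage, cgm_available = available)
}
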