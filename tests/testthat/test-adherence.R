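tg13 <- derive_protocol_targets("08:00", "21:00")  # 13 h baseline window

test_that("a TRE day meeting every criterion is adherent", {
  # exactly at targets (09:30-19:30), onsets 10 min after reported times
  w <- window_row(570, 1170)
  ev <- events_row(580, 1180)
  rec <- score_tre_day(w, tg13, ev)
  expect_true(rec$criterion_window_reduced)
  expect_true(rec$criterion_window_le_12h)
  expect_true(rec$criterion_times_shifted)
  expect_true(rec$criterion_glucose_match)
  expect_true(rec$adherent)
})

test_that("a glucose onset far from reported intake fails the CGM criterion", {
  w <- window_row(570, 1170)
  ev <- events_row(570 - 120, 1180)  # excursion 2 h before reported first
  rec <- score_tre_day(w, tg13, ev)
  expect_false(rec$criterion_glucose_match)
  expect_false(rec$adherent)
})

test_that("missing CGM or diary makes adherence missing, not false", {
  w <- window_row(570, 1170)
  no_cgm <- events_row(NA_real_, NA_real_, n = 0L, coverage = 0.2,
                       available = FALSE)
  rec <- score_tre_day(w, tg13, no_cgm)
  expect_true(is.na(rec$adherent))
  expect_false(rec$cgm_available)
  rec <- score_tre_day(NULL, tg13, events_row(580, 1180))
  expect_true(is.na(rec$adherent))
  expect_false(rec$diary_available)
  # a covered day with no excursion at all contradicts reported intake
  quiet <- events_row(NA_real_, NA_real_, n = 0L)
  expect_false(score_tre_day(w, tg13, quiet)$adherent)
})

test_that("the window-reduction and 12 h clauses are scored separately", {
  # 15.5 h baseline: a perfect 3 h reduction still exceeds 12 h
  tg <- derive_protocol_targets("07:00", "22:30")
  w <- window_row(tg$target_first, tg$target_last)
  rec <- score_tre_day(w, tg, events_row(w$first_min + 5, w$last_min + 5))
  expect_true(rec$criterion_window_reduced)
  expect_false(rec$criterion_window_le_12h)
  expect_false(rec$adherent)
})

test_that("control days are adherent iff the reported window stays >= 12 h", {
  expect_true(score_control_day(window_row(480, 480 + 13.5 * 60))$adherent)
  expect_false(score_control_day(window_row(480, 480 + 11.9 * 60))$adherent)
  expect_true(is.na(score_control_day(NULL)$adherent))
  # monotone in window duration
  durations <- seq(600, 900, by = 30)
  flags <- vapply(durations, function(d) {
    score_control_day(window_row(480, 480 + d))$adherent
  }, logical(1))
  expect_true(all(diff(flags) >= 0))
})

test_that("adherence percent recalculates the denominator for missing days", {
  expect_equal(adherence_percent(c(rep(TRUE, 22), rep(FALSE, 13))),
               100 * 22 / 35)
  expect_equal(adherence_percent(rep(FALSE, 35)), 0)
  expect_equal(adherence_percent(c(rep(TRUE, 22), rep(FALSE, 6), rep(NA, 7))),
               100 * 22 / 28)
  expect_warning(out <- adherence_percent(c(NA, NA)), "undefined")
  expect_true(is.na(out))
  # order invariance and duplication invariance
  x <- c(rep(TRUE, 9), rep(FALSE, 4), NA)
  expect_equal(adherence_percent(sample(x)), adherence_percent(x))
  expect_equal(adherence_percent(c(x, x)), adherence_percent(x))
  # marking an adherent day missing lowers numerator and denominator together
  y <- x
  y[1] <- NA
  expect_true(sum(y, na.rm = TRUE) < sum(x, na.rm = TRUE))
  expect_true(sum(!is.na(y)) < sum(!is.na(x)))
})

test_that("phase summaries convert counts to percent and days per week", {
  rec <- tibble::tibble(
    participant = "P01", group = "TRE",
    day_index = 1:14,
    adherent = c(rep(TRUE, 12), FALSE, FALSE)
  )
  s <- phase_summary(rec, "W2")
  expect_equal(s$percent, 100 * 12 / 14)
  expect_equal(s$days_per_week, 6)
  all_in <- dplyr::mutate(rec, adherent = TRUE)
  expect_equal(phase_summary(all_in, "W2")$percent, 100)
  expect_equal(phase_summary(all_in, "W2")$days_per_week, 7)
  expect_error(phase_summary(rec, "W9"), "unknown phase")
})

test_that("group mean and SEM match hand computation for two participants", {
  x <- c(60.1, 65.2)
  expect_equal(mean(x), 62.65)
  expect_equal(stats::sd(x) / sqrt(2), 2.55)
  rec <- tibble::tibble(
    participant = rep(c("A", "B"), each = 14), group = "TRE",
    day_index = rep(1:14, 2),
    adherent = TRUE
  )
  tbl <- group_phase_table(rec)
  w2 <- tbl[tbl$phase == "W2", ]
  expect_equal(w2$n, 2L)
  expect_equal(w2$mean_percent, 100)
  expect_equal(w2$sem, 0)
})

test_that("phase combination reproduces the unweighted study-level means", {
  expect_equal(combine_phases(60.1, 65.2), 62.65)
  expect_equal(round_half_up(combine_phases(60.1, 65.2), 1), 62.7)
  expect_equal(combine_phases(82.4, 75.2), 78.8)
  expect_equal(combine_phases(44.4, 44.4), 44.4)  # idempotence
  expect_true(is.na(combine_phases(NA_real_, 50)))
  # day-weighted variant for sensitivity analysis
  expect_equal(combine_phases(60.1, 65.2, weights = c(14, 21)),
               (14 * 60.1 + 21 * 65.2) / 35)
})
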