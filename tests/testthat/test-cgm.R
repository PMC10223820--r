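test_that("CGM parsing sorts, collapses duplicate timestamps and rejects bad rows", {
  ts <- format(as.POSIXct("2022-03-01 04:00", tz = "UTC") + (0:95) * 900,
               "%Y-%m-%d %H:%M")
  path <- write_cgm_csv(sprintf("P01,%s,%.1f", ts, rep(5, 96)))
  tr <- read_cgm(path)
  expect_equal(nrow(tr), 96L)
  expect_true(all(diff(as.numeric(tr$timestamp)) == 900))

  path <- write_cgm_csv(c("P01,2022-03-01 08:00,5.0",
                          "P01,2022-03-01 08:00,6.0"))
  expect_equal(read_cgm(path)$glucose, 5.5)

  path <- write_cgm_csv(c("P01,2022-03-01 08:00,5.0",
                          "P01,2022-03-01 08:15,-1.0"))
  expect_warning(tr <- read_cgm(path), "line\\(s\\) 3")
  expect_equal(nrow(tr), 1L)

  path <- write_cgm_csv("P01,yesterday teatime,5.0")
  expect_error(read_cgm(path), "timestamp")
})

test_that("rectangular steps are detected iff sustained at least an hour", {
  flat <- make_trace(rep(5, 40))
  expect_equal(nrow(detect_excursions(flat)), 0L)

  # 7 elevated samples at 15-min cadence span 90 min
  step90 <- step_trace(base = 5, high = 6.5, n_high = 7)
  exc <- detect_excursions(step90)
  expect_equal(nrow(exc), 1L)
  expect_equal(exc$sustained_minutes, 90)
  expect_equal(exc$reference, 5)
  expect_equal(exc$peak, 6.5)
  expect_equal(which(step90$glucose > 5)[1],
               which(step90$timestamp == exc$onset))

  # 4 elevated samples span 45 min: below the 1 h sustain rule
  step45 <- step_trace(n_high = 4)
  expect_equal(nrow(detect_excursions(step45)), 0L)

  # elevation below threshold never counts
  low <- step_trace(high = 5.9, n_high = 10)
  expect_equal(nrow(detect_excursions(low)), 0L)
})

test_that("detector equals the brute-force all-pairs oracle on random traces", {
  set.seed(202)
  for (i in 1:120) {
    n <- sample(10:80, 1)
    g <- 5 + cumsum(rnorm(n, 0, 0.3))
    if (runif(1) < 0.7) {
      k <- sample(n, 1)
      span <- k:min(n, k + sample(3:12, 1))
      g[span] <- g[span] + runif(1, 0.5, 3)
    }
    tr <- make_trace(pmax(g, 0.5), cadence = sample(c(5, 10, 15), 1))
    if (runif(1) < 0.4) {
      tr <- tr[-sample(nrow(tr), min(nrow(tr) - 2, sample(1:6, 1))), ]
    }
    expect_equal(detect_excursions(tr), oracle_excursions(tr))
  }
})

test_that("excursions are invariant to adding a constant and never overlap", {
  set.seed(55)
  for (i in 1:20) {
    g <- 5 + cumsum(rnorm(60, 0, 0.35))
    tr <- make_trace(pmax(g, 0.5))
    a <- detect_excursions(tr)
    shifted <- tr
    shifted$glucose <- shifted$glucose + 3.7
    b <- detect_excursions(shifted)
    expect_equal(a$onset, b$onset)
    expect_equal(a$sustained_minutes, b$sustained_minutes)
    expect_equal(b$reference - a$reference, rep(3.7, nrow(a)))
    if (nrow(a) > 1) {
      expect_true(all(as.numeric(a$onset[-1]) > as.numeric(a$end[-nrow(a)])))
    }
  }
})

test_that("abutting qualifying stretches merge into one excursion", {
  # two plateaus with no dip between them: glucose never returns to baseline
  g <- c(rep(5, 6), rep(6.5, 6), rep(7.5, 6), rep(5, 6))
  exc <- detect_excursions(make_trace(g))
  expect_equal(nrow(exc), 1L)
  expect_equal(exc$peak, 7.5)
})

test_that("daily summaries report onsets, counts and sensor coverage", {
  cfg <- simulation_config(noise_sd = 0)
  day <- simulate_glucose_day(c(585, 900, 1155), cfg)  # on the sample grid
  tr <- tibble::tibble(timestamp = day$timestamp, glucose = day$glucose)
  exc <- detect_excursions(tr)
  ev <- daily_glucose_events(tr, exc)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_excursions, 3L)
  expect_true(abs(ev$first_onset_min - 585) <= 15)
  expect_true(abs(ev$last_onset_min - 1155) <= 15)
  expect_equal(ev$coverage_fraction, 1)
  expect_true(ev$cgm_available)

  quiet <- make_trace(rep(5, 96))
  ev <- daily_glucose_events(quiet, detect_excursions(quiet))
  expect_true(is.na(ev$first_onset_min))
  expect_equal(ev$n_excursions, 0L)

  none <- quiet[0, ]
  ev <- daily_glucose_events(none, detect_excursions(none),
                             days = as.Date("2022-03-01"))
  expect_equal(ev$coverage_fraction, 0)
  expect_false(ev$cgm_available)
})
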