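test_that("glucose days reduce to flat basal without meals, noise or rhythms", {
  cfg <- simulation_config(noise_sd = 0, circadian_amplitude = 0,
                           dawn_bump_amplitude = 0)
  day <- simulate_glucose_day(numeric(0), cfg)
  expect_equal(nrow(day), 96L)
  expect_equal(unique(day$glucose), cfg$basal_glucose)
})

test_that("the meal kernel peaks at exactly the amplitude, tau after intake", {
  cfg <- simulation_config(noise_sd = 0, circadian_amplitude = 0,
                           dawn_bump_amplitude = 0)
  day <- simulate_glucose_day(720, cfg, amplitudes = 2)
  expect_equal(max(day$glucose), cfg$basal_glucose + 2)
  expect_equal(day$time_min[which.max(day$glucose)], 720 + cfg$meal_tau)
  # zero before intake, back near basal after the truncated tail
  expect_equal(day$glucose[day$time_min < 720], rep(cfg$basal_glucose, 32))
  expect_equal(day$glucose[day$time_min > 720 + cfg$meal_duration],
               rep(cfg$basal_glucose, sum(day$time_min > 720 + cfg$meal_duration)))
})

test_that("day simulation is reproducible under a fixed seed", {
  cfg <- simulation_config()
  a <- simulate_glucose_day(c(600, 1100), cfg, seed = 9)
  b <- simulate_glucose_day(c(600, 1100), cfg, seed = 9)
  expect_identical(a, b)
})

test_that("behavioural ground truth follows the adherence probability", {
  cfg <- simulation_config(adherence_p = 1, sensor_dropout_p = 0)
  p <- simulate_participant(cfg, "TRE", "P01", seed = 4)
  expect_true(all(p$truth$true_adherent[p$truth$day > 0]))
  cfg0 <- simulation_config(adherence_p = 0, sensor_dropout_p = 0)
  p0 <- simulate_participant(cfg0, "TRE", "P01", seed = 4)
  expect_false(any(p0$truth$true_adherent[p0$truth$day > 0]))
  expect_true(all(!is.na(p0$truth$violation_type[p0$truth$day > 0])))
})

test_that("sensor dropout days match the binomial expectation", {
  cfg <- simulation_config(sensor_dropout_p = 0.2)
  missing_days <- vapply(1:40, function(s) {
    p <- simulate_participant(cfg, "TRE", "P01", seed = s)
    sum(p$truth$sensor_dropout[p$truth$day > 0])
  }, numeric(1))
  m <- mean(missing_days)
  se <- sqrt(0.2 * 0.8 * 35 / 40)
  expect_true(abs(m - 7) < 3 * se)
})

test_that("cohorts have the requested shape and are seed-reproducible", {
  cfg <- simulation_config(n_tre = 3, n_control = 2)
  a <- simulate_study(cfg, seed = 21)
  expect_equal(nrow(a$roster), 5L)
  expect_equal(sum(a$roster$group == "TRE"), 3L)
  expect_setequal(unique(a$truth$participant), a$roster$id)
  b <- simulate_study(cfg, seed = 21)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cgm, b$cgm)

  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  write_cohort(a, dir_a); write_cohort(b, dir_b)
  for (f in list.files(dir_a)) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)), label = f)
  }

  empty <- simulate_study(simulation_config(n_tre = 0, n_control = 0), seed = 1)
  expect_equal(nrow(empty$roster), 0L)
  expect_equal(nrow(empty$truth), 0L)
  dir_e <- withr::local_tempdir()
  write_cohort(empty, dir_e)
  expect_equal(length(readLines(file.path(dir_e, "cgm.csv"))), 1L)  # header only
})

test_that("emitted files round-trip through the package readers", {
  cfg <- simulation_config(n_tre = 2, n_control = 1)
  co <- simulate_study(cfg, seed = 17)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  roster <- read_roster(file.path(dir, "roster.csv"))
  expect_equal(nrow(roster), 3L)
  ev <- read_diary(file.path(dir, "diary.csv"))
  expect_setequal(unique(ev$participant), roster$id)
  tr <- read_cgm(file.path(dir, "cgm.csv"))
  expect_true(all(tr$glucose > 0))
  q <- readr::read_csv(file.path(dir, "questionnaire.csv"),
                       show_col_types = FALSE)
  expect_silent(code_likert(q$item, q$category))
})
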