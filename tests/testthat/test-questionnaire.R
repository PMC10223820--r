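test_that("Likert categories code to printed-range midpoints and scales", {
  expect_equal(code_likert("window_days", "Always 7 days"), 7)
  expect_equal(code_likert("window_days", "Never 0 days"), 0)
  expect_equal(code_likert("window_days", "Approx. half 3-4 days"), 3.5)
  expect_equal(code_likert("window_days", "Sometimes 1–2 days"), 1.5)  # en-dash
  expect_equal(code_likert("ease", c("Extremely difficult", "Extremely easy")),
               c(1, 5))
  expect_equal(code_likert("realistic_days", "5"), 5)
  expect_equal(code_likert("restrict_hours", c("<0.5 h", ">4 h")), c(1, 6))
  expect_error(code_likert("window_days", "Mostly"), "window_days.*Mostly")
  expect_error(code_likert("sleep_quality", "Good"), "unknown questionnaire item")
})

test_that("days-per-week convert to integer percents by half-up rounding", {
  expect_equal(days_to_percent(4.3), 61L)
  expect_equal(days_to_percent(3), 43L)
  expect_equal(days_to_percent(7), 100L)
  expect_equal(days_to_percent(0), 0L)
  expect_error(days_to_percent(7.5), "\\[0, 7\\]")
  # monotone non-decreasing over the whole range
  grid <- seq(0, 7, by = 0.01)
  expect_true(all(diff(days_to_percent(grid)) >= 0))
})

test_that("group summaries report mean and SEM with n-1 denominator", {
  resp <- tibble::tibble(
    participant = sprintf("P%02d", 1:6),
    group = rep(c("TRE", "CONTROL"), each = 3),
    item = "window_days",
    value = c(4, 4, 4, 3, 5, 4)
  )
  s <- group_summary(resp)
  tre <- s[s$group == "TRE", ]
  expect_equal(tre$mean, 4)
  expect_equal(tre$sem, 0)
  two <- group_summary(tibble::tibble(participant = c("A", "B"), group = "TRE",
                                      item = "x", value = c(3, 5)))
  expect_equal(two$mean, 4)
  expect_equal(two$sem, 1)
  one <- group_summary(tibble::tibble(participant = "A", group = "TRE",
                                      item = "x", value = 4))
  expect_equal(one$mean, 4)
  expect_true(is.na(one$sem))
})

test_that("two-sample t-test matches the reference implementation and edge cases", {
  expect_equal(two_sample_t(c(5, 5, 5), c(5, 5, 5)),
               tibble::tibble(statistic = 0, df = 4, p = 1))
  tt <- two_sample_t(1:3, 4:6, pooled = TRUE)
  expect_equal(round(tt$statistic, 3), -3.674)
  expect_equal(tt$df, 4)
  set.seed(81)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    pooled <- runif(1) < 0.5
    ref <- stats::t.test(a, b, var.equal = pooled)
    got <- two_sample_t(a, b, pooled = pooled)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    # antisymmetric in group order
    rev <- two_sample_t(b, a, pooled = pooled)
    expect_equal(rev$statistic, -got$statistic)
    expect_equal(rev$p, got$p)
  }
  const <- two_sample_t(c(2, 2), c(3, 3))
  expect_equal(const$statistic, -Inf)
  expect_equal(const$p, 0)
})

test_that("2x2 chi-squared matches hand-computed statistics", {
  # E = {7.5, 0.5, 7.5, 0.5}: sum (O-E)^2/E = 2(0.25/7.5) + 2(0.25/0.5)
  sexes <- matrix(c(8, 7, 0, 1), nrow = 2)
  got <- chi_square_2x2(sexes)
  expect_equal(got$statistic, 2 * 0.25 / 7.5 + 2 * 0.25 / 0.5,
               tolerance = 1e-12)
  expect_equal(got$df, 1)
  even <- chi_square_2x2(matrix(5, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  # invariant to transposition
  m <- matrix(c(9, 3, 4, 8), 2)
  expect_equal(chi_square_2x2(m), chi_square_2x2(t(m)))
  expect_warning(bad <- chi_square_2x2(matrix(c(3, 4, 0, 0), 2)), "margin")
  expect_true(is.na(bad$statistic))
})

test_that("the questionnaire table compares groups item by item", {
  set.seed(5)
  resp <- tidyr::expand_grid(participant = sprintf("P%02d", 1:8),
                             item = c("window_days", "ease")) |>
    dplyr::mutate(
      group = rep(c("TRE", "CONTROL"), each = 2, length.out = 16),
      value = round(runif(16, 1, 5))
    )
  tbl <- questionnaire_table(resp)
  expect_setequal(tbl$item, c("window_days", "ease"))
  expect_true(all(c("tre_mean", "ctrl_mean", "t", "p") %in% names(tbl)))
  hand <- resp$value[resp$item == "window_days" & resp$group == "TRE"]
  expect_equal(tbl$tre_mean[tbl$item == "window_days"], mean(hand))
})
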