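#' @title Exit-questionnaire coding and summaries
#' @name questionnaire
#' @description
#' The exit questionnaire measures subjective adherence and preference on
#' Likert scales. Days-per-week items use five verbal bins which are coded
#' to the midpoint of each printed range; the ease item is a five-point
#' difficulty scale; the realistic-days item collects an exact 0--7 count;
#' the window-restriction item is a six-bin ordinal duration scale.
NULL

likert_day_bins <- c("Never 0 days" = 0, "Sometimes 1-2 days" = 1.5,
                     "Approx. half 3-4 days" = 3.5,
                     "Most of the time 5-6 days" = 5.5, "Always 7 days" = 7)
likert_ease <- c("Extremely difficult" = 1, "Somewhat difficult" = 2,
                 "Neither easy nor difficult" = 3, "Somewhat easy" = 4,
                 "Extremely easy" = 5)
likert_restrict <- c("<0.5 h" = 1, "0.5-1 h" = 2, "1.1-2 h" = 3,
                     "2.1-3 h" = 4, "3.1-4 h" = 5, ">4 h" = 6)

day_bin_items <- c("morning_days", "evening_days", "window_days", "plan_days")

likert_map_for <- function(item) {
  if (item %in% day_bin_items) return(likert_day_bins)
  switch(item,
         ease = likert_ease,
         restrict_hours = likert_restrict,
         realistic_days = stats::setNames(0:7, as.character(0:7)),
         stop("unknown questionnaire item: ", item, call. = FALSE))
}

#' Code a Likert response category to its numeric value
#'
#' Day-bin categories map to the midpoints of their printed ranges
#' (Never 0 days -> 0, Sometimes 1-2 days -> 1.5, Approx. half 3-4 days
#' -> 3.5, Most of the time 5-6 days -> 5.5, Always 7 days -> 7); the
#' ease item maps Extremely difficult..Extremely easy to 1..5;
#' `realistic_days` accepts integers 0--7 verbatim; `restrict_hours` bins
#' map to ordinal 1--6. En-dashes in option text are accepted.
#'
#' @param item Item id (vectorised): one of `ease`, `morning_days`,
#'   `evening_days`, `window_days`, `plan_days`, `realistic_days`,
#'   `restrict_hours`.
#' @param category Verbatim option text (vectorised).
#' @return Numeric codings.
#' @examples
#' code_likert("window_days", "Approx. half 3-4 days")  # 3.5
#' @export
code_likert <- function(item, category) {
  category <- gsub("–", "-", category)
  mapply(function(it, cat) {
    map <- likert_map_for(it)
    if (!cat %in% names(map)) {
      stop("unknown category for item '", it, "': \"", cat, "\"", call. = FALSE)
    }
    unname(map[cat])
  }, item, category, USE.NAMES = FALSE)
}

#' Convert days-per-week to an integer percent of the week
#'
#' @param days Numeric days in [0, 7].
#' @return `round-half-up(100 * days / 7)` as an integer.
#' @examples
#' days_to_percent(c(4.3, 3, 7))  # 61 43 100
#' @export
days_to_percent <- function(days) {
  if (any(is.na(days)) || any(days < 0 | days > 7)) {
    stop("days-per-week must lie in [0, 7]", call. = FALSE)
  }
  as.integer(round_half_up(100 * days / 7))
}

#' Mean and SEM of coded responses per group and item
#'
#' @param responses Tibble with `participant`, `group`, `item` and either
#'   `category` (coded via [code_likert()]) or a numeric `value` column.
#' @return A tibble `item,group,n,mean,sem`; `sem` is NA (sample SD with
#'   n-1 denominator over sqrt(n)) when a cell has fewer than 2 values.
#' @export
group_summary <- function(responses) {
  responses <- tibble::as_tibble(responses)
  if (!"value" %in% names(responses)) {
    responses$value <- code_likert(responses$item, responses$category)
  }
  responses |>
    dplyr::group_by(.data$item, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value), .groups = "drop")
}

#' Two-sample t-test on coded responses
#'
#' Student's pooled-variance test by default (matching common statistical
#' software defaults); Welch's unequal-variance test via `pooled = FALSE`.
#' When both groups are constant with equal means the statistic is 0 with
#' p = 1; constant groups with different means give an infinite statistic
#' with p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param pooled Use the pooled-variance (Student) statistic.
#' @return A one-row tibble `statistic,df,p`.
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    df <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) {
      return(tibble::tibble(statistic = 0, df = df, p = 1))
    }
    return(tibble::tibble(statistic = sign(mean(a) - mean(b)) * Inf,
                          df = df, p = 0))
  }
  fit <- stats::t.test(a, b, var.equal = pooled)
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p = fit$p.value)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param correct Apply Yates' continuity correction (default FALSE).
#' @return A one-row tibble `statistic,df,p`; NA with a warning when a
#'   row or column total is zero (expected counts undefined).
#' @examples
#' chi_square_2x2(matrix(c(8, 7, 0, 1), nrow = 2))
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero row/column margin: chi-squared statistic undefined",
            call. = FALSE)
    return(tibble::tibble(statistic = NA_real_, df = 1, p = NA_real_))
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter), p = fit$p.value)
}

#' Between-group questionnaire comparison table
#'
#' Produces the exit-questionnaire reporting layout: per item, each
#' group's mean and SEM of the coded responses plus the two-sample
#' t-test comparing the groups.
#'
#' @param responses Tibble `participant,group,item,category` (or with a
#'   numeric `value` column).
#' @param pooled Passed to [two_sample_t()].
#' @return A tibble `item,tre_mean,tre_sem,ctrl_mean,ctrl_sem,t,p`.
#' @export
questionnaire_table <- function(responses, pooled = TRUE) {
  responses <- tibble::as_tibble(responses)
  if (!"value" %in% names(responses)) {
    responses$value <- code_likert(responses$item, responses$category)
  }
  purrr::map_dfr(unique(responses$item), function(it) {
    a <- responses$value[responses$item == it & responses$group == "TRE"]
    b <- responses$value[responses$item == it & responses$group == "CONTROL"]
    tt <- if (length(a) >= 2 && length(b) >= 2) two_sample_t(a, b, pooled) else
      tibble::tibble(statistic = NA_real_, df = NA_real_, p = NA_real_)
    tibble::tibble(item = it,
                   tre_mean = mean(a), tre_sem = sem(a),
                   ctrl_mean = mean(b), ctrl_sem = sem(b),
                   t = tt$statistic, p = tt$p)
  })
}
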