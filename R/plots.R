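#' Diagnostic plot of one participant-day
#'
#' Shows the day's glucose curve with the reported first/last intake
#' times, the target eating window (TRE participants), and the detected
#' excursion onsets — the at-a-glance view used to judge whether CGM
#' responses correspond to the reported eating occasions.
#'
#' @param cgm CGM tibble (`participant`, `timestamp`, `glucose`).
#' @param diary Diary events as from [read_diary()].
#' @param participant Participant id.
#' @param eating_day Date of the eating day to plot.
#' @param targets Optional [derive_protocol_targets()] row; when given,
#'   the target window is shaded and excursion constants are taken from
#'   it.
#' @return A ggplot object. Errors when the day has no CGM samples.
#' @export
plot_cgm_day <- function(cgm, diary, participant, eating_day,
                         targets = NULL) {
  eating_day <- as.Date(eating_day)
  trace <- cgm |>
    dplyr::filter(.data$participant == !!participant,
                  eating_day_of(.data$timestamp) == !!eating_day)
  if (nrow(trace) == 0) {
    stop("no CGM data for ", participant, " on ", format(eating_day),
         call. = FALSE)
  }
  exc <- detect_excursions(trace, targets)
  win <- daily_windows(diary) |>
    dplyr::filter(.data$participant == !!participant,
                  .data$eating_day == !!eating_day)
  midnight <- as.POSIXct(paste(eating_day, "00:00:00"), tz = "UTC")

  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$timestamp,
                                           y = .data$glucose))
  if (!is.null(targets)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = midnight + targets$target_first * 60,
      xmax = midnight + targets$target_last * 60,
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue"
    )
  }
  p <- p + ggplot2::geom_line(colour = "grey30")
  if (nrow(win) == 1) {
    p <- p + ggplot2::geom_vline(
      xintercept = midnight + c(win$first_min, win$last_min) * 60,
      linetype = "dashed", colour = "darkred"
    )
  }
  if (nrow(exc)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(
        timestamp = exc$onset,
        glucose = trace$glucose[match(exc$onset, trace$timestamp)]
      ),
      colour = "darkorange", size = 3, shape = 17
    )
  }
  p + ggplot2::labs(
    x = NULL, y = "glucose (mmol/L)",
    title = paste0(participant, " — ", format(eating_day)),
    subtitle = "dashed: reported first/last intake; triangles: excursion onsets"
  ) + ggplot2::theme_minimal()
}

#' Plot group-by-phase adherence
#'
#' @param object A [score_study()] result.
#' @param ... Unused.
#' @return A ggplot of mean adherence percent (+/- SEM) by phase and
#'   group.
#' @method autoplot tre_adherence
#' @export
autoplot.tre_adherence <- function(object, ...) {
  tbl <- dplyr::filter(object$groups, .data$phase != "Mean")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$phase, y = .data$mean_percent,
                                    group = .data$group,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_percent - .data$sem,
      ymax = .data$mean_percent + .data$sem
    )) +
    ggplot2::labs(x = "study phase", y = "adherence (% of available days)",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
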