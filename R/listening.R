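#' Aggregate daily listening logs
#'
#' Summarizes per-session listening logs into mean hours per day per subject
#' over each subject's logged span, flagging subjects below the adherence
#' threshold (default 2 h/day, the recommended minimum daily exposure).
#'
#' @param logs A data frame with columns `subject_id`, `date` (ISO-8601
#'   `YYYY-MM-DD`), `minutes_listened` (>= 0) and optionally `source`
#'   (`"app"` or `"self_report"`).
#' @param adherence_threshold_hours Daily-hours threshold below which a
#'   subject is flagged nonadherent.
#' @return A tibble with `subject_id`, `days_logged`, `span_days` (inclusive
#'   calendar span from first to last log), `total_hours`, `mean_hours_per_day`
#'   (total hours / span), `adherent`.
#' @export
#' @examples
#' logs <- data.frame(subject_id = "S1",
#'                    date = as.character(seq(as.Date("2024-01-01"),
#'                                            by = 1, length.out = 90)),
#'                    minutes_listened = 120)
#' aggregate_listening(logs)  # 2 h/day, adherent
aggregate_listening <- function(logs, adherence_threshold_hours = 2) {
  required <- c("subject_id", "date", "minutes_listened")
  if (!all(required %in% names(logs))) {
    stop("Logs need columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(logs) == 0) stop("Need logs for at least one subject.",
                            call. = FALSE)
  if (anyNA(logs$minutes_listened) || any(logs$minutes_listened < 0)) {
    stop("`minutes_listened` must be nonnegative.", call. = FALSE)
  }
  dates <- as.Date(logs$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("Dates must be ISO-8601 (YYYY-MM-DD); first bad value: ",
         logs$date[which(is.na(dates))[1]], call. = FALSE)
  }
  if ("source" %in% names(logs) &&
      !all(logs$source %in% c("app", "self_report"))) {
    stop("`source` must be 'app' or 'self_report'.", call. = FALSE)
  }
  logs$date <- dates
  has_any <- tapply(logs$minutes_listened, logs$subject_id, sum) > 0
  if (any(!has_any)) {
    warning("Excluding subject(s) with no listening recorded: ",
            paste(names(has_any)[!has_any], collapse = ", "))
  }
  logs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarize(
      days_logged = dplyr::n_distinct(.data$date),
      span_days = as.integer(max(.data$date) - min(.data$date)) + 1L,
      total_hours = sum(.data$minutes_listened) / 60,
      .groups = "drop") |>
    dplyr::filter(.data$total_hours > 0) |>
    dplyr::mutate(
      mean_hours_per_day = .data$total_hours / .data$span_days,
      adherent = .data$mean_hours_per_day >= adherence_threshold_hours)
}
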