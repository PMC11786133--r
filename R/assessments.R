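# Per-instrument item schemas: item count and admissible item values.
INSTRUMENT_SCHEMAS <- list(
  THI  = list(n_items = 25, values = c(0, 2, 4), max_total = 100),
  HADS = list(n_items = 14, values = 0:3,        max_total = 42),
  AIS  = list(n_items = 8,  values = 0:3,        max_total = 24),
  FTQ  = list(n_items = 17, values = 0:1,        max_total = 17),
  TCS  = list(n_items = 13, values = 0:4,        max_total = 52),
  VAS  = list(n_items = 1,  values = 0:10,       max_total = 10)
)

# Conventional alternating HADS item assignment: odd items anxiety, even items
# depression. This is a scoring convention, configurable per site.
HADS_DEFAULT_ANXIETY_ITEMS <- seq(1, 13, by = 2)

validate_items <- function(instrument, items) {
  schema <- INSTRUMENT_SCHEMAS[[instrument]]
  if (is.null(schema)) {
    stop("Unknown instrument: ", instrument, call. = FALSE)
  }
  items <- as.numeric(items)
  if (length(items) != schema$n_items) {
    stop(sprintf("%s requires %d items, got %d.",
                 instrument, schema$n_items, length(items)), call. = FALSE)
  }
  bad <- which(!(items %in% schema$values))
  if (length(bad)) {
    stop(sprintf(
      "%s item %d has value %s; admissible values: %s.",
      instrument, bad[1], format(items[bad[1]]),
      paste(schema$values, collapse = ", ")), call. = FALSE)
  }
  items
}

new_scale_score <- function(instrument, total, subscales = NULL,
                            timepoint = NA_character_) {
  structure(
    list(instrument = instrument, total = total, subscales = subscales,
         timepoint = timepoint),
    class = "scale_score"
  )
}

#' @export
print.scale_score <- function(x, ...) {
  cat(x$instrument, "score:", x$total)
  if (!is.null(x$subscales)) {
    cat("  (", paste(names(x$subscales), unlist(x$subscales),
                     sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Score the Tinnitus Handicap Inventory (THI)
#'
#' 25 items scored 0/2/4; the total ranges 0-100, higher meaning more severe
#' tinnitus-related handicap. Missing or off-scale items are rejected.
#'
#' @param items Integer vector of 25 responses, each 0, 2 or 4.
#' @param timepoint Optional timepoint label (`"T0"`..`"T3"`).
#' @return A `scale_score` with the THI total.
#' @export
#' @examples
#' score_thi(rep(4, 25))$total  # 100, the scale maximum
score_thi <- function(items, timepoint = NA_character_) {
  items <- validate_items("THI", items)
  new_scale_score("THI", sum(items), timepoint = timepoint)
}

#' Score the Hospital Anxiety and Depression Scale (HADS)
#'
#' 14 items scored 0-3; seven items form the anxiety subscale (HADS-A) and the
#' remaining seven the depression subscale (HADS-D), each ranging 0-21. The
#' anxiety item positions are configurable; the shipped default is the
#' conventional alternating assignment (odd items anxiety).
#'
#' @param items Integer vector of 14 responses in 0..3.
#' @param anxiety_items Integer vector of exactly 7 item positions (1-based)
#'   forming the anxiety subscale.
#' @inheritParams score_thi
#' @return A `scale_score` whose `subscales` holds `A` and `D`; `total` is
#'   their sum.
#' @export
score_hads <- function(items, anxiety_items = HADS_DEFAULT_ANXIETY_ITEMS,
                       timepoint = NA_character_) {
  items <- validate_items("HADS", items)
  anxiety_items <- as.integer(anxiety_items)
  if (length(anxiety_items) != 7 || anyNA(anxiety_items) ||
      any(anxiety_items < 1 | anxiety_items > 14) ||
      anyDuplicated(anxiety_items)) {
    stop("`anxiety_items` must be 7 distinct positions in 1..14.",
         call. = FALSE)
  }
  a <- sum(items[anxiety_items])
  d <- sum(items[-anxiety_items])
  new_scale_score("HADS", a + d, subscales = list(A = a, D = d),
                  timepoint = timepoint)
}

#' Score the Athens Insomnia Scale (AIS)
#'
#' 8 items scored 0-3; total 0 (no sleep disorder) to 24 (most severe
#' insomnia).
#'
#' @param items Integer vector of 8 responses in 0..3.
#' @inheritParams score_thi
#' @export
score_ais <- function(items, timepoint = NA_character_) {
  items <- validate_items("AIS", items)
  new_scale_score("AIS", sum(items), timepoint = timepoint)
}

#' Score the Fear of Tinnitus Questionnaire (FTQ)
#'
#' 17 binary items, 1 point each; total 0-17, higher meaning greater fear of
#' tinnitus.
#'
#' @param items Integer vector of 17 responses in 0..1.
#' @inheritParams score_thi
#' @export
score_ftq <- function(items, timepoint = NA_character_) {
  items <- validate_items("FTQ", items)
  new_scale_score("FTQ", sum(items), timepoint = timepoint)
}

#' Score the Tinnitus Catastrophizing Scale (TCS)
#'
#' 13 items rated 0-4; total 0-52, higher meaning more tinnitus-specific
#' catastrophizing.
#'
#' @param items Integer vector of 13 responses in 0..4.
#' @inheritParams score_thi
#' @export
score_tcs <- function(items, timepoint = NA_character_) {
  items <- validate_items("TCS", items)
  new_scale_score("TCS", sum(items), timepoint = timepoint)
}

#' Validate a Visual Analog Scale (VAS) rating
#'
#' A single integer loudness/annoyance rating in 0..10, passed through after
#' validation.
#'
#' @param value Integer in 0..10.
#' @inheritParams score_thi
#' @export
score_vas <- function(value, timepoint = NA_character_) {
  value <- validate_items("VAS", value)
  new_scale_score("VAS", value, timepoint = timepoint)
}

#' Validate a tinnitus severity grade
#'
#' The subjective severity assessment assigns one of four grades, I (no or
#' minimal impairment) through IV (unable to work or live normally). Accepts
#' Roman-numeral tokens (also Unicode Roman numerals and lowercase) and
#' integers 1-4.
#'
#' @param grade Grade token.
#' @return The normalized grade as a factor level in `c("I","II","III","IV")`.
#' @export
#' @examples
#' validate_severity("IV")
#' validate_severity(2)
validate_severity <- function(grade) {
  grades <- c("I", "II", "III", "IV")
  if (length(grade) != 1 || is.na(grade)) {
    stop("`grade` must be a single non-missing token.", call. = FALSE)
  }
  if (is.numeric(grade)) {
    if (!grade %in% 1:4) {
      stop("Numeric severity grade must be 1, 2, 3 or 4; got ", grade, ".",
           call. = FALSE)
    }
    return(factor(grades[grade], levels = grades))
  }
  token <- toupper(trimws(as.character(grade)))
  # Unicode Roman numerals as printed in some clinical tables
  unicode <- c("Ⅰ" = "I", "Ⅱ" = "II", "Ⅲ" = "III",
               "Ⅳ" = "IV")
  if (token %in% names(unicode)) token <- unicode[[token]]
  if (!token %in% grades) {
    stop("Unknown severity grade: '", grade,
         "'. Expected I, II, III or IV.", call. = FALSE)
  }
  factor(token, levels = grades)
}

#' Score long-form item responses
#'
#' Scores a tidy long-form response table with columns `subject_id`,
#' `timepoint`, `instrument`, `item_index`, `value` into one row per
#' subject-timepoint-instrument. Items must be complete for each instrument;
#' incomplete instruments raise an error unless `prorate = TRUE`, in which case
#' the total is scaled to the full item count (requires at least half the items
#' present) and flagged in the `prorated` column.
#'
#' @param responses A data frame in the long schema above.
#' @param anxiety_items HADS anxiety item positions, see [score_hads()].
#' @param prorate Allow prorating of incomplete instruments (default `FALSE`).
#' @return A tibble with columns `subject_id`, `timepoint`, `instrument`,
#'   `total`, `hads_a`, `hads_d`, `prorated`.
#' @export
score_responses <- function(responses,
                            anxiety_items = HADS_DEFAULT_ANXIETY_ITEMS,
                            prorate = FALSE) {
  required <- c("subject_id", "timepoint", "instrument", "item_index", "value")
  if (!all(required %in% names(responses))) {
    stop("Responses need columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  score_one <- function(d) {
    instrument <- d$instrument[1]
    schema <- INSTRUMENT_SCHEMAS[[instrument]]
    if (is.null(schema)) stop("Unknown instrument: ", instrument, call. = FALSE)
    d <- dplyr::arrange(d, .data$item_index)
    complete <- nrow(d) == schema$n_items &&
      identical(as.integer(d$item_index), seq_len(schema$n_items))
    prorated <- FALSE
    if (!complete) {
      if (!prorate) {
        stop(sprintf("Incomplete %s for subject %s at %s: %d of %d items.",
                     instrument, d$subject_id[1], d$timepoint[1],
                     nrow(d), schema$n_items), call. = FALSE)
      }
      if (nrow(d) < ceiling(schema$n_items / 2)) {
        stop(sprintf("Cannot prorate %s with fewer than half the items (%d/%d).",
                     instrument, nrow(d), schema$n_items), call. = FALSE)
      }
      if (any(!(d$value %in% schema$values))) {
        stop(sprintf("Off-scale %s response.", instrument), call. = FALSE)
      }
      total <- sum(d$value) * schema$n_items / nrow(d)
      prorated <- TRUE
      return(tibble::tibble(total = total, hads_a = NA_real_,
                            hads_d = NA_real_, prorated = prorated))
    }
    score <- switch(instrument,
      THI  = score_thi(d$value),
      HADS = score_hads(d$value, anxiety_items),
      AIS  = score_ais(d$value),
      FTQ  = score_ftq(d$value),
      TCS  = score_tcs(d$value),
      VAS  = score_vas(d$value)
    )
    tibble::tibble(
      total = score$total,
      hads_a = if (instrument == "HADS") score$subscales$A else NA_real_,
      hads_d = if (instrument == "HADS") score$subscales$D else NA_real_,
      prorated = prorated
    )
  }
  responses |>
    dplyr::group_by(.data$subject_id, .data$timepoint, .data$instrument) |>
    dplyr::group_modify(~ score_one(dplyr::mutate(.x,
      subject_id = .y$subject_id, timepoint = .y$timepoint,
      instrument = .y$instrument))) |>
    dplyr::ungroup()
}
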