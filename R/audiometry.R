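#' Construct an audiogram
#'
#' An audiogram holds air-conduction pure-tone thresholds for one ear over the
#' standard octave frequencies 125 Hz to 8 kHz, on the dB HL scale.
#'
#' @param ear `"left"` or `"right"`.
#' @param frequencies_hz Numeric vector of test frequencies in Hz, a strictly
#'   ascending subset of `c(125, 250, 500, 1000, 2000, 4000, 8000)`.
#' @param thresholds_db_hl Numeric vector of thresholds in dB HL, one per
#'   frequency, each within `[-10, 120]`.
#'
#' @return An object of class `audiogram`: a list with elements `ear`,
#'   `frequencies_hz` and `thresholds_db_hl`.
#' @export
#' @examples
#' ag <- audiogram("left", c(500, 1000, 2000, 4000), c(15, 15, 20, 30))
#' compute_pta(ag)
audiogram <- function(ear, frequencies_hz, thresholds_db_hl) {
  ear <- match.arg(ear, c("left", "right"))
  allowed <- c(125, 250, 500, 1000, 2000, 4000, 8000)
  if (length(frequencies_hz) != length(thresholds_db_hl)) {
    stop("`frequencies_hz` and `thresholds_db_hl` must have equal length.",
         call. = FALSE)
  }
  if (length(frequencies_hz) == 0) {
    stop("An audiogram needs at least one frequency.", call. = FALSE)
  }
  if (!all(frequencies_hz %in% allowed)) {
    bad <- setdiff(frequencies_hz, allowed)
    stop("Non-audiometric frequencies: ", paste(bad, collapse = ", "),
         " Hz. Allowed: ", paste(allowed, collapse = ", "), " Hz.",
         call. = FALSE)
  }
  if (is.unsorted(frequencies_hz, strictly = TRUE)) {
    stop("`frequencies_hz` must be strictly ascending.", call. = FALSE)
  }
  if (anyNA(thresholds_db_hl) ||
      any(thresholds_db_hl < -10 | thresholds_db_hl > 120)) {
    stop("Thresholds must lie within [-10, 120] dB HL.", call. = FALSE)
  }
  structure(
    list(ear = ear,
         frequencies_hz = as.numeric(frequencies_hz),
         thresholds_db_hl = as.numeric(thresholds_db_hl)),
    class = "audiogram"
  )
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram (", x$ear, " ear)\n", sep = "")
  print(stats::setNames(x$thresholds_db_hl,
                        paste0(x$frequencies_hz, " Hz")))
  invisible(x)
}

# Frequencies entering the four-frequency pure-tone average.
PTA_FREQUENCIES_HZ <- c(500, 1000, 2000, 4000)

#' Pure-tone average (PTA)
#'
#' Arithmetic mean of the air-conduction thresholds at 500, 1000, 2000 and
#' 4000 Hz, the four-frequency PTA used for study eligibility.
#'
#' @param audiogram An [audiogram()].
#' @return The PTA in dB HL (unrounded).
#' @export
compute_pta <- function(audiogram) {
  stopifnot(inherits(audiogram, "audiogram"))
  idx <- match(PTA_FREQUENCIES_HZ, audiogram$frequencies_hz)
  if (anyNA(idx)) {
    missing_f <- PTA_FREQUENCIES_HZ[is.na(idx)]
    stop("PTA requires thresholds at 500, 1000, 2000 and 4000 Hz; missing: ",
         paste(missing_f, collapse = ", "), " Hz.", call. = FALSE)
  }
  mean(audiogram$thresholds_db_hl[idx])
}

#' Construct a tinnitus profile
#'
#' Clinical description of a patient's tinnitus: the psychophysically matched
#' pitch, its location, course, temporal status, and the four-grade subjective
#' severity rating.
#'
#' @param pitch_hz Matched tinnitus pitch in Hz, in `(0, 20000)`.
#' @param location `"unilateral"`, `"in_head"` or `"bilateral"`.
#' @param course_months Duration of tinnitus in months, `>= 0`.
#' @param status `"continued"` or `"intermittent"`.
#' @param severity_grade Severity grade, one of `"I"`, `"II"`, `"III"`, `"IV"`
#'   (see [validate_severity()]).
#'
#' @return An object of class `tinnitus_profile`.
#' @export
tinnitus_profile <- function(pitch_hz, location, course_months, status,
                             severity_grade) {
  if (!is.numeric(pitch_hz) || length(pitch_hz) != 1 || is.na(pitch_hz) ||
      pitch_hz <= 0 || pitch_hz >= 20000) {
    stop("`pitch_hz` must be a single value in (0, 20000) Hz.", call. = FALSE)
  }
  location <- match.arg(location, c("unilateral", "in_head", "bilateral"))
  if (!is.numeric(course_months) || course_months < 0) {
    stop("`course_months` must be >= 0.", call. = FALSE)
  }
  status <- match.arg(status, c("continued", "intermittent"))
  structure(
    list(pitch_hz = as.numeric(pitch_hz),
         location = location,
         course_months = as.numeric(course_months),
         status = status,
         severity_grade = validate_severity(severity_grade)),
    class = "tinnitus_profile"
  )
}

# Exclusion diagnoses that rule a patient out regardless of audiometry.
ELIGIBILITY_EXCLUSION_FLAGS <- c(
  "pulsatile", "objective", "otosclerosis", "meniere",
  "sudden_snhl_acute", "severe_systemic"
)

#' Check study eligibility
#'
#' Applies the enrollment rules: adults (age >= 18 years), worse-ear
#' four-frequency PTA no more than 55 dB HL, and none of the exclusion
#' diagnoses (pulsatile or objective tinnitus, otosclerosis, Meniere disease,
#' acute sudden sensorineural hearing loss, severe systemic disease). A PTA of
#' exactly 55 dB HL is eligible.
#'
#' @param age Age in years.
#' @param worse_ear_pta PTA of the worse (higher-PTA) ear, dB HL.
#' @param exclusion_flags Character vector of present exclusion diagnoses, a
#'   subset of `r paste0('c("', paste(ELIGIBILITY_EXCLUSION_FLAGS, collapse = '", "'), '")')`.
#'
#' @return A list with `eligible` (logical) and `reasons` (character vector of
#'   failed rules, empty when eligible).
#' @export
#' @examples
#' check_eligibility(45, 55)           # eligible: boundary PTA allowed
#' check_eligibility(17, 20)           # ineligible: age
check_eligibility <- function(age, worse_ear_pta, exclusion_flags = character()) {
  if (!is.numeric(age) || length(age) != 1 || is.na(age) || age < 0) {
    stop("`age` must be a single nonnegative number of years.", call. = FALSE)
  }
  if (!is.numeric(worse_ear_pta) || length(worse_ear_pta) != 1 ||
      is.na(worse_ear_pta)) {
    stop("`worse_ear_pta` must be a single number (dB HL).", call. = FALSE)
  }
  exclusion_flags <- as.character(exclusion_flags)
  unknown <- setdiff(exclusion_flags, ELIGIBILITY_EXCLUSION_FLAGS)
  if (length(unknown)) {
    stop("Unknown exclusion flags: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  reasons <- character()
  if (age < 18) {
    reasons <- c(reasons, "age: must be at least 18 years")
  }
  if (worse_ear_pta > 55) {
    reasons <- c(reasons, sprintf(
      "pta: worse-ear PTA %.1f dB HL exceeds the 55 dB HL limit",
      worse_ear_pta))
  }
  if (length(exclusion_flags)) {
    reasons <- c(reasons, paste0("exclusion: ", sort(unique(exclusion_flags))))
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Worse-ear PTA of a pair of audiograms
#'
#' The worse ear is the ear with the larger PTA; with equal PTAs either ear
#' gives the same value.
#'
#' @param left,right [audiogram()] objects for the two ears.
#' @return The larger of the two PTAs, in dB HL.
#' @export
worse_ear_pta <- function(left, right) {
  max(compute_pta(left), compute_pta(right))
}

#' Read and write audiograms as CSV
#'
#' The CSV schema has columns `ear`, `frequency_hz`, `threshold_db_hl`, one row
#' per ear-frequency pair; a file may hold one or both ears.
#'
#' @param path Path to a CSV file.
#' @return `read_audiogram_csv()`: a named list of [audiogram()] objects keyed
#'   by ear. `write_audiogram_csv()`: `path`, invisibly.
#' @export
read_audiogram_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("ear", "frequency_hz", "threshold_db_hl")
  if (!all(required %in% names(df))) {
    stop("Audiogram CSV needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$ear, .data$frequency_hz)
  out <- lapply(split(df, df$ear), function(d) {
    audiogram(d$ear[1], d$frequency_hz, d$threshold_db_hl)
  })
  out
}

#' @param audiograms A single [audiogram()] or list of them.
#' @rdname read_audiogram_csv
#' @export
write_audiogram_csv <- function(audiograms, path) {
  if (inherits(audiograms, "audiogram")) audiograms <- list(audiograms)
  rows <- lapply(audiograms, function(a) {
    tibble::tibble(ear = a$ear,
                   frequency_hz = a$frequencies_hz,
                   threshold_db_hl = a$thresholds_db_hl)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}
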