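#' Read and write the pipeline's CSV tables
#'
#' Thin readr wrappers enforcing the three table schemas. Observations: one
#' row per observation set with columns `patient_id`, `timestamp`
#' (ISO-8601), `resp_rate`, `spo2`, `o2_flow`, `temp`, `temp_site`, `sbp`,
#' `hr`, `consciousness`, `pain`; an empty cell is a missing measurement.
#' Events: `patient_id`, `timestamp`, `event_type` (1--4), `detail`.
#' Patients: `patient_id`, `admission` (emergency-department arrival),
#' `discharge`, plus optional `ward_admission`, `center`, `age`, `sex`,
#' `cfs`, `dnr`, `delirium_flag`.
#'
#' @param path CSV file path.
#' @param tz Timezone applied to timestamps (default UTC).
#' @return A tibble with parsed timestamp columns.
#' @name ews_io
NULL

#' @rdname ews_io
#' @export
read_observations <- function(path, tz = "UTC") {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      temp_site = readr::col_character(),
      consciousness = readr::col_character(),
      .default = readr::col_double()
    )
  )
  attr(out$timestamp, "tzone") <- tz
  assert_columns(out, c("patient_id", "timestamp", "resp_rate", "spo2",
                        "o2_flow", "temp", "sbp", "hr", "consciousness"),
                 "observations CSV")
  out
}

#' @rdname ews_io
#' @export
read_events <- function(path, tz = "UTC") {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      event_type = readr::col_integer(),
      .default = readr::col_character()
    )
  )
  attr(out$timestamp, "tzone") <- tz
  assert_columns(out, c("patient_id", "timestamp", "event_type"), "events CSV")
  if (!all(out$event_type %in% 1:4)) abort("event_type must be 1, 2, 3 or 4")
  out
}

#' @rdname ews_io
#' @export
read_patients <- function(path, tz = "UTC") {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      admission = readr::col_datetime(),
      discharge = readr::col_datetime(),
      .default = readr::col_guess()
    )
  )
  for (col in intersect(c("admission", "ward_admission", "discharge"), names(out))) {
    attr(out[[col]], "tzone") <- tz
  }
  assert_columns(out, c("patient_id", "admission", "discharge"), "patients CSV")
  out
}

#' @rdname ews_io
#' @param cohort A list with `patients`, `observations`, `events` (e.g. from
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$observations, file.path(dir, "observations.csv"))
  readr::write_csv(cohort$events, file.path(dir, "events.csv"))
  invisible(file.path(dir, c("patients.csv", "observations.csv", "events.csv")))
}
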