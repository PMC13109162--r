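#' Hand-constructed worked fixture
#'
#' A tiny deterministic five-patient dataset exercising every labeling and
#' imputation rule: a Type 4 event absorbed into a Type 1--3 event 8 h
#' later; two early Type 4 events splitting a stay into two episodes 72 h
#' after the last of them; a Type 4 event with no room for a second episode;
#' an event-free patient whose observation sets exercise all four
#' zero-imputation conditions plus carry-forward; and a patient with a
#' distinct Type 4 / Type 1--3 event pair more than 12 h apart, where the
#' Type 1--3 event window overrides post-Type-4 neutralization. Expected
#' labels and episodes were enumerated by hand from the interval rules and
#' ship alongside the data.
#'
#' @return List with `patients`, `observations`, `events`,
#'   `expected_labels` (patient, timestamp, episode, label for the
#'   all-events analysis) and `expected_episodes`.
#' @examples
#' fx <- generate_worked_fixture()
#' fx$expected_episodes
#' @export
generate_worked_fixture <- function() {
  base <- as.POSIXct("2022-10-01 00:00:00", tz = "UTC")
  at <- function(h) base + h * 3600

  patients <- tibble(
    patient_id = paste0("F", 1:5),
    admission = at(rep(0, 5)),
    discharge = at(c(300, 300, 100, 120, 300)),
    center = c(1L, 1L, 2L, 2L, 3L)
  )

  events <- tibble(
    patient_id = c("F1", "F1", "F2", "F2", "F3", "F5", "F5"),
    timestamp = at(c(50, 58, 10, 40, 40, 50, 70)),
    event_type = c(4L, 2L, 4L, 4L, 4L, 4L, 3L),
    detail = c("medical", "icu_transfer", "medical", "medical", "medical",
               "medical", "palliative")
  )

  obs_times <- list(
    F1 = c(20, 40, 47, 60, 200),
    F2 = c(5, 12, 100, 150, 290),
    F3 = c(10, 20, 29, 50, 99),
    F4 = c(10, 50, 56, 90),
    F5 = c(45, 47, 55, 60, 80, 200)
  )
  observations <- purrr::imap_dfr(obs_times, function(hs, pid) {
    tibble(
      patient_id = pid,
      timestamp = at(hs),
      resp_rate = 16, spo2 = 96, o2_flow = 0, temp = 36.8,
      temp_site = "tympanic", sbp = 130, hr = 70,
      consciousness = "alert", pain = 0
    )
  })
  # F4 exercises the imputation conditions:
  #  t=10 first set (resp_rate, spo2 missing -> 0);
  #  t=50 fully measured; t=56 (6 h gap) missing -> carried forward;
  #  t=90 (34 h gap) spo2 missing -> 0
  observations$resp_rate[observations$patient_id == "F4"] <- c(NA, 16, NA, 16)
  observations$spo2[observations$patient_id == "F4"] <- c(NA, 96, NA, NA)

  expected_labels <- tibble(
    patient_id = rep(names(obs_times), lengths(obs_times)),
    timestamp = at(unlist(obs_times, use.names = FALSE)),
    episode = c(
      1L, 1L, 1L, 1L, 1L,          # F1: single episode (no retained Type 4)
      1L, 1L, 1L, 2L, 2L,          # F2: second episode from 112 h
      1L, 1L, 1L, 1L, 1L,          # F3: no room for a second episode
      1L, 1L, 1L, 1L,              # F4
      1L, 1L, 1L, 1L, 1L, 2L      # F5: second episode from 122 h
    ),
    label = c(
      "non_event", "neutralized", "event", "neutralized", "neutralized",  # F1
      "event", "neutralized", "neutralized", "non_event", "non_event",    # F2
      "non_event", "neutralized", "event", "neutralized", "neutralized",  # F3
      "non_event", "non_event", "non_event", "non_event",                 # F4
      "event", "event", "neutralized", "event", "neutralized", "neutralized" # F5
    )
  )

  expected_episodes <- tibble(
    patient_id = c("F1", "F2", "F2", "F3", "F4", "F5", "F5"),
    episode = c(1L, 1L, 2L, 1L, 1L, 1L, 2L),
    start = at(c(0, 0, 112, 0, 0, 0, 122)),
    end = at(c(300, 112, 300, 100, 120, 122, 300))
  )

  list(patients = patients, observations = observations, events = events,
       expected_labels = expected_labels, expected_episodes = expected_episodes)
}
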