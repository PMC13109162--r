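#' Labeling window configuration
#'
#' Time windows (in hours) that drive episode construction and observation
#' labeling: observation sets within `event_window` (12 h) before a clinical
#' event are *event* sets; sets between `neutral_window` (24 h) and
#' `event_window` before an event, or recorded after an event, are
#' *neutralized* (excluded from analysis); a new episode starts
#' `episode_gap` (72 h) after the last Type 4 event of the first episode;
#' and a Type 1--3 event within `merge_window` (12 h) of a preceding Type 4
#' event absorbs it.
#'
#' @param event_window Hours before an event labeled as event (default 12).
#' @param neutral_window Hours before an event within which sets outside the
#'   event window are neutralized (default 24; must exceed `event_window`).
#' @param episode_gap Hours after the last early Type 4 event at which the
#'   second episode starts (default 72).
#' @param merge_window Hours within which a Type 1--3 event absorbs a
#'   preceding Type 4 event (default 12).
#' @return A list of class `ews_window_config`.
#' @export
window_config <- function(event_window = 12, neutral_window = 24,
                          episode_gap = 72, merge_window = 12) {
  stopifnot(
    event_window > 0, neutral_window > 0, episode_gap > 0, merge_window > 0,
    event_window < neutral_window
  )
  structure(
    list(event_window = event_window, neutral_window = neutral_window,
         episode_gap = episode_gap, merge_window = merge_window),
    class = "ews_window_config"
  )
}

#' Merge clinical events within each patient
#'
#' Applies the per-patient event bookkeeping rules used before labeling:
#' events recorded at identical timestamps are de-duplicated keeping the most
#' severe (Type 1--3 over Type 4); at most one Type 1--3 event is retained
#' per patient (later events are dropped with a warning); and any Type 4
#' event within `merge_window` hours before the retained Type 1--3 event is
#' absorbed into it (the merged unit is a single Type 1--3 event keeping the
#' Type 1--3 timestamp). A Type 4 event more than `merge_window` hours before
#' the Type 1--3 event remains a distinct event.
#'
#' @param events Data frame with columns `patient_id`, `timestamp`
#'   (POSIXct), `event_type` (integer 1--4), sorted by `timestamp` within
#'   each patient (unsorted input is an error).
#' @param windows A [window_config()].
#' @return Tibble of retained events with an `event_id` column and
#'   `absorbed` (number of Type 4 events merged into a Type 1--3 event).
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "p1",
#'   timestamp = as.POSIXct("2022-10-01", tz = "UTC") + c(50, 58) * 3600,
#'   event_type = c(4L, 2L)
#' )
#' merge_events(ev) # one Type 2 event at +58 h
#' @export
merge_events <- function(events, windows = window_config()) {
  assert_columns(events, c("patient_id", "timestamp", "event_type"), "events")
  assert_sorted_within(events, "timestamp", "patient_id", "events")
  ev <- as_tibble(events)
  if (!"event_id" %in% names(ev)) {
    ev$event_id <- sprintf("E%04d", seq_len(nrow(ev)))
  }
  ev$absorbed <- 0L
  mw <- .hours(windows$merge_window)

  dropped <- 0L
  out <- ev |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(g, key) {
      # simultaneous events: keep the most severe (Type 1-3 beats Type 4)
      g <- g |>
        dplyr::group_by(.data$timestamp) |>
        dplyr::slice_min(ifelse(.data$event_type <= 3L, 0L, 1L),
                         n = 1L, with_ties = FALSE) |>
        dplyr::ungroup()
      first13 <- which(g$event_type <= 3L)[1]
      if (!is.na(first13)) {
        after <- seq_len(nrow(g)) > first13
        dropped <<- dropped + sum(after)
        g <- g[!after, , drop = FALSE]
        t13 <- as.numeric(g$timestamp[first13])
        absorb <- g$event_type == 4L &
          as.numeric(g$timestamp) >= t13 - mw & as.numeric(g$timestamp) < t13
        g$absorbed[first13] <- sum(absorb)
        g <- g[!absorb, , drop = FALSE]
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_id, .data$timestamp)
  if (dropped > 0L) {
    warn(sprintf(
      "%d event(s) after a patient's first Type 1-3 event were dropped (one Type 1-3 event per patient)",
      dropped
    ))
  }
  out
}

#' Build analysis episodes for each hospitalization
#'
#' Each hospitalization contributes one or two analysis episodes. The first
#' episode starts at admission (emergency-department arrival). If no Type 4
#' event occurs within the first `episode_gap` (72) hours, the whole stay is
#' a single episode. Otherwise the first episode ends -- and the second
#' starts -- `episode_gap` hours after the last Type 4 event of the first
#' episode; "last" is computed as a fixed point, so a Type 4 event falling
#' inside the extended first episode extends it again. The second episode is
#' omitted when its start would fall at or beyond discharge.
#'
#' @param patients Data frame with `patient_id`, `admission`, `discharge`
#'   (POSIXct).
#' @param events Merged events from [merge_events()]; events outside the
#'   patient's admission--discharge interval are an error.
#' @param windows A [window_config()].
#' @return Tibble with `patient_id`, `episode` (1 or 2), `start`, `end`;
#'   episodes partition the stay (`[start, end)` for episode 1 when a second
#'   episode exists).
#' @export
build_episodes <- function(patients, events, windows = window_config()) {
  assert_columns(patients, c("patient_id", "admission", "discharge"), "patients")
  ev <- .check_events_in_stay(events, patients)
  gap <- .hours(windows$episode_gap)

  t4 <- ev[ev$event_type == 4L, c("patient_id", "timestamp")]
  t4_by_patient <- split(as.numeric(t4$timestamp), t4$patient_id)

  purrr::pmap_dfr(
    list(patients$patient_id, as.numeric(patients$admission),
         as.numeric(patients$discharge)),
    function(pid, adm, dis) {
      if (adm >= dis) abort(sprintf("patient %s: admission is not before discharge", pid))
      t4s <- t4_by_patient[[as.character(pid)]] %||% numeric(0)
      end1 <- adm + gap
      if (!any(t4s < end1)) {
        split_at <- NA_real_
      } else {
        repeat {
          new_end <- max(t4s[t4s < end1]) + gap
          if (new_end == end1) break
          end1 <- new_end
        }
        split_at <- if (end1 < dis) end1 else NA_real_
      }
      tz <- attr(patients$admission, "tzone") %||% "UTC"
      as_time <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = tz)
      if (is.na(split_at)) {
        tibble(patient_id = pid, episode = 1L,
               start = as_time(adm), end = as_time(dis))
      } else {
        tibble(patient_id = pid, episode = c(1L, 2L),
               start = as_time(c(adm, split_at)),
               end = as_time(c(split_at, dis)))
      }
    }
  )
}

#' @noRd
.check_events_in_stay <- function(events, patients, what = "events") {
  ev <- as_tibble(events)
  if (nrow(ev) == 0L) return(ev)
  joined <- dplyr::left_join(
    ev, patients[, c("patient_id", "admission", "discharge")], by = "patient_id"
  )
  if (anyNA(joined$admission)) {
    abort(sprintf("%s refer to unknown patients: %s", what,
                  paste(unique(ev$patient_id[is.na(joined$admission)]), collapse = ", ")))
  }
  out <- joined$timestamp < joined$admission | joined$timestamp > joined$discharge
  if (any(out)) {
    abort(sprintf("%s outside the admission-discharge interval for patient(s): %s",
                  what, paste(unique(joined$patient_id[out]), collapse = ", ")))
  }
  ev
}

#' Label observation sets as event, non-event, or neutralized
#'
#' Assigns every in-hospital observation set exactly one label relative to
#' the patient's merged clinical events and episodes:
#'
#' * **event** -- the set falls within `event_window` (12 h) before the
#'   nearest upcoming outcome event (half-open: `[t - 12h, t)`). An event
#'   window anchored on a Type 1--3 event overrides any neutralization from
#'   an earlier event; a window anchored on a Type 4 event applies only when
#'   the set is not already neutralized by an earlier event in the same
#'   episode.
#' * **neutralized** -- after a Type 1--3 event (through discharge); after a
#'   Type 4 event until the end of its episode; within the
#'   `[t - 24h, t - 12h)` pre-band of any event; or within 12 h before an
#'   event type excluded from `event_types` (treatment proximity without an
#'   analyzable outcome).
#' * **non_event** -- otherwise (more than `neutral_window` before any
#'   event, or no upcoming event).
#'
#' @param observations Data frame with `patient_id` and `timestamp`
#'   (POSIXct); observations outside the hospitalization are an error.
#' @param events Merged events from [merge_events()].
#' @param patients Data frame with `patient_id`, `admission`, `discharge`.
#' @param windows A [window_config()].
#' @param event_types Integer subset of 1:4 defining which event types count
#'   as outcomes (all events `1:4`, or life-threatening events `1:3`; other
#'   types still neutralize).
#' @return `observations` with `episode`, `label` and `anchor_event_id`
#'   columns appended (anchor given for event-labeled sets).
#' @export
label_observations <- function(observations, events, patients,
                               windows = window_config(), event_types = 1:4) {
  assert_columns(observations, c("patient_id", "timestamp"), "observations")
  obs <- .check_events_in_stay(observations, patients, what = "observations")
  ev <- .check_events_in_stay(events, patients)
  episodes <- build_episodes(patients, ev, windows)

  ew <- .hours(windows$event_window)
  nw <- .hours(windows$neutral_window)

  split2 <- episodes |>
    dplyr::filter(.data$episode == 2L) |>
    dplyr::select("patient_id", split_at = "start")
  pat <- patients |>
    dplyr::select("patient_id", "admission", "discharge") |>
    dplyr::left_join(split2, by = "patient_id")

  ev_by_patient <- split(ev, ev$patient_id)
  obs$..row <- seq_len(nrow(obs))
  res <- obs |>
    dplyr::left_join(pat, by = "patient_id") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(g, key) {
      e <- ev_by_patient[[as.character(key$patient_id)]]
      t <- as.numeric(g$timestamp)
      split_at <- as.numeric(g$split_at[1])
      g$episode <- if (is.na(split_at)) 1L else ifelse(t < split_at, 1L, 2L)
      if (is.null(e) || nrow(e) == 0L) {
        g$label <- "non_event"
        g$anchor_event_id <- NA_character_
        return(g)
      }
      lab <- .classify_times(
        t, as.numeric(e$timestamp), e$event_type, e$event_id,
        split_at, as.numeric(g$discharge[1]), ew, nw, event_types
      )
      g$label <- lab$label
      g$anchor_event_id <- lab$anchor
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$..row) |>
    dplyr::select(-"..row", -"admission", -"discharge", -"split_at")
  res
}

# core labeling rules on numeric times for one patient; events sorted
#' @noRd
.classify_times <- function(t, ev_t, ev_type, ev_id, split_at, discharge,
                            ew, nw, event_types) {
  n <- length(t)
  post13 <- post4 <- pre_neutral <- nonout_win <- rep(FALSE, n)
  for (j in seq_along(ev_t)) {
    te <- ev_t[j]
    if (ev_type[j] <= 3L) {
      post13 <- post13 | (t >= te)
    } else {
      ep_end <- if (!is.na(split_at) && te < split_at) split_at else discharge
      post4 <- post4 | (t >= te & (t < ep_end | ep_end == discharge))
    }
    pre_neutral <- pre_neutral | (t >= te - nw & t < te - ew)
    if (!(ev_type[j] %in% event_types)) {
      nonout_win <- nonout_win | (t >= te - ew & t < te)
    }
  }
  in_win <- rep(FALSE, n)
  anchor <- rep(NA_character_, n)
  anchor_is13 <- rep(FALSE, n)
  for (j in rev(which(ev_type %in% event_types))) {
    w <- t >= ev_t[j] - ew & t < ev_t[j]
    in_win[w] <- TRUE
    anchor[w] <- ev_id[j]
    anchor_is13[w] <- ev_type[j] <= 3L
  }
  is_event <- in_win & (anchor_is13 | !(post13 | post4))
  label <- dplyr::case_when(
    is_event ~ "event",
    post13 | post4 | pre_neutral | nonout_win ~ "neutralized",
    .default = "non_event"
  )
  anchor[label != "event"] <- NA_character_
  list(label = label, anchor = anchor)
}

#' Patient-day denominators for burden metrics
#'
#' Computes, per patient, the length of stay in days and the *analyzed* time:
#' the stay minus the union of neutralized intervals (after a Type 1--3
#' event through discharge; after a Type 4 event until the end of its
#' episode; each event's `[t - 24h, t - 12h)` pre-band; and the full 12-h
#' pre-window of event types excluded from `event_types`). Event windows of
#' outcome events count as analyzed time, mirroring how observation sets are
#' retained.
#'
#' @inheritParams label_observations
#' @return Tibble with `patient_id`, `stay_days`, `analyzed_days`.
#' @export
patient_days <- function(patients, events, windows = window_config(),
                         event_types = 1:4) {
  ev <- .check_events_in_stay(events, patients)
  episodes <- build_episodes(patients, ev, windows)
  ew <- .hours(windows$event_window)
  nw <- .hours(windows$neutral_window)
  split2 <- episodes |>
    dplyr::filter(.data$episode == 2L) |>
    dplyr::select("patient_id", split_at = "start")
  ev_by_patient <- split(ev, ev$patient_id)

  pat <- dplyr::left_join(patients, split2, by = "patient_id")
  purrr::pmap_dfr(
    list(pat$patient_id, as.numeric(pat$admission), as.numeric(pat$discharge),
         as.numeric(pat$split_at)),
    function(pid, adm, dis, split_at) {
      stay <- (dis - adm) / 86400
      e <- ev_by_patient[[as.character(pid)]]
      if (is.null(e) || nrow(e) == 0L) {
        return(tibble(patient_id = pid, stay_days = stay, analyzed_days = stay))
      }
      te <- as.numeric(e$timestamp)
      ty <- e$event_type
      starts <- c(
        te[ty <= 3L],                                 # post Type 1-3
        te[ty == 4L],                                 # post Type 4
        te - nw,                                      # pre-band, any event
        te[!(ty %in% event_types)] - ew               # non-outcome windows
      )
      ends <- c(
        rep(dis, sum(ty <= 3L)),
        vapply(te[ty == 4L], function(x) {
          if (!is.na(split_at) && x < split_at) split_at else dis
        }, numeric(1)),
        te - ew,
        te[!(ty %in% event_types)]
      )
      neut <- interval_union_length(pmax(starts, adm), pmin(ends, dis)) / 86400
      tibble(patient_id = pid, stay_days = stay, analyzed_days = stay - neut)
    }
  )
}
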