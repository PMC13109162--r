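base_t <- as.POSIXct("2022-10-01 00:00:00", tz = "UTC")
at <- function(h) base_t + h * 3600
one_patient <- function(dis_h = 300) {
  tibble::tibble(patient_id = "p1", admission = at(0), discharge = at(dis_h))
}
ev <- function(h, type) {
  tibble::tibble(patient_id = "p1", timestamp = at(h), event_type = as.integer(type))
}

test_that("a Type 1-3 event absorbs a Type 4 event within 12 h, not beyond", {
  m <- merge_events(ev(c(50, 58), c(4, 2)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$event_type, 2L)
  expect_equal(m$timestamp, at(58))  # merged unit keeps the Type 1-3 time
  expect_equal(m$absorbed, 1L)

  m2 <- merge_events(ev(c(50, 70), c(4, 2)))
  expect_equal(nrow(m2), 2L)                      # two distinct events
  expect_equal(merge_events(ev(10, 4))$event_type, 4L)  # nothing to merge
})

test_that("only one Type 1-3 event per patient is retained, with a warning", {
  expect_warning(m <- merge_events(ev(c(30, 60, 80), c(2, 3, 4))), "dropped")
  expect_equal(nrow(m), 1L)
  expect_equal(m$timestamp, at(30))
})

test_that("simultaneous events keep the most severe type", {
  m <- merge_events(ev(c(40, 40), c(4, 1)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$event_type, 1L)
})

test_that("unsorted events are rejected", {
  bad <- ev(c(60, 20), c(4, 4))
  expect_error(merge_events(bad), "sorted")
})

test_that("episode construction follows the 72-h rule", {
  # two early Type 4 events: second episode starts 72 h after the last
  eps <- build_episodes(one_patient(300), ev(c(10, 40), c(4, 4)))
  expect_equal(eps$episode, c(1L, 2L))
  expect_equal(eps$start[2], at(112))
  expect_equal(eps$end[2], at(300))
  # no events: whole stay is one episode
  eps0 <- build_episodes(one_patient(200), ev(numeric(0), integer(0)))
  expect_equal(nrow(eps0), 1L)
  expect_equal(as.numeric(eps0$end - eps0$start, units = "hours"), 200)
  # no room for a second episode: 40 + 72 > 100
  eps1 <- build_episodes(one_patient(100), ev(40, 4))
  expect_equal(nrow(eps1), 1L)
  # a Type 4 inside the extended first episode extends it again
  eps2 <- build_episodes(one_patient(400), ev(c(10, 75), c(4, 4)))
  expect_equal(eps2$start[2], at(147))
  # ...but one after the first episode's end belongs to episode 2
  eps3 <- build_episodes(one_patient(400), ev(c(10, 100), c(4, 4)))
  expect_equal(eps3$start[2], at(82))
  # events outside the stay are an error
  expect_error(build_episodes(one_patient(100), ev(150, 4)), "outside")
})

test_that("observation labels follow the 12/24-h windows", {
  obs <- tibble::tibble(patient_id = "p1", timestamp = at(c(70, 85, 88, 92, 99.9, 100, 105)))
  lab <- label_observations(obs, merge_events(ev(100, 2)), one_patient(300))
  expect_equal(lab$label,
               c("non_event",    # > 24 h before
                 "neutralized",  # 24-12 h band
                 "event",        # exactly t - 12 h (half-open on the left class)
                 "event", "event",
                 "neutralized",  # at the event instant: post-event
                 "neutralized")) # after a Type 1-3 event
})

test_that("labeling invariants: partition, no-event identity, translation", {
  withr::with_seed(11, ds <- build_label_dataset(40))
  merged <- suppressWarnings(merge_events(ds$events))
  lab <- label_observations(ds$observations, merged, ds$patients)
  expect_equal(nrow(lab), nrow(ds$observations))           # exactly one label each
  expect_true(all(lab$label %in% c("event", "non_event", "neutralized")))

  no_ev <- label_observations(ds$observations, merged[0, ], ds$patients)
  expect_true(all(no_ev$label == "non_event"))

  shift <- 37 * 3600
  lab2 <- label_observations(
    dplyr::mutate(ds$observations, timestamp = timestamp + shift),
    dplyr::mutate(merged, timestamp = timestamp + shift),
    dplyr::mutate(ds$patients, admission = admission + shift,
                  discharge = discharge + shift)
  )
  expect_equal(lab2$label, lab$label)
  expect_equal(lab2$episode, lab$episode)
})

test_that("pipeline labels match the exhaustive interval oracle", {
  withr::with_seed(4242, {
    ds <- build_label_dataset(150)
    expect_equal(count_label_mismatches(ds, event_types = 1:4), 0L)
    expect_equal(count_label_mismatches(ds, event_types = 1:3), 0L)
  })
})

test_that("observations outside the hospitalization are an error", {
  obs <- tibble::tibble(patient_id = "p1", timestamp = at(350))
  expect_error(label_observations(obs, ev(10, 4), one_patient(300)), "outside")
})

test_that("analyzed patient-days subtract neutralized time", {
  pat <- one_patient(300)  # 12.5 days
  # Type 4 at 50 h: neutralized 26-38 h (pre-band) and 50-122 h (to episode break)
  pd <- patient_days(pat, merge_events(ev(50, 4)))
  expect_equal(pd$stay_days, 12.5)
  expect_equal(pd$analyzed_days, (300 - 72 - 12) / 24)
  # no events: everything analyzed
  pd0 <- patient_days(pat, ev(numeric(0), integer(0)))
  expect_equal(pd0$analyzed_days, 12.5)
  # Type 1-3 at 100 h neutralizes through discharge plus its 76-88 h pre-band
  pd13 <- patient_days(pat, merge_events(ev(100, 2)))
  expect_equal(pd13$analyzed_days, (100 - 12) / 24)
  # in the life-threatening analysis a Type 4 window itself is neutralized
  pd4 <- patient_days(pat, merge_events(ev(50, 4)), event_types = 1:3)
  expect_equal(pd4$analyzed_days, (300 - 72 - 12 - 12) / 24)
})
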