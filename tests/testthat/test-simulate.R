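test_that("cohort generation is reproducible under a fixed seed", {
  spec <- cohort_spec(n_patients = 30)
  a <- generate_cohort(spec, seed = 5)
  b <- generate_cohort(spec, seed = 5)
  expect_identical(a, b)
  c <- generate_cohort(spec, seed = 6)
  expect_false(identical(a$observations, c$observations))
})

test_that("generated tables respect hospitalization bounds and schemas", {
  co <- generate_cohort(cohort_spec(n_patients = 50), seed = 2)
  expect_true(all(co$patients$admission < co$patients$discharge))
  j <- dplyr::left_join(co$events, co$patients, by = "patient_id")
  expect_true(all(j$timestamp >= j$admission & j$timestamp <= j$discharge))
  jo <- dplyr::left_join(co$observations, co$patients, by = "patient_id")
  expect_true(all(jo$timestamp >= jo$admission & jo$timestamp <= jo$discharge))
  expect_true(all(co$events$event_type %in% 1:4))
  expect_true(all(co$observations$spo2 >= 0 & co$observations$spo2 <= 100, na.rm = TRUE))
  expect_true(all(co$observations$pain %in% 0:10 | is.na(co$observations$pain)))
  # pain missingness is elevated outside center 1
  miss_by_center <- co$observations |>
    dplyr::left_join(co$patients[, c("patient_id", "center")], by = "patient_id") |>
    dplyr::group_by(center = .data$center == 1) |>
    dplyr::summarise(p = mean(is.na(pain)))
  expect_gt(miss_by_center$p[!miss_by_center$center],
            miss_by_center$p[miss_by_center$center])
})

test_that("length of stay matches the median/IQR targets within 10% at n = 5000", {
  pats <- generate_patients(cohort_spec(n_patients = 5000), seed = 17)
  los <- as.numeric(pats$discharge - pats$admission, units = "days")
  q <- unname(stats::quantile(los, c(0.25, 0.5, 0.75)))
  expect_lt(abs(q[2] - 11) / 11, 0.10)
  targets <- c(7.51, 16.10)  # lognormal(log 11, 0.565) quartiles
  expect_lt(abs(q[1] - targets[1]) / targets[1], 0.10)
  expect_lt(abs(q[3] - targets[2]) / targets[2], 0.10)
})

test_that("life-threatening event counts are Poisson with rate x patient-days", {
  spec <- cohort_spec(n_patients = 150)
  pats <- generate_patients(spec, seed = 23)
  lambda <- spec$type13_rate *
    sum(as.numeric(pats$discharge - pats$admission, units = "days"))
  counts <- vapply(seq_len(500), function(s) {
    ev <- generate_events(spec, pats, seed = 1000 + s)
    sum(ev$event_type <= 3)
  }, numeric(1))
  # chi-square goodness of fit against Poisson(lambda), pooled tails
  breaks <- unique(stats::qpois(c(0.05, 0.25, 0.5, 0.75, 0.95), lambda))
  bins <- cut(counts, breaks = c(-Inf, breaks, Inf))
  probs <- diff(c(0, stats::ppois(breaks, lambda), 1))
  gof <- suppressWarnings(stats::chisq.test(table(bins), p = probs))
  expect_gt(gof$p.value, 0.01)
  # and the mean count is the rate arithmetic
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.1)
})

test_that("deterioration ramps only precede events", {
  # with no events the 'none' and 'gews' profiles generate identical vitals
  spec0 <- cohort_spec(n_patients = 20, type13_rate = 0, type4_mean = 0)
  co <- generate_cohort(spec0, seed = 9)
  expect_equal(nrow(co$events), 0L)
  spec_none <- cohort_spec(n_patients = 20, type13_rate = 0, type4_mean = 0,
                           profile = "none")
  co_none <- generate_cohort(spec_none, seed = 9)
  expect_identical(co$observations, co_none$observations)
})

test_that("the worked fixture matches its shipped expectations end to end", {
  fx <- generate_worked_fixture()
  merged <- merge_events(fx$events)
  expect_equal(build_episodes(fx$patients, merged)[, c("patient_id", "episode", "start", "end")],
               fx$expected_episodes)
  lab <- label_observations(fx$observations, merged, fx$patients)
  expect_equal(lab$label, fx$expected_labels$label)
  expect_equal(lab$episode, fx$expected_labels$episode)
  # the all-zero-band patient scores 0 on GEWS
  f1 <- fx$observations[fx$observations$patient_id == "F1", ][1, ]
  expect_equal(score_observations(f1, "gews")$total, 0L)
  # imputation fixture: F4 exercises zero, carry and long-gap conditions
  s <- score_observations(fx$observations, "gews", missing = "keep")
  imp <- impute_scores(s, "gews")
  f4 <- imp[imp$patient_id == "F4", ]
  expect_equal(f4$resp_rate_prov, c("imputed_zero", "measured", "carried_forward", "measured"))
  expect_equal(f4$spo2_prov, c("imputed_zero", "measured", "carried_forward", "imputed_zero"))
  expect_equal(f4$resp_rate_score, c(0L, 0L, 0L, 0L))
  expect_equal(f4$spo2_score, c(0L, 0L, 0L, 0L))
})
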