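base_t <- as.POSIXct("2022-10-01 00:00:00", tz = "UTC")
scored_seq <- function(hours, rr = NULL, label = NULL) {
  n <- length(hours)
  obs <- zero_band_obs(n)
  obs$patient_id <- "p1"
  obs$timestamp <- base_t + hours * 3600
  if (!is.null(rr)) obs$resp_rate <- rr
  s <- score_observations(obs, "gews", missing = "keep")
  if (!is.null(label)) s$label <- label
  s
}

test_that("the four zero conditions and carry-forward behave as specified", {
  # (a) first observation: missing -> 0
  s <- impute_scores(scored_seq(0, rr = NA), "gews")
  expect_equal(s$resp_rate_score, 0L)
  expect_equal(s$resp_rate_prov, "imputed_zero")

  # carry within 6 h: RR scored 2 (rate 25) then missing -> carried 2
  s <- impute_scores(scored_seq(c(0, 6), rr = c(25, NA)), "gews")
  expect_equal(s$resp_rate_score, c(2L, 2L))
  expect_equal(s$resp_rate_prov, c("measured", "carried_forward"))

  # (c) a 14-h gap since the previous set -> 0, not carried
  s <- impute_scores(scored_seq(c(0, 14), rr = c(25, NA)), "gews")
  expect_equal(s$resp_rate_score, c(2L, 0L))
  expect_equal(s$resp_rate_prov[2], "imputed_zero")

  # (b) no prior value of the parameter documented -> 0 even within 12 h
  s <- impute_scores(scored_seq(c(0, 6), rr = c(NA, NA)), "gews")
  expect_equal(s$resp_rate_score, c(0L, 0L))

  # (d) neutralized sets are imputed as 0
  s <- impute_scores(scored_seq(c(0, 6), rr = c(25, NA),
                                label = c("non_event", "neutralized")), "gews")
  expect_equal(s$resp_rate_score[2], 0L)
  expect_equal(s$resp_rate_prov[2], "imputed_zero")

  # identity on complete data
  full <- scored_seq(c(0, 6, 12), rr = c(16, 25, 30))
  s <- impute_scores(full, "gews")
  expect_equal(s$resp_rate_score, full$resp_rate_score)
  expect_equal(s$total, full$total)
})

test_that("carry-forward never reaches across a gap longer than 12 h", {
  # measured at 0 h, a 20-h gap zeroes the 20-h set, and the 26-h set carries
  # that zero rather than the 26-h-old measurement
  s <- impute_scores(scored_seq(c(0, 20, 26), rr = c(25, NA, NA)), "gews")
  expect_equal(s$resp_rate_score, c(2L, 0L, 0L))
  expect_equal(s$resp_rate_prov, c("measured", "imputed_zero", "carried_forward"))
})

test_that("imputed output is complete and every value is 0 or an earlier measurement", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(3:15, 1)
      hours <- cumsum(c(0, runif(n - 1, 1, 20)))
      obs <- random_obs(n)
      obs$patient_id <- "p1"
      obs$timestamp <- base_t + hours * 3600
      for (nm in c("resp_rate", "spo2", "pain", "consciousness")) {
        obs[[nm]][runif(n) < 0.4] <- NA
      }
      scored <- score_observations(obs, "gews", missing = "keep")
      imp <- impute_scores(scored, "gews")
      cols <- paste0(names(ews_band_table("gews")$parameters), "_score")
      expect_false(anyNA(imp[cols]))
      expect_false(anyNA(imp$total))
      for (cc in cols) {
        for (i in seq_len(n)) {
          prov <- imp[[sub("_score", "_prov", cc)]][i]
          if (prov %in% c("imputed_zero")) next
          if (prov == "carried_forward") {
            earlier_measured <- scored[[cc]][seq_len(i - 1)]
            expect_true(imp[[cc]][i] == 0L ||
                          imp[[cc]][i] %in% earlier_measured[!is.na(earlier_measured)])
          }
        }
      }
      # imputing twice changes nothing (idempotence)
      expect_identical(impute_scores(imp, "gews")[cols], imp[cols])
    }
  })
})

test_that("imputation respects patient boundaries and rejects unsorted input", {
  s1 <- scored_seq(c(0, 6), rr = c(25, NA))
  s2 <- scored_seq(c(100, 106), rr = c(NA, NA))
  s2$patient_id <- "p2"
  both <- dplyr::bind_rows(s1, s2)
  imp <- impute_scores(both, "gews")
  # p2's first set must not inherit p1's measurement
  expect_equal(imp$resp_rate_score[3:4], c(0L, 0L))

  bad <- dplyr::arrange(s1, dplyr::desc(timestamp))
  expect_error(impute_scores(bad, "gews"), "sorted")
})

test_that("the parameter-specific gap basis zeroes stale parameter chains", {
  # sets 0, 8, 16 h apart pairwise <= 12 h, but RR only measured at 0 h:
  # under the parameter basis the 16-h set is > 12 h from the last RR value
  s <- scored_seq(c(0, 8, 16), rr = c(25, NA, NA))
  set_based <- impute_scores(s, "gews", gap_basis = "observation_set")
  par_based <- impute_scores(s, "gews", gap_basis = "parameter")
  expect_equal(set_based$resp_rate_score, c(2L, 2L, 2L))
  expect_equal(par_based$resp_rate_score, c(2L, 2L, 0L))
})
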