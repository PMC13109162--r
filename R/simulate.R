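#' Synthetic geriatric-ward cohort specification
#'
#' Parameters of the seedable cohort generator that emulates the statistical
#' structure the validation analysis assumes: ~511 frail older patients with
#' a log-normal length of stay (median 11 d, quartiles near 7--15 d),
#' life-threatening (Type 1--3) events as a Poisson process at 0.005 per
#' patient-day, frequent Type 4 events concentrated near admission (~0.6 per
#' patient with an exponentially declining hazard), emergency-department
#' observations plus two jittered ward shifts per day, a linear 12-h
#' pre-event deterioration ramp in selected vital parameters, and
#' per-parameter missingness with pain recording notably worse in two of
#' the three simulated centers.
#'
#' Deterioration profiles choose which parameters the ramp shifts:
#' `"gews"` shifts parameters into bands the GEWS scores but the NEWS
#' largely does not (heart rate toward ~100, temperature toward ~37.9,
#' systolic pressure toward ~105, pain toward 8, agitation); `"news"` does
#' the converse (desaturation toward ~91%, respiration toward ~23,
#' consciousness toward voice-responsive); `"symmetric"` applies half of
#' each; `"none"` removes the signal entirely (chance discrimination).
#' `effect_size` scales all shifts (0 = no signal).
#'
#' @param n_patients Cohort size (default 511).
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters
#'   (defaults `log(11)` and 0.565, splitting the asymmetric 7--15 d
#'   interquartile target on the log scale).
#' @param type13_rate Type 1--3 events per patient-day (default 0.005).
#' @param type4_mean Expected Type 4 events per patient (default 0.6).
#' @param type4_decay_hours Mean of the exponential event-time distribution
#'   after admission for Type 4 events (default 24 h).
#' @param shift_times Ward observation hours of day (default 08:00, 16:00).
#' @param jitter_sd_minutes SD of the shift-time jitter (default 30).
#' @param profile Deterioration profile, see Details.
#' @param effect_size Multiplier on all deterioration shifts (default 1).
#' @param missingness Named per-parameter missingness probabilities.
#' @param pain_missing_high Pain missingness in centers 2 and 3 (default 0.4).
#' @param n_centers Number of simulated centers (default 3).
#' @param start_date Accrual start (POSIXct).
#' @param accrual_days Admissions are spread uniformly over this many days.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return A list of class `ews_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 511L,
                        los_meanlog = log(11), los_sdlog = 0.565,
                        type13_rate = 0.005,
                        type4_mean = 0.6, type4_decay_hours = 24,
                        shift_times = c(8, 16), jitter_sd_minutes = 30,
                        profile = c("gews", "news", "symmetric", "none"),
                        effect_size = 1,
                        missingness = c(resp_rate = 0.10, spo2 = 0.04,
                                        o2_flow = 0.04, temp = 0.05,
                                        sbp = 0.04, hr = 0.03,
                                        consciousness = 0.08, pain = 0.10),
                        pain_missing_high = 0.4,
                        n_centers = 3L,
                        start_date = as.POSIXct("2022-09-01", tz = "UTC"),
                        accrual_days = 180,
                        seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(
    n_patients >= 1, los_sdlog > 0, type13_rate >= 0, type4_mean >= 0,
    type4_decay_hours > 0, all(missingness >= 0 & missingness <= 1),
    pain_missing_high >= 0 && pain_missing_high <= 1, effect_size >= 0
  )
  if (length(shift_times) < 1) abort("at least one ward shift per day is required")
  structure(
    list(n_patients = as.integer(n_patients),
         los_meanlog = los_meanlog, los_sdlog = los_sdlog,
         type13_rate = type13_rate, type4_mean = type4_mean,
         type4_decay_hours = type4_decay_hours,
         shift_times = shift_times, jitter_sd_minutes = jitter_sd_minutes,
         profile = profile, effect_size = effect_size,
         missingness = missingness, pain_missing_high = pain_missing_high,
         n_centers = as.integer(n_centers),
         start_date = start_date, accrual_days = accrual_days,
         seed = as.integer(seed)),
    class = "ews_cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws patients, clinical events and vital-sign observation sets from a
#' [cohort_spec()]. Output conforms to the pipeline's three table schemas;
#' event timestamps respect hospitalization bounds; deterioration ramps only
#' precede generated events; and a fixed seed reproduces the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return List with tibbles `patients`, `observations`, `events`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 20), seed = 7)
#' nrow(cohort$patients)
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "ews_cohort_spec"))
  withr::with_seed(stream_seed(seed, "simulation"), {
    patients <- .gen_patients(spec)
    events <- .gen_events(spec, patients)
    observations <- .gen_observations(spec, patients, events)
    list(patients = patients, observations = observations, events = events)
  })
}

#' @rdname generate_cohort
#' @param patients,events Previously generated tables (for stagewise use).
#' @export
generate_patients <- function(spec, seed = spec$seed) {
  withr::with_seed(stream_seed(seed, "simulation"), .gen_patients(spec))
}

#' @rdname generate_cohort
#' @export
generate_events <- function(spec, patients, seed = spec$seed) {
  withr::with_seed(stream_seed(seed, "simulation") + 1L, .gen_events(spec, patients))
}

#' @rdname generate_cohort
#' @export
generate_observations <- function(spec, patients, events, seed = spec$seed) {
  withr::with_seed(stream_seed(seed, "simulation") + 2L,
                   .gen_observations(spec, patients, events))
}

#' @noRd
.gen_patients <- function(spec) {
  n <- spec$n_patients
  los_days <- pmax(stats::rlnorm(n, spec$los_meanlog, spec$los_sdlog), 1)
  admission <- spec$start_date +
    round(stats::runif(n, 0, spec$accrual_days * 86400) / 60) * 60
  ward_admission <- admission + round(stats::runif(n, 3, 8) * 60) * 60
  discharge <- admission + round(los_days * 86400 / 60) * 60
  cfs_probs <- c(`3` = 9, `4` = 9, `5` = 9, `6` = 31, `7` = 10, `8` = 10, `9` = 10)
  tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    center = sample.int(spec$n_centers, n, replace = TRUE),
    admission = admission,
    ward_admission = ward_admission,
    discharge = discharge,
    age = round(pmin(pmax(stats::rnorm(n, 85, 5), 65), 105)),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.60, 0.40)),
    cfs = as.integer(sample(names(cfs_probs), n, replace = TRUE,
                            prob = cfs_probs / sum(cfs_probs))),
    dnr = sample(0:2, n, replace = TRUE, prob = c(0.45, 0.17, 0.38)),
    delirium_flag = stats::runif(n) < 0.082
  )
}

#' @noRd
.gen_events <- function(spec, patients) {
  n <- nrow(patients)
  los_days <- as.numeric(patients$discharge - patients$admission, units = "days")

  # Type 1-3: homogeneous Poisson over the stay
  n13 <- stats::rpois(n, spec$type13_rate * los_days)
  ev13 <- purrr::map_dfr(which(n13 > 0L), function(i) {
    k <- n13[i]
    t <- patients$admission[i] +
      round(stats::runif(k, 3600, los_days[i] * 86400))
    tibble(patient_id = patients$patient_id[i], timestamp = t,
           event_type = sample(1:3, k, replace = TRUE,
                               prob = c(7, 12, 12) / 31),
           detail = "life_threatening")
  })

  # Type 4: admission-proximal, exponentially declining hazard
  n4 <- stats::rpois(n, spec$type4_mean)
  ev4 <- purrr::map_dfr(which(n4 > 0L), function(i) {
    k <- n4[i]
    span <- los_days[i] * 86400
    tau <- spec$type4_decay_hours * 3600
    u <- stats::runif(k)
    dt <- -tau * log(1 - u * (1 - exp(-span / tau)))  # truncated exponential
    tibble(patient_id = patients$patient_id[i],
           timestamp = patients$admission[i] + round(pmax(dt, 600)),
           event_type = 4L,
           detail = sample(c("medical", "surgical"), k, replace = TRUE,
                           prob = c(0.97, 0.03)))
  })

  ev <- dplyr::bind_rows(ev13, ev4)
  if (nrow(ev) == 0L) {
    return(tibble(patient_id = character(), timestamp = patients$admission[0],
                  event_type = integer(), detail = character(),
                  event_id = character()))
  }
  ev <- dplyr::arrange(ev, .data$patient_id, .data$timestamp)
  ev$event_id <- sprintf("E%05d", seq_len(nrow(ev)))
  ev
}

# deterioration shift per unit ramp weight, by profile
#' @noRd
.profile_shifts <- function(profile) {
  gews <- list(hr = 32, temp = 1.3, sbp = -32, pain = 8, agitated = 0.35,
               spo2 = 0, resp_rate = 0, voice = 0)
  news <- list(hr = 0, temp = 0, sbp = 0, pain = 0, agitated = 0,
               spo2 = -5, resp_rate = 7, voice = 0.35)
  switch(profile,
    gews = gews,
    news = news,
    symmetric = purrr::map2(gews, news, function(a, b) (a + b) / 2),
    none = purrr::map(gews, function(x) 0)
  )
}

#' @noRd
.gen_observations <- function(spec, patients, events) {
  n <- nrow(patients)
  jitter_sd <- spec$jitter_sd_minutes * 60

  times_list <- purrr::map(seq_len(n), function(i) {
    adm <- as.numeric(patients$admission[i])
    ward <- as.numeric(patients$ward_admission[i])
    dis <- as.numeric(patients$discharge[i])
    day0 <- as.numeric(trunc(patients$admission[i], "days"))
    ndays <- ceiling((dis - day0) / 86400)
    shifts <- rep(day0 + 86400 * (seq_len(ndays) - 1L), each = length(spec$shift_times)) +
      rep(spec$shift_times * 3600, times = ndays)
    shifts <- shifts + stats::rnorm(length(shifts), 0, jitter_sd)
    shifts <- shifts[shifts > ward + 3600 & shifts < dis]
    sort(round(c(adm, adm + 7200, ward, shifts) / 60) * 60)
  })
  n_obs <- lengths(times_list)
  pid <- rep(patients$patient_id, n_obs)
  center <- rep(patients$center, n_obs)
  t <- unlist(times_list, use.names = FALSE)
  N <- length(t)

  # per-patient baselines centered in each score's 0-bands
  base <- tibble(
    rr = stats::rnorm(n, 16, 1.5),
    spo2 = pmin(stats::rnorm(n, 96.5, 1), 99.5),
    o2 = ifelse(stats::runif(n) < 0.10, sample(1:2, n, replace = TRUE), 0),
    temp = stats::rnorm(n, 36.6, 0.2),
    sbp = stats::rnorm(n, 138, 12),
    hr = stats::rnorm(n, 68, 5),
    pain = ifelse(stats::runif(n) < 0.30, 1, 0)
  )
  rows <- rep(seq_len(n), n_obs)

  ar1 <- function(sd, phi = 0.5) {
    innov <- stats::rnorm(N, 0, sd * sqrt(1 - phi^2))
    unlist(lapply(split(innov, rows), function(x)
      as.numeric(stats::filter(x, phi, method = "recursive"))), use.names = FALSE)
  }

  rr <- base$rr[rows] + ar1(1.5)
  spo2 <- base$spo2[rows] + ar1(1.2)
  o2 <- base$o2[rows]
  temp <- base$temp[rows] + ar1(0.25)
  sbp <- base$sbp[rows] + ar1(10)
  hr <- base$hr[rows] + ar1(6)
  pain <- base$pain[rows] + ar1(0.7)
  consciousness <- rep("alert", N)
  consciousness[stats::runif(N) < 0.03] <- "voice"

  # linear 12-h pre-event ramp; overlapping event ramps take the max weight
  w <- numeric(N)
  if (nrow(events) > 0L) {
    ev_by_patient <- split(as.numeric(events$timestamp), events$patient_id)
    offset <- c(0L, cumsum(n_obs))
    for (i in seq_len(n)) {
      te <- ev_by_patient[[patients$patient_id[i]]]
      if (is.null(te)) next
      idx <- (offset[i] + 1L):(offset[i] + n_obs[i])
      ti <- t[idx]
      for (e in te) {
        d <- e - ti
        wi <- ifelse(d > 0 & d <= 12 * 3600, 1 - d / (12 * 3600), 0)
        w[idx] <- pmax(w[idx], wi)
      }
    }
  }
  sh <- .profile_shifts(spec$profile)
  eff <- spec$effect_size
  rr <- rr + w * eff * sh$resp_rate
  spo2 <- spo2 + w * eff * sh$spo2
  temp <- temp + w * eff * sh$temp
  sbp <- sbp + w * eff * sh$sbp
  hr <- hr + w * eff * sh$hr
  pain <- pain + w * eff * sh$pain
  agit <- stats::runif(N) < pmin(w * eff * sh$agitated, 1)
  voic <- stats::runif(N) < pmin(w * eff * sh$voice, 1)
  consciousness[voic] <- "voice"
  consciousness[agit] <- "agitated"

  obs <- tibble(
    patient_id = pid,
    timestamp = as.POSIXct(t, origin = "1970-01-01",
                           tz = attr(patients$admission, "tzone") %||% "UTC"),
    resp_rate = round(pmin(pmax(rr, 5), 60)),
    spo2 = round(pmin(pmax(spo2, 70), 100)),
    o2_flow = o2,
    temp = round(pmin(pmax(temp, 32), 42), 1),
    temp_site = sample(c("tympanic", "axilla", "temporal", "forehead"),
                       N, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1)),
    sbp = round(pmin(pmax(sbp, 55), 280)),
    hr = round(pmin(pmax(hr, 30), 220)),
    consciousness = consciousness,
    pain = round(pmin(pmax(pain, 0), 10))
  )

  # per-parameter missingness (completely at random); pain recording is
  # markedly worse outside center 1
  miss <- spec$missingness
  for (nm in c("resp_rate", "spo2", "o2_flow", "temp", "sbp", "hr", "consciousness")) {
    obs[[nm]][stats::runif(N) < miss[[nm]]] <- NA
  }
  p_pain <- ifelse(center == 1L, miss[["pain"]], spec$pain_missing_high)
  obs$pain[stats::runif(N) < p_pain] <- NA
  obs$temp_site[is.na(obs$temp)] <- NA

  obs
}
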