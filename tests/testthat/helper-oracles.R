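# Independent brute-force oracles used to check the package's vectorized
# implementations. These are deliberately naive (scalar loops, exhaustive
# enumeration) and share no code with the implementation.

# AUROC as exhaustive pairwise concordance with half credit for ties
oracle_auroc <- function(score, event) {
  e <- score[event]
  n <- score[!event]
  tot <- 0
  for (x in e) for (y in n) tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(e) * length(n))
}

# average precision by explicit threshold enumeration
oracle_ap <- function(score, event) {
  thr <- sort(unique(score), decreasing = TRUE)
  n1 <- sum(event)
  ap <- 0
  prev_recall <- 0
  for (th in thr) {
    alert <- score >= th
    recall <- sum(alert & event) / n1
    precision <- sum(alert & event) / sum(alert)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# exhaustive interval-membership labeler for one patient: times in hours,
# ev = data.frame(t, type) sorted by t; returns list(label, episode)
oracle_label_patient <- function(obs_h, ev, adm, dis, event_types = 1:4,
                                 ew = 12, nw = 24, gap = 72, mw = 12) {
  # de-duplicate simultaneous events, most severe first
  if (nrow(ev) > 0) {
    keep <- rep(TRUE, nrow(ev))
    for (tt in unique(ev$t[duplicated(ev$t)])) {
      idx <- which(ev$t == tt)
      sev <- ifelse(ev$type[idx] <= 3, 0, 1)
      keep[idx] <- FALSE
      keep[idx[which.min(sev)]] <- TRUE
    }
    ev <- ev[keep, , drop = FALSE]
    # one Type 1-3 event per patient
    first13 <- which(ev$type <= 3)[1]
    if (!is.na(first13)) {
      ev <- ev[seq_len(first13), , drop = FALSE]
      t13 <- ev$t[first13]
      ev <- ev[!(ev$type == 4 & ev$t >= t13 - mw & ev$t < t13), , drop = FALSE]
    }
  }
  # episode split: fixed point on "last Type 4 of the first episode"
  t4 <- ev$t[ev$type == 4]
  split <- NA_real_
  if (any(t4 < adm + gap)) {
    end1 <- adm + gap
    repeat {
      new_end <- max(t4[t4 < end1]) + gap
      if (new_end == end1) break
      end1 <- new_end
    }
    if (end1 < dis) split <- end1
  }
  ep_end_of <- function(te) if (!is.na(split) && te < split) split else dis

  label <- character(length(obs_h))
  episode <- integer(length(obs_h))
  for (i in seq_along(obs_h)) {
    t <- obs_h[i]
    episode[i] <- if (!is.na(split) && t >= split) 2L else 1L
    post13 <- post4 <- pre <- nonout <- FALSE
    for (j in seq_len(nrow(ev))) {
      te <- ev$t[j]; ty <- ev$type[j]
      if (ty <= 3 && t >= te) post13 <- TRUE
      if (ty == 4 && t >= te) {
        ee <- ep_end_of(te)
        if (t < ee || ee == dis) post4 <- TRUE
      }
      if (t >= te - nw && t < te - ew) pre <- TRUE
      if (!(ty %in% event_types) && t >= te - ew && t < te) nonout <- TRUE
    }
    # nearest upcoming outcome event whose window contains t
    anchor_type <- NA_integer_
    oe <- ev[ev$type %in% event_types, , drop = FALSE]
    for (j in order(oe$t)) {
      if (t >= oe$t[j] - ew && t < oe$t[j]) { anchor_type <- oe$type[j]; break }
    }
    label[i] <-
      if (!is.na(anchor_type) && (anchor_type <= 3 || !(post13 || post4))) "event"
      else if (post13 || post4 || pre || nonout) "neutralized"
      else "non_event"
  }
  list(label = label, episode = episode)
}

# random one-patient labeling configuration; times in integer MINUTES so
# window-boundary arithmetic is exact for both the oracle and the pipeline
random_label_config <- function() {
  dis <- round(runif(1, 100, 400) * 60)
  k <- sample(0:5, 1)
  ev <- data.frame(t = sort(round(runif(k, 60, dis))),
                   type = sample(1:4, k, replace = TRUE))
  n_obs <- sample(1:50, 1)
  obs <- sort(round(runif(n_obs, 0, dis)))
  list(dis = dis, ev = ev, obs = obs)
}

# assemble many random configs into pipeline-ready tables (one patient each)
build_label_dataset <- function(n_configs, base = as.POSIXct("2022-10-01", tz = "UTC")) {
  configs <- lapply(seq_len(n_configs), function(i) random_label_config())
  patients <- tibble::tibble(
    patient_id = sprintf("R%04d", seq_len(n_configs)),
    admission = base,
    discharge = base + vapply(configs, function(cf) cf$dis, numeric(1)) * 60
  )
  events <- purrr::imap_dfr(configs, function(cf, i) {
    if (nrow(cf$ev) == 0) return(NULL)
    tibble::tibble(patient_id = sprintf("R%04d", i),
                   timestamp = base + cf$ev$t * 60,
                   event_type = as.integer(cf$ev$type))
  })
  observations <- purrr::imap_dfr(configs, function(cf, i) {
    tibble::tibble(patient_id = sprintf("R%04d", i),
                   timestamp = base + cf$obs * 60)
  })
  list(configs = configs, patients = patients, events = events,
       observations = observations)
}

# compare pipeline labels against the oracle for every patient in a built
# dataset; returns number of mismatching observation sets
count_label_mismatches <- function(ds, event_types = 1:4) {
  merged <- suppressWarnings(merge_events(ds$events))
  got <- label_observations(ds$observations, merged, ds$patients,
                            event_types = event_types)
  base <- ds$patients$admission[1]
  mism <- 0L
  for (i in seq_len(nrow(ds$patients))) {
    pid <- ds$patients$patient_id[i]
    cf <- ds$configs[[i]]
    want <- oracle_label_patient(cf$obs, cf$ev, adm = 0, dis = cf$dis,
                                 event_types = event_types,
                                 ew = 720, nw = 1440, gap = 4320, mw = 720)
    g <- got[got$patient_id == pid, ]
    mism <- mism + sum(g$label != want$label) + sum(g$episode != want$episode)
  }
  mism
}

# quick complete observation set in every 0-band of both scores
zero_band_obs <- function(n = 1) {
  tibble::tibble(
    resp_rate = rep(16, n), spo2 = 96, o2_flow = 0, temp = 36.8,
    temp_site = "tympanic", sbp = 130, hr = 70,
    consciousness = "alert", pain = 0
  )
}

# random raw observation sets spanning each table's domains
random_obs <- function(n) {
  tibble::tibble(
    resp_rate = sample(4:45, n, replace = TRUE),
    spo2 = sample(70:100, n, replace = TRUE),
    o2_flow = sample(c(0, 0, 0, 1, 2, 4, 6), n, replace = TRUE),
    temp = round(runif(n, 34, 40.5), 1),
    temp_site = sample(c("tympanic", "axilla", "temporal", "forehead"),
                       n, replace = TRUE),
    sbp = sample(60:240, n, replace = TRUE),
    hr = sample(35:160, n, replace = TRUE),
    consciousness = sample(c("alert", "voice", "pain", "unresponsive", "agitated"),
                           n, replace = TRUE, prob = c(.8, .05, .05, .05, .05)),
    pain = sample(0:10, n, replace = TRUE)
  )
}
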