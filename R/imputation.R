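#' Two-stage imputation of missing subscores
#'
#' Completes missing per-parameter subscores in scored observation sets (as
#' produced by [score_observations()] with `missing = "keep"`), operating on
#' subscores rather than raw vital values: 0 is a valid score but not a
#' valid vital measurement.
#'
#' Stage 1 imputes a missing subscore as 0 when the observation set (a) is
#' the patient's first recorded set, (b) has no prior documented value of
#' that parameter, (c) was registered more than `max_gap` hours after the
#' previous observation set of the patient, or (d) is a neutralized set
#' (still imputed so that carry-forward chains passing through it are
#' well-defined; neutralized sets remain excluded downstream). Stage 2 fills
#' any remaining missing subscore by last observation carried forward: the
#' subscore of the patient's previous observation set after stage 1, so a
#' carried value never crosses a gap larger than `max_gap` (condition (c)
#' pre-empts it).
#'
#' With `gap_basis = "parameter"`, condition (c) is instead evaluated
#' against the time of the last *measured* value of that specific parameter
#' (the alternative literal reading, exposed for sensitivity analysis).
#'
#' @param data Scored observations: one row per set with `patient_id`,
#'   `timestamp`, `<parameter>_score` / `<parameter>_prov` columns, sorted
#'   by timestamp within patient (unsorted input is an error). A `label`
#'   column (from [label_observations()]) activates condition (d); without
#'   it no set is treated as neutralized.
#' @param table Band table (or name) defining which parameters to complete.
#' @param max_gap Hours; gaps longer than this break carry-forward (default 12).
#' @param locf Enable stage 2 (default `TRUE`); if disabled, subscores not
#'   covered by stage 1 remain missing.
#' @param gap_basis `"observation_set"` (default) or `"parameter"`.
#' @return `data` with missing subscores filled, provenance updated to
#'   `"imputed_zero"` or `"carried_forward"`, and `total` / `max_single`
#'   recomputed.
#' @export
impute_scores <- function(data, table, max_gap = 12, locf = TRUE,
                          gap_basis = c("observation_set", "parameter")) {
  gap_basis <- match.arg(gap_basis)
  if (!inherits(table, "ews_band_table")) table <- ews_band_table(table)
  params <- names(table$parameters)
  score_cols <- paste0(params, "_score")
  assert_columns(data, c("patient_id", "timestamp", score_cols), "scored observations")
  assert_sorted_within(data, "timestamp", "patient_id", "scored observations")

  out <- as_tibble(data)
  n <- nrow(out)
  if (n == 0L) return(out)

  pid <- as.character(out$patient_id)
  new_patient <- c(TRUE, pid[-1L] != pid[-n])
  group_start <- cummax(ifelse(new_patient, seq_len(n), 0L))
  t <- as.numeric(out$timestamp)
  gap_prev <- c(NA_real_, diff(t)) / 3600
  gap_prev[new_patient] <- NA_real_
  neutralized <- if ("label" %in% names(out)) out$label == "neutralized" else rep(FALSE, n)

  for (k in seq_along(params)) {
    s <- out[[score_cols[k]]]
    prov_col <- paste0(params[k], "_prov")
    prov <- if (prov_col %in% names(out)) out[[prov_col]] else
      ifelse(is.na(s), "missing", "measured")
    measured <- !is.na(s) & prov == "measured"

    meas_vals <- ifelse(measured, as.numeric(s), NA_real_)
    prev_meas_idx <- prev_value_index(meas_vals, group_start)
    never_measured <- prev_meas_idx == 0L

    if (gap_basis == "observation_set") {
      long_gap <- !is.na(gap_prev) & gap_prev > max_gap
    } else {
      long_gap <- !never_measured & (t - t[pmax(prev_meas_idx, 1L)]) / 3600 > max_gap
    }

    miss <- is.na(s)
    stage1 <- miss & (new_patient | never_measured | long_gap | neutralized)

    # anchors: measured values and stage-1 zeros; stage 2 carries the
    # previous set's completed subscore forward from the nearest anchor
    anchor <- ifelse(measured, as.numeric(s), NA_real_)
    anchor[stage1] <- 0
    carry_idx <- cummax(ifelse(is.na(anchor), 0L, seq_len(n)))
    carry_idx[carry_idx < group_start] <- 0L

    filled <- as.integer(s)
    filled[stage1] <- 0L
    prov[stage1] <- "imputed_zero"
    stage2 <- miss & !stage1
    if (locf && any(stage2)) {
      src <- carry_idx[stage2]
      stopifnot(all(src > 0L))  # row 1 of a patient is always an anchor
      filled[stage2] <- filled[src]
      prov[stage2] <- "carried_forward"
    }
    out[[score_cols[k]]] <- filled
    out[[prov_col]] <- prov
  }

  mat <- as.matrix(out[score_cols])
  out$total <- as.integer(rowSums(mat))
  out$max_single <- as.integer(apply(mat, 1L, function(r) if (anyNA(r)) NA_integer_ else max(r)))
  out
}
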