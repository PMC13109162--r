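#' Score observation sets with an early warning score
#'
#' Takes a data frame of timestamped vital-sign observation sets (one row per
#' set) and appends, for every parameter the band table scores, a subscore
#' column `<parameter>_score` and a provenance column `<parameter>_prov`,
#' plus the composite `total` and the maximum single subscore `max_single`.
#' Body temperature is site-corrected with [adjust_temperature()] before
#' banding when a `temp_site` column is present.
#'
#' Missing parameters are handled according to `missing`: with `"keep"` (the
#' default) the subscore is `NA` with provenance `"missing"`, so the
#' two-stage imputation in [impute_scores()] can decide between zero
#' imputation and last observation carried forward; `total` and `max_single`
#' are then `NA` whenever any subscore is missing. With `"zero"` a missing
#' parameter scores 0 immediately with provenance `"imputed_zero"`
#' (standalone scoring without a longitudinal context).
#'
#' @param data Data frame with one row per observation set. Must contain a
#'   column per scored parameter (`resp_rate`, `spo2`, `o2_flow`, `temp`,
#'   `sbp`, `hr`, `consciousness`, and `pain` for GEWS); `temp_site` is used
#'   when present.
#' @param table An [ews_band_table()] or a name/path accepted by it.
#' @param missing `"keep"` or `"zero"`, see Details.
#' @param strict If `TRUE`, values falling inside a printed band gap (e.g. a
#'   respiration rate of 20.5 under NEWS' printed `12--20` / `21--24` bands)
#'   raise a warning naming the parameter instead of being silently scored
#'   by the lower band.
#' @return `data` as a tibble with subscore, provenance, `total` and
#'   `max_single` columns appended.
#' @examples
#' obs <- tibble::tibble(
#'   resp_rate = 16, spo2 = 95, o2_flow = 0, temp = 36.8,
#'   temp_site = "tympanic", sbp = 130, hr = 70,
#'   consciousness = "alert", pain = 0
#' )
#' score_observations(obs, "gews")$total # 0
#' @export
score_observations <- function(data, table, missing = c("keep", "zero"),
                               strict = FALSE) {
  missing <- match.arg(missing)
  if (!inherits(table, "ews_band_table")) table <- ews_band_table(table)
  params <- names(table$parameters)
  assert_columns(data, params, "observations")
  out <- as_tibble(data)

  vals <- as.list(out[params])
  if ("temp" %in% params) {
    site <- if ("temp_site" %in% names(out)) out$temp_site else NA_character_
    vals$temp <- adjust_temperature(out$temp, site)
  }
  if (strict) {
    for (nm in params) {
      p <- table$parameters[[nm]]
      if (p$kind != "numeric") next
      v <- as.numeric(vals[[nm]])
      in_printed <- rep(FALSE, length(v))
      for (i in seq_len(nrow(p$bands))) {
        bi <- p$bands[i, ]
        bi$lo <- bi$printed_lo; bi$hi <- bi$printed_hi
        in_printed <- in_printed | (!is.na(v) & .band_contains(bi, v))
      }
      gap <- !is.na(v) & !in_printed
      if (any(gap)) {
        warn(sprintf(
          "%s/%s: %d value(s) fall in a printed band gap (e.g. %g); scored by the lower band",
          table$name, nm, sum(gap), v[which(gap)[1]]
        ))
      }
    }
  }

  score_mat <- matrix(NA_integer_, nrow = nrow(out), ncol = length(params),
                      dimnames = list(NULL, params))
  for (nm in params) score_mat[, nm] <- score_parameter(vals[[nm]], nm, table)

  for (nm in params) {
    col <- unname(score_mat[, nm])
    prov <- ifelse(is.na(col), "missing", "measured")
    if (missing == "zero") {
      prov[is.na(col)] <- "imputed_zero"
      col[is.na(col)] <- 0L
      score_mat[, nm] <- col
    }
    out[[paste0(nm, "_score")]] <- col
    out[[paste0(nm, "_prov")]] <- prov
  }
  out$total <- as.integer(rowSums(score_mat))
  out$max_single <- suppressWarnings(as.integer(apply(score_mat, 1L, function(r) {
    if (anyNA(r)) NA_integer_ else max(r)
  })))
  out
}

#' Alert trigger rules
#'
#' A trigger rule converts a scored observation set into a binary alert:
#' alert when the total score reaches `threshold`, or -- if the single-score
#' rule `s3` is enabled -- when any single parameter scores 3 regardless of
#' the total.
#'
#' `default_trigger_rules()` returns the rule set used in validating GEWS
#' against NEWS: NEWS >= 5 with and without S3, NEWS >= 7 (urgent response),
#' GEWS >= 4 S3 (the predefined escalation threshold), GEWS >= 5 with and
#' without S3 (the recommended alerting threshold), and GEWS >= 8 (urgent
#' medical assistance).
#'
#' @param name Rule label, e.g. `"GEWS>=5 S3"`.
#' @param score Which score's totals the rule applies to (`"news"` or
#'   `"gews"`, matched against scored columns in the pipeline).
#' @param threshold Total-score alert threshold (>= 1).
#' @param s3 Should a single subscore of 3 also trigger the alert?
#' @return A one-row tibble (`trigger_rule`) or a tibble of rules
#'   (`default_trigger_rules`).
#' @examples
#' default_trigger_rules()
#' @export
trigger_rule <- function(name, score, threshold, s3 = FALSE) {
  stopifnot(length(threshold) == 1L, threshold >= 1)
  tibble(name = name, score = tolower(score),
         threshold = as.integer(threshold), s3 = isTRUE(s3))
}

#' @rdname trigger_rule
#' @export
default_trigger_rules <- function() {
  dplyr::bind_rows(
    trigger_rule("NEWS>=5 S3", "news", 5, s3 = TRUE),
    trigger_rule("NEWS>=5", "news", 5, s3 = FALSE),
    trigger_rule("NEWS>=7", "news", 7, s3 = FALSE),
    trigger_rule("GEWS>=4 S3", "gews", 4, s3 = TRUE),
    trigger_rule("GEWS>=5 S3", "gews", 5, s3 = TRUE),
    trigger_rule("GEWS>=5", "gews", 5, s3 = FALSE),
    trigger_rule("GEWS>=8", "gews", 8, s3 = FALSE)
  )
}

#' Evaluate a trigger rule
#'
#' @param total Integer vector of total scores.
#' @param max_single Integer vector of maximum single subscores.
#' @param rule A [trigger_rule()] row, or a list with `threshold` and `s3`.
#' @return Logical alert vector: `total >= threshold | (s3 & max_single == 3)`.
#' @examples
#' rule <- trigger_rule("GEWS>=5 S3", "gews", 5, s3 = TRUE)
#' evaluate_trigger(total = 3, max_single = 3, rule = rule) # TRUE via S3
#' @export
evaluate_trigger <- function(total, max_single, rule) {
  total >= rule$threshold | (isTRUE(rule$s3[[1]]) & max_single == 3L)
}
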