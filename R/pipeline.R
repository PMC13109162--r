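#' Run the full score-validation pipeline
#'
#' Orchestrates the complete analysis chain on one dataset: score every
#' observation set with each band table, merge events, build episodes, label
#' observation sets, impute missing subscores, exclude neutralized sets, and
#' compute per-rule performance/burden metrics and per-score discrimination
#' (AUROC and area under the precision-recall curve) -- separately for the
#' all-events (Type 1--4) and life-threatening (Type 1--3) analyses by
#' default. The engine is score-agnostic: the scores compared are exactly
#' the band tables passed in.
#'
#' When a [resampling_config()] is supplied, patient-clustered bootstrap
#' percentile confidence intervals are attached to AUROC and PR-AUC, and
#' paired cluster-permutation p-values are computed for the difference in
#' each between the first two tables.
#'
#' @param observations,events,patients The three input tables (see
#'   [ews_io]); events are raw (merging is applied internally).
#' @param tables Named list of band tables (or names/paths accepted by
#'   [ews_band_table()]); names must match the `score` field of `rules`.
#' @param rules Tibble of [trigger_rule()] rows.
#' @param windows A [window_config()].
#' @param analyses Named list of outcome event-type subsets.
#' @param impute_gap Hours; imputation gap threshold (see [impute_scores()]).
#' @param patient_days_method `"analyzed"` (stay minus neutralized time, the
#'   default) or `"stay"` for burden denominators.
#' @param resampling Optional [resampling_config()] enabling CIs and
#'   permutation p-values.
#' @return An object of class `ews_validation` with components `metrics`
#'   (per analysis x rule), `discrimination` (per analysis x score),
#'   `comparisons` (permutation tests, when enabled), `curves` (ROC and PR
#'   points), `data` (analyzed observation sets per analysis), and
#'   `manifest` (row counts at every stage, label and provenance counts,
#'   patient-day denominators, seed). Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 40), seed = 1)
#' fit <- ews_validate(cohort$observations, cohort$events, cohort$patients)
#' generics::tidy(fit)
#' @export
ews_validate <- function(observations, events, patients,
                         tables = list(gews = "gews", news = "news"),
                         rules = default_trigger_rules(),
                         windows = window_config(),
                         analyses = list(all_events = 1:4, life_threatening = 1:3),
                         impute_gap = 12,
                         patient_days_method = c("analyzed", "stay"),
                         resampling = NULL) {
  patient_days_method <- match.arg(patient_days_method)
  tables <- purrr::map(tables, function(tb) {
    if (inherits(tb, "ews_band_table")) tb else ews_band_table(tb)
  })
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a named list")
  }
  unresolved <- setdiff(unique(rules$score), names(tables))
  if (length(unresolved) > 0L) {
    abort(sprintf("rules reference unknown score(s): %s",
                  paste(unresolved, collapse = ", ")))
  }

  merged <- merge_events(events, windows)
  scored <- purrr::map(tables, function(tb) score_observations(observations, tb))

  manifest <- list(
    n_patients = nrow(patients),
    n_observations = nrow(observations),
    n_events_in = nrow(events),
    n_events_merged = nrow(merged),
    seed = if (!is.null(resampling)) resampling$seed else NA_integer_,
    patient_days_method = patient_days_method,
    stages = list()
  )

  metrics <- discrimination <- comparisons <- curves <- list()
  data_out <- list()

  for (a in names(analyses)) {
    event_types <- analyses[[a]]
    labels <- label_observations(observations, merged, patients, windows, event_types)
    stopifnot(nrow(labels) == nrow(observations))  # stage conservation

    wide <- labels |> dplyr::select("patient_id", "timestamp", "label")
    prov_counts <- list()
    for (s in names(tables)) {
      imp <- impute_scores(
        dplyr::bind_cols(scored[[s]], labels["label"]),
        tables[[s]], max_gap = impute_gap
      )
      stopifnot(nrow(imp) == nrow(observations), !anyNA(imp$total))
      wide[[paste0("total_", s)]] <- imp$total
      wide[[paste0("max_single_", s)]] <- imp$max_single
      prov_cols <- grep("_prov$", names(imp), value = TRUE)
      prov_counts[[s]] <- table(unlist(imp[prov_cols]))
    }

    pd_tbl <- patient_days(patients, merged, windows, event_types)
    denom <- sum(if (patient_days_method == "analyzed") pd_tbl$analyzed_days
                 else pd_tbl$stay_days)

    analyzed <- dplyr::filter(wide, .data$label != "neutralized")
    manifest$stages[[a]] <- list(
      labels = as.list(table(wide$label)),
      n_analyzed = nrow(analyzed),
      patient_days = denom,
      score_provenance = purrr::map(prov_counts, as.list)
    )
    data_out[[a]] <- analyzed

    metrics[[a]] <- rule_metrics(analyzed, rules, denom) |>
      dplyr::mutate(analysis = a, patient_days = denom, .before = 1)

    has_both <- length(unique(analyzed$label)) == 2L
    if (!has_both) {
      warn(sprintf("analysis '%s': only one label class present; discrimination skipped", a))
      discrimination[[a]] <- tibble(
        analysis = a, score = names(tables),
        n_event = sum(analyzed$label == "event"),
        n_non_event = sum(analyzed$label == "non_event"),
        auroc = NA_real_, pr_auc = NA_real_
      )
      next
    }

    disc <- purrr::map_dfr(names(tables), function(s) {
      sc <- analyzed[[paste0("total_", s)]]
      tibble(
        analysis = a, score = s,
        n_event = sum(analyzed$label == "event"),
        n_non_event = sum(analyzed$label == "non_event"),
        auroc = auroc(sc, analyzed$label),
        pr_auc = pr_auc(sc, analyzed$label)
      )
    })
    curves[[a]] <- purrr::map_dfr(names(tables), function(s) {
      sc <- analyzed[[paste0("total_", s)]]
      dplyr::bind_rows(
        roc_points(sc, analyzed$label) |>
          dplyr::mutate(curve = "roc", x = .data$fpr, y = .data$sensitivity),
        pr_points(sc, analyzed$label) |>
          dplyr::mutate(curve = "pr", x = .data$recall, y = .data$precision)
      ) |>
        dplyr::mutate(analysis = a, score = s)
    })

    if (!is.null(resampling)) {
      cis <- purrr::map_dfr(names(tables), function(s) {
        col <- paste0("total_", s)
        a_ci <- clustered_bootstrap_ci(
          analyzed, function(d) auroc(d[[col]], d$label),
          B = resampling$bootstrap_samples, seed = resampling$seed
        )
        p_ci <- clustered_bootstrap_ci(
          analyzed, function(d) pr_auc(d[[col]], d$label),
          B = resampling$bootstrap_samples, seed = resampling$seed
        )
        tibble(score = s,
               auroc_lower = a_ci$lower, auroc_upper = a_ci$upper,
               pr_auc_lower = p_ci$lower, pr_auc_upper = p_ci$upper)
      })
      disc <- dplyr::left_join(disc, cis, by = "score")

      if (length(tables) >= 2L) {
        s1 <- names(tables)[1]; s2 <- names(tables)[2]
        swap <- list(c(paste0("total_", s1), paste0("total_", s2)),
                     c(paste0("max_single_", s1), paste0("max_single_", s2)))
        comparisons[[a]] <- purrr::map_dfr(
          list(auroc = auroc, pr_auc = pr_auc),
          function(f) {
            paired_permutation_test(
              analyzed,
              statistic_a = function(d) f(d[[paste0("total_", s1)]], d$label),
              statistic_b = function(d) f(d[[paste0("total_", s2)]], d$label),
              swap_cols = swap, n_perm = resampling$permutations,
              seed = resampling$seed
            )
          },
          .id = "metric"
        ) |>
          dplyr::mutate(analysis = a, score_a = s1, score_b = s2, .before = 1)
      }
    }
    discrimination[[a]] <- disc
  }

  structure(
    list(
      metrics = dplyr::bind_rows(metrics),
      discrimination = dplyr::bind_rows(discrimination),
      comparisons = if (length(comparisons)) dplyr::bind_rows(comparisons) else NULL,
      curves = if (length(curves)) dplyr::bind_rows(curves) else NULL,
      data = data_out,
      manifest = manifest,
      config = list(tables = names(tables), rules = rules, windows = windows,
                    analyses = analyses, impute_gap = impute_gap,
                    patient_days_method = patient_days_method,
                    resampling = resampling)
    ),
    class = "ews_validation"
  )
}

#' @export
print.ews_validation <- function(x, ...) {
  cat("<ews_validation>\n")
  cat(sprintf("  %d patients, %d observation sets, %d events (%d after merging)\n",
              x$manifest$n_patients, x$manifest$n_observations,
              x$manifest$n_events_in, x$manifest$n_events_merged))
  for (a in names(x$manifest$stages)) {
    st <- x$manifest$stages[[a]]
    cat(sprintf("  %s: %d analyzed sets, %.1f patient-days\n",
                a, st$n_analyzed, st$patient_days))
  }
  cat("  discrimination:\n")
  print(as.data.frame(x$discrimination[, c("analysis", "score", "auroc", "pr_auc")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a human-readable validation report
#'
#' Writes the per-rule metric table, the discrimination table, ROC/PR curve
#' points and a run manifest to a directory, as CSV plus a Markdown summary.
#' The Markdown report includes a clinical-burden appendix expressing
#' ROA/AOER as expected alerts and detected events during a 24-h period on a
#' 24-bed acute ward (see [ward_rate()]).
#'
#' @param x An [ews_validate()] result.
#' @param dir Output directory (created if needed).
#' @param beds,hours Ward-rate appendix basis (default 24 beds, 24 h).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(x, dir, beds = 24, hours = 24) {
  stopifnot(inherits(x, "ews_validation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    metrics = file.path(dir, "metrics_by_rule.csv"),
    discrimination = file.path(dir, "discrimination.csv"),
    report = file.path(dir, "report.md"),
    manifest = file.path(dir, "manifest.yaml")
  )
  readr::write_csv(x$metrics, paths["metrics"])
  readr::write_csv(x$discrimination, paths["discrimination"])
  if (!is.null(x$curves)) {
    readr::write_csv(dplyr::filter(x$curves, .data$curve == "roc"),
                     file.path(dir, "roc_points.csv"))
    readr::write_csv(dplyr::filter(x$curves, .data$curve == "pr"),
                     file.path(dir, "pr_points.csv"))
  }

  md_table <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 3, format = "fg"))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, rows)
  }
  lines <- c("# Early-warning-score validation report", "")
  for (a in unique(x$metrics$analysis)) {
    m <- dplyr::filter(x$metrics, .data$analysis == a)
    lines <- c(lines, sprintf("## %s", a), "",
               sprintf("Patient-days: %.1f (%s)", m$patient_days[1],
                       x$manifest$patient_days_method), "",
               md_table(m[, c("rule", "alerts", "accuracy", "npv", "ppv",
                              "sensitivity", "specificity", "roa", "nne", "aoer")]),
               "")
    d <- dplyr::filter(x$discrimination, .data$analysis == a)
    lines <- c(lines, "### Discrimination", "",
               md_table(d[, intersect(c("score", "n_event", "n_non_event",
                                        "auroc", "pr_auc", "auroc_lower",
                                        "auroc_upper", "pr_auc_lower",
                                        "pr_auc_upper"), names(d))]), "")
    burden <- m |>
      dplyr::transmute(
        rule = .data$rule,
        alerts_per_period = round(ward_rate(.data$roa, beds, hours), 3),
        detected_events_per_period = round(ward_rate(.data$aoer, beds, hours), 3)
      )
    lines <- c(lines,
               sprintf("### Burden appendix (%d-bed ward, %d-h period)", beds, hours),
               "", md_table(burden), "")
  }
  if (!is.null(x$comparisons)) {
    lines <- c(lines, "## Paired permutation comparisons", "",
               md_table(x$comparisons), "")
  }
  writeLines(lines, paths["report"])
  yaml::write_yaml(x$manifest, paths["manifest"])
  invisible(paths)
}
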