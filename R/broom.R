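#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a validation result
#'
#' `tidy()` returns the requested component of an [ews_validate()] result as
#' a tibble; `glance()` returns a one-row summary (cohort sizes and the
#' discrimination of each score in the first analysis).
#'
#' @param x An `ews_validation` object.
#' @param type `"metrics"` (per-rule performance and burden, the default),
#'   `"discrimination"`, or `"comparisons"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ews_validation
#' @export
tidy.ews_validation <- function(x, type = c("metrics", "discrimination",
                                            "comparisons"), ...) {
  type <- match.arg(type)
  out <- x[[type]]
  if (is.null(out)) {
    abort(sprintf("no %s component (run ews_validate() with a resampling_config)", type))
  }
  as_tibble(out)
}

#' @rdname tidy.ews_validation
#' @method glance ews_validation
#' @export
glance.ews_validation <- function(x, ...) {
  d <- x$discrimination |>
    dplyr::filter(.data$analysis == .data$analysis[1]) |>
    dplyr::select("score", "auroc", "pr_auc") |>
    tidyr::pivot_wider(names_from = "score",
                       values_from = c("auroc", "pr_auc"))
  dplyr::bind_cols(
    tibble(
      n_patients = x$manifest$n_patients,
      n_observations = x$manifest$n_observations,
      n_events = x$manifest$n_events_merged,
      n_analyzed = x$manifest$stages[[1]]$n_analyzed,
      patient_days = x$manifest$stages[[1]]$patient_days
    ),
    d
  )
}

#' Plot ROC and precision-recall curves for a validation result
#'
#' @param object An `ews_validation` object with curves (both label classes
#'   present).
#' @param analysis Which analysis to plot (default: the first).
#' @param ... Unused.
#' @return A ggplot with one panel per curve type, colored by score.
#' @method autoplot ews_validation
#' @export
autoplot.ews_validation <- function(object, analysis = NULL, ...) {
  if (is.null(object$curves)) abort("no curves to plot (single-class analysis)")
  analysis <- analysis %||% object$curves$analysis[1]
  dat <- dplyr::filter(object$curves, .data$analysis == !!analysis) |>
    dplyr::mutate(curve = dplyr::recode(.data$curve,
                                        roc = "ROC (FPR vs sensitivity)",
                                        pr = "Precision-recall"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = toupper(.data$score))) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::facet_wrap(~curve) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "Score",
                  title = sprintf("Discrimination (%s)", analysis)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot alert burden by trigger rule
#'
#' Bar chart of the rate-of-alerts and alerted-outcome-event-rate per 100
#' patient-days for every trigger rule in a validation result; the gap
#' between the bars is the false-alarm load.
#'
#' @param x An `ews_validation` object.
#' @param analysis Which analysis to plot (default: the first).
#' @return A ggplot.
#' @export
plot_clinical_burden <- function(x, analysis = NULL) {
  stopifnot(inherits(x, "ews_validation"))
  analysis <- analysis %||% x$metrics$analysis[1]
  dat <- x$metrics |>
    dplyr::filter(.data$analysis == !!analysis) |>
    dplyr::select("rule", ROA = "roa", AOER = "aoer") |>
    tidyr::pivot_longer(-"rule", names_to = "metric", values_to = "rate")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rule, y = .data$rate,
                                    fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "per 100 patient-days", fill = NULL,
                  title = sprintf("Alert burden (%s)", analysis)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
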