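#' Resampling configuration
#'
#' Settings for cluster-aware inference: the bootstrap resamples patients
#' (all of a patient's observation sets travel together) and the paired
#' permutation test swaps the two scores per patient cluster. One seed
#' drives independent, named random streams for bootstrap, permutation and
#' simulation, so adding one procedure does not perturb another.
#'
#' @param bootstrap_samples Number of bootstrap resamples (default 10,000).
#' @param permutations Number of Monte Carlo permutations (default 9,999).
#' @param significance Significance threshold after multiplicity correction
#'   (default 0.00051, Bonferroni over the metric family).
#' @param seed Integer seed recorded in every report.
#' @return A list of class `ews_resampling_config`.
#' @export
resampling_config <- function(bootstrap_samples = 10000, permutations = 9999,
                              significance = 0.00051, seed = 1L) {
  stopifnot(bootstrap_samples >= 1, permutations >= 1)
  structure(
    list(bootstrap_samples = as.integer(bootstrap_samples),
         permutations = as.integer(permutations),
         significance = significance, seed = as.integer(seed)),
    class = "ews_resampling_config"
  )
}

#' Patient-clustered bootstrap percentile confidence interval
#'
#' Resamples patients with replacement; each resample keeps all of a
#' sampled patient's observation sets together, respecting within-patient
#' correlation. The interval is the percentile interval of the statistic
#' over resamples. Deterministic under a fixed seed. If the statistic is
#' undefined (`NA`) in more than half of the resamples, the interval is
#' reported as failed rather than computed from the defined remainder.
#'
#' @param data Data frame with a `cluster` column identifying patients.
#' @param statistic Function `data -> scalar` (may return `NA` when
#'   undefined, e.g. PPV with no alerts in the resample).
#' @param cluster Name of the patient-identifier column.
#' @param B Number of bootstrap resamples.
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return One-row tibble: `estimate`, `lower`, `upper`, `b`, `prop_na`,
#'   `failed`.
#' @export
clustered_bootstrap_ci <- function(data, statistic, cluster = "patient_id",
                                   B = 10000, conf = 0.95, seed = 1L) {
  assert_columns(data, cluster, "data")
  if (length(unique(data[[cluster]])) < 2L) {
    abort("clustered_bootstrap_ci: at least 2 patients are required")
  }
  idx_by_cluster <- split(seq_len(nrow(data)), data[[cluster]])
  ncl <- length(idx_by_cluster)
  estimate <- statistic(data)
  vals <- withr::with_seed(stream_seed(seed, "bootstrap"), {
    vapply(seq_len(B), function(b) {
      take <- sample.int(ncl, ncl, replace = TRUE)
      statistic(data[unlist(idx_by_cluster[take], use.names = FALSE), , drop = FALSE])
    }, numeric(1))
  })
  prop_na <- mean(is.na(vals))
  failed <- prop_na > 0.5
  alpha <- (1 - conf) / 2
  q <- if (failed) c(NA_real_, NA_real_) else
    stats::quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble(estimate = estimate, lower = q[1], upper = q[2],
         b = as.integer(B), prop_na = prop_na, failed = failed)
}

#' Paired Monte Carlo permutation test for a score comparison
#'
#' Tests whether a performance statistic differs between two scores computed
#' on the same observation sets. The observed difference is
#' `statistic_a(data) - statistic_b(data)`. The empirical null is generated
#' by randomly exchanging the two scores' columns within each patient
#' cluster (all of a patient's sets swap together), under which the two
#' arms are exchangeable if the scores perform equally. The two-sided
#' p-value uses add-one smoothing, `p = (1 + #{|d*| >= |d|}) / (n_perm + 1)`,
#' and is therefore never exactly 0. Deterministic under a fixed seed.
#'
#' @param data Data frame holding both scores' columns, aligned row-by-row
#'   on identical observation sets.
#' @param statistic_a,statistic_b Functions `data -> scalar` for the two
#'   arms (e.g. AUROC of the GEWS total and of the NEWS total).
#' @param swap_cols List of length-2 character vectors naming column pairs
#'   to exchange under the null (e.g.
#'   `list(c("total_gews", "total_news"), c("max_single_gews", "max_single_news"))`).
#' @param cluster Name of the patient-identifier column; use `NULL` for
#'   per-observation swapping (sensitivity analysis).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @return One-row tibble: `delta` (observed difference), `p_value`,
#'   `n_perm`.
#' @export
paired_permutation_test <- function(data, statistic_a, statistic_b, swap_cols,
                                    cluster = "patient_id", n_perm = 9999,
                                    seed = 1L) {
  for (pair in swap_cols) {
    if (length(pair) != 2L) abort("each swap_cols entry must name exactly 2 columns")
    assert_columns(data, pair, "data")
    if (length(data[[pair[1]]]) != length(data[[pair[2]]])) {
      abort("misaligned score columns")
    }
  }
  cl <- if (is.null(cluster)) seq_len(nrow(data)) else data[[cluster]]
  cl <- match(cl, unique(cl))
  ncl <- max(cl)

  delta_of <- function(d) statistic_a(d) - statistic_b(d)
  delta <- delta_of(data)

  perm <- withr::with_seed(stream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(p) {
      flip <- (stats::runif(ncl) < 0.5)[cl]
      d <- data
      for (pair in swap_cols) {
        a <- d[[pair[1]]]
        d[[pair[1]]][flip] <- d[[pair[2]]][flip]
        d[[pair[2]]][flip] <- a[flip]
      }
      delta_of(d)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(delta), na.rm = TRUE)) / (n_perm + 1)
  tibble(delta = delta, p_value = p, n_perm = as.integer(n_perm))
}
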