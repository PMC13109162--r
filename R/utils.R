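#' @importFrom rlang %||% .data abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# hours -> seconds (all timestamps are POSIXct; arithmetic is in seconds)
.hours <- function(h) h * 3600

.is_datetime <- function(x) inherits(x, "POSIXct")

#' @noRd
assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

#' @noRd
assert_sorted_within <- function(data, time_col, group_col, what = "data") {
  ok <- data |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::summarise(ok = !is.unsorted(.data[[time_col]]), .groups = "drop")
  if (!all(ok$ok)) {
    bad <- ok[[group_col]][!ok$ok]
    abort(sprintf(
      "%s must be sorted by %s within each %s (unsorted: %s)",
      what, time_col, group_col, paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  invisible(data)
}

# index of the last non-NA entry at or before each position, respecting group
# starts (`group_start` is the row index where each row's group begins)
#' @noRd
prev_value_index <- function(x, group_start) {
  i <- seq_along(x)
  i[is.na(x)] <- 0L
  at_or_before <- cummax(i)
  strictly_before <- c(0L, at_or_before[-length(x)])
  strictly_before[strictly_before < group_start] <- 0L
  strictly_before
}

# union length (in seconds) of a set of possibly overlapping intervals
#' @noRd
interval_union_length <- function(start, end) {
  keep <- !is.na(start) & !is.na(end) & end > start
  start <- as.numeric(start)[keep]
  end <- as.numeric(end)[keep]
  if (length(start) == 0L) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1L]; cur_e <- end[1L]
  for (k in seq_along(start)[-1L]) {
    if (start[k] <= cur_e) {
      cur_e <- max(cur_e, end[k])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[k]; cur_e <- end[k]
    }
  }
  total + (cur_e - cur_s)
}

# derived, named random streams off one user seed (so bootstrap, permutation
# and simulation draws never perturb one another); kept below 2^31 - 1
#' @noRd
stream_seed <- function(seed, stream = c("bootstrap", "permutation", "simulation")) {
  stream <- match.arg(stream)
  offset <- c(bootstrap = 1L, permutation = 2L, simulation = 3L)[[stream]]
  as.integer((as.numeric(seed) * 48271 + offset * 1000003) %% 2147483647)
}
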