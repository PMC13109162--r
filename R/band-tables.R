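#' Load an early-warning-score band table
#'
#' A band table is the declarative definition of an early warning score: for
#' each vital parameter an ordered list of value bands, each mapping to a
#' subscore in 0--3, plus a categorical map for the level of consciousness.
#' Two tables ship with the package: `"news"` (the National Early Warning
#' Score, six parameters scored 0--3 plus a binary oxygen-therapy item worth
#' 2) and `"gews"` (the Geriatric Early Warning Score, with frailty-adapted
#' bands, graded oxygen therapy, agitation scored as the most severe
#' consciousness state, and pain as an eighth scored item). Any other string
#' is taken as a path to a band-table file in the same YAML schema, so band
#' placement is an editable configuration, never code.
#'
#' Printed bands such as `9--11` are closed intervals. Where adjacent printed
#' bands leave an integer or decimal gap (e.g. `20` to `21`), the gap is
#' attached to the lower band at load time so that the bands jointly cover
#' the physiologic domain; fractional measurements falling in a printed gap
#' are therefore scored by the band below. The loader validates that bands
#' are non-overlapping and, after gap closure, cover the declared domain.
#'
#' @param table `"news"`, `"gews"`, or a path to a band-table YAML file.
#' @return An object of class `ews_band_table`: a list with `name` and
#'   `parameters`, where each numeric parameter carries a tibble of bands
#'   (`lo`, `hi`, `lo_closed`, `hi_closed`, `score`, and the printed bounds)
#'   and each categorical parameter a named score map.
#' @examples
#' gews <- ews_band_table("gews")
#' names(gews$parameters)
#' @export
ews_band_table <- function(table = c("news", "gews")) {
  if (is.character(table) && length(table) == 1L) {
    path <- if (tolower(table) %in% c("news", "gews")) {
      system.file("extdata", paste0(tolower(table), ".bands"), package = "gews", mustWork = TRUE)
    } else {
      if (!file.exists(table)) abort(sprintf("band-table file not found: %s", table))
      table
    }
    raw <- yaml::read_yaml(path)
  } else if (is.list(table)) {
    raw <- table
  } else {
    abort("`table` must be \"news\", \"gews\", a file path, or a band-table list")
  }

  parameters <- purrr::imap(raw$parameters, function(p, nm) {
    kind <- p$kind %||% "numeric"
    if (kind == "categorical") {
      map <- unlist(p$map)
      list(kind = "categorical", map = map)
    } else {
      bands <- purrr::map_dfr(p$bands, function(b) {
        tibble(
          printed_lo = as.numeric(b$min %||% -Inf),
          printed_hi = as.numeric(b$max %||% Inf),
          lo_closed = isTRUE(b$min_closed %||% TRUE),
          hi_closed = isTRUE(b$max_closed %||% TRUE),
          score = as.integer(b$score)
        )
      })
      bands <- dplyr::arrange(bands, .data$printed_lo, .data$printed_hi)
      # close printed gaps: the gap belongs to the lower band
      bands$lo <- bands$printed_lo
      bands$hi <- bands$printed_hi
      n <- nrow(bands)
      if (n > 1L) {
        for (i in seq_len(n - 1L)) {
          if (bands$hi[i] < bands$lo[i + 1L]) {
            bands$hi[i] <- bands$lo[i + 1L]
            bands$hi_closed[i] <- !bands$lo_closed[i + 1L]
          }
        }
      }
      list(
        kind = "numeric",
        unit = p$unit %||% NA_character_,
        domain = as.numeric(p$domain %||% c(-Inf, Inf)),
        bands = bands
      )
    }
  })

  out <- structure(
    list(name = raw$name, parameters = parameters),
    class = "ews_band_table"
  )
  validate_band_table(out)
  out
}

#' Validate a band table
#'
#' Checks that every subscore lies in 0--3, that numeric bands are
#' non-overlapping and jointly cover the parameter's declared physiologic
#' domain (by an exhaustive sweep over a dense grid plus all band
#' boundaries), and that subscores along the value axis form a unimodal
#' valley (non-increasing, then non-decreasing), i.e. severity grows toward
#' both physiologic extremes.
#'
#' @param table An `ews_band_table`.
#' @param grid_n Number of sweep points per parameter.
#' @return `table`, invisibly; errors describe the offending parameter.
#' @export
validate_band_table <- function(table, grid_n = 512L) {
  stopifnot(inherits(table, "ews_band_table"))
  for (nm in names(table$parameters)) {
    p <- table$parameters[[nm]]
    if (p$kind == "categorical") {
      if (!all(p$map %in% 0:3)) {
        abort(sprintf("%s/%s: categorical scores must be in 0..3", table$name, nm))
      }
      next
    }
    b <- p$bands
    if (!all(b$score %in% 0:3)) {
      abort(sprintf("%s/%s: band scores must be in 0..3", table$name, nm))
    }
    grid <- unique(sort(c(
      seq(p$domain[1], p$domain[2], length.out = grid_n),
      b$lo[is.finite(b$lo)], b$hi[is.finite(b$hi)],
      b$lo[is.finite(b$lo)] + 1e-9, b$hi[is.finite(b$hi)] - 1e-9
    )))
    grid <- grid[grid >= p$domain[1] & grid <= p$domain[2]]
    hits <- vapply(grid, function(v) sum(.band_contains(b, v)), integer(1))
    if (any(hits == 0L)) {
      abort(sprintf(
        "%s/%s: bands do not cover the domain (e.g. value %g)",
        table$name, nm, grid[which(hits == 0L)[1]]
      ))
    }
    if (any(hits > 1L)) {
      abort(sprintf(
        "%s/%s: overlapping bands (e.g. value %g)",
        table$name, nm, grid[which(hits > 1L)[1]]
      ))
    }
    # unimodal valley in severity across ordered bands
    s <- b$score
    valley <- which.min(s)
    if (is.unsorted(rev(s[seq_len(valley)])) || is.unsorted(s[valley:length(s)])) {
      abort(sprintf("%s/%s: band scores are not a unimodal valley", table$name, nm))
    }
  }
  invisible(table)
}

# broadcasts a one-row band against a value vector, or many bands against a
# scalar value
#' @noRd
.band_contains <- function(bands, value) {
  k <- max(nrow(bands), length(value))
  lo <- rep_len(bands$lo, k); hi <- rep_len(bands$hi, k)
  loc <- rep_len(bands$lo_closed, k); hic <- rep_len(bands$hi_closed, k)
  v <- rep_len(value, k)
  ifelse(loc, v >= lo, v > lo) & ifelse(hic, v <= hi, v < hi)
}

#' @export
print.ews_band_table <- function(x, ...) {
  cat(sprintf("<ews_band_table> %s: %d parameters\n", x$name, length(x$parameters)))
  for (nm in names(x$parameters)) {
    p <- x$parameters[[nm]]
    if (p$kind == "categorical") {
      cat(sprintf("  %s: %s\n", nm,
                  paste(sprintf("%s=%d", names(p$map), p$map), collapse = ", ")))
    } else {
      cat(sprintf("  %s [%s]: %d bands\n", nm, p$unit, nrow(p$bands)))
    }
  }
  invisible(x)
}

#' Site-correct a body temperature
#'
#' Forehead temperature measurements read low; 0.2 degC is added to the
#' recorded value. Axillary, temporal and tympanic measurements are used as
#' recorded. A present temperature with a missing site is returned unchanged
#' with a warning (conservative identity).
#'
#' @param temp Recorded temperature in degC (vector; `NA` allowed).
#' @param site Measurement site, one of `"axilla"`, `"temporal"`,
#'   `"tympanic"`, `"forehead"` (vector; `NA` allowed).
#' @return Corrected temperature vector.
#' @examples
#' adjust_temperature(36.8, "forehead") # 37.0
#' adjust_temperature(36.8, "tympanic") # 36.8
#' @export
adjust_temperature <- function(temp, site) {
  known <- c("axilla", "temporal", "tympanic", "forehead")
  bad <- !is.na(site) & !(site %in% known)
  if (any(bad)) {
    abort(sprintf(
      "unknown temperature site: %s (expected one of %s)",
      paste(unique(site[bad]), collapse = ", "), paste(known, collapse = ", ")
    ))
  }
  if (any(!is.na(temp) & is.na(site))) {
    warn("temperature recorded without a measurement site; no correction applied")
  }
  temp + ifelse(!is.na(temp) & !is.na(site) & site == "forehead", 0.2, 0)
}

#' Score a single parameter against its bands
#'
#' Maps values of one vital parameter to subscores 0--3 by band membership
#' (no rounding: fractional values are scored by the band containing them).
#' A numeric value outside every band is a configuration/coverage error, not
#' a silent 0. Missing values score `NA` (the imputation stage decides).
#'
#' @param value Numeric vector, or character vector for categorical
#'   parameters such as `consciousness`.
#' @param parameter Parameter name as used in the band table (e.g.
#'   `"resp_rate"`, `"spo2"`, `"pain"`, `"consciousness"`).
#' @param table An [ews_band_table()].
#' @return Integer vector of subscores (NA where `value` is missing).
#' @examples
#' score_parameter(7, "pain", ews_band_table("gews"))   # 3
#' score_parameter(24, "resp_rate", ews_band_table("news")) # 2
#' @export
score_parameter <- function(value, parameter, table) {
  p <- table$parameters[[parameter]]
  if (is.null(p)) {
    abort(sprintf("%s does not score parameter '%s'", table$name, parameter))
  }
  if (p$kind == "categorical") {
    value <- as.character(value)
    bad <- !is.na(value) & !(value %in% names(p$map))
    if (any(bad)) {
      abort(sprintf(
        "%s/%s: unknown category: %s", table$name, parameter,
        paste(unique(value[bad]), collapse = ", ")
      ))
    }
    out <- unname(p$map[value])
    return(as.integer(out))
  }
  value <- as.numeric(value)
  out <- rep(NA_integer_, length(value))
  remaining <- !is.na(value)
  for (i in seq_len(nrow(p$bands))) {
    hit <- remaining & .band_contains(p$bands[i, ], value)
    out[hit] <- p$bands$score[i]
    remaining <- remaining & !hit
  }
  if (any(remaining)) {
    abort(sprintf(
      "%s/%s: value outside all bands (coverage violated): %s",
      table$name, parameter,
      paste(unique(value[remaining]), collapse = ", ")
    ))
  }
  out
}
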