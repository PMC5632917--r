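#' Standard column names of a daily series
#'
#' A daily series is a tibble with one row per calendar day and the columns
#' `date`, `admissions_total`, optionally `admissions_male` and
#' `admissions_female`, the pollutant concentrations `pm25`, `pm10`, `so2`,
#' `no2` (24-h means, ug/m3) and the daily minimum temperature `tmin` (deg C).
#'
#' @return Character vector of recognised column names.
#' @export
daily_series_cols <- function() {
  c("date", "admissions_total", "admissions_male", "admissions_female",
    "pm25", "pm10", "so2", "no2", "tmin")
}

pollutant_cols <- function() c("pm25", "pm10", "so2", "no2")

#' Read a daily admissions/pollution/weather CSV
#'
#' Reads a CSV with one row per day, renames columns to the standard names
#' (see [daily_series_cols()]), sorts by date and validates the result.
#'
#' @param path Path to a CSV file with a header row and ISO-8601 dates.
#' @param col_map Optional named character vector mapping standard column
#'   names to the names used in the file, e.g.
#'   `c(admissions_total = "n_admit", tmin = "temp_min")`. Columns already
#'   bearing standard names need not be listed.
#'
#' @return A validated daily-series tibble sorted by date.
#' @export
read_daily_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "airadmit_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("mapped column(s) absent from file: ",
                   paste(missing_src, collapse = ", ")),
            class = "airadmit_schema_error")
    }
    raw <- rename(raw, !!!setNames(unname(col_map), names(col_map)))
  }
  required <- c("date", "admissions_total", "tmin")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req) > 0) {
    abort(paste0("required column(s) missing: ",
                 paste(missing_req, collapse = ", ")),
          class = "airadmit_schema_error")
  }
  if (!inherits(raw$date, "Date")) {
    parsed <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
    if (anyNA(parsed) && !anyNA(raw$date)) {
      abort(paste0("unparseable date at row ", which(is.na(parsed))[1]),
            class = "airadmit_parse_error")
    }
    raw$date <- parsed
  }
  for (col in intersect(c(pollutant_cols(), "tmin"), names(raw))) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))[1]
      abort(paste0("non-numeric value in column '", col, "' at row ", bad),
            class = "airadmit_parse_error")
    }
  }
  validate_daily_series(select(raw, all_of(intersect(daily_series_cols(),
                                                     names(raw)))))
}

#' Write a daily series to CSV
#'
#' @param data A daily-series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Validate a daily series
#'
#' Checks the invariants of a daily series: dates unique and orderable,
#' admission counts nonnegative integers with `male + female = total` where
#' both sexes are present, concentrations nonnegative, temperature finite.
#' Calendar gaps are flagged with a warning (downstream lag features treat
#' them as missing; nothing is imputed).
#'
#' @param data A tibble with at least `date`, `admissions_total`, `tmin`.
#' @return The validated tibble, sorted by date.
#' @export
validate_daily_series <- function(data) {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("empty daily series", class = "airadmit_validation_error")
  if (anyDuplicated(data$date)) {
    dup <- data$date[duplicated(data$date)][1]
    abort(paste0("duplicate date: ", dup), class = "airadmit_validation_error")
  }
  data <- arrange(data, .data$date)
  for (col in intersect(c("admissions_total", "admissions_male",
                          "admissions_female"), names(data))) {
    x <- data[[col]]
    bad <- which(!is.na(x) & (x < 0 | x != round(x)))
    if (length(bad) > 0) {
      abort(paste0("column '", col, "' must be a nonnegative integer count; ",
                   "offending row ", bad[1], " (date ", data$date[bad[1]], ")"),
            class = "airadmit_validation_error")
    }
  }
  if (all(c("admissions_male", "admissions_female") %in% names(data))) {
    ok <- is.na(data$admissions_male) | is.na(data$admissions_female) |
      (data$admissions_male + data$admissions_female == data$admissions_total)
    if (!all(ok)) {
      abort(paste0("male + female admissions differ from total at row ",
                   which(!ok)[1]),
            class = "airadmit_validation_error")
    }
  }
  for (col in intersect(pollutant_cols(), names(data))) {
    bad <- which(!is.na(data[[col]]) & data[[col]] < 0)
    if (length(bad) > 0) {
      abort(paste0("negative concentration in '", col, "' at row ", bad[1]),
            class = "airadmit_validation_error")
    }
  }
  if (any(!is.finite(data$tmin) & !is.na(data$tmin))) {
    abort("non-finite tmin", class = "airadmit_validation_error")
  }
  gaps <- diff(as.integer(data$date))
  if (any(gaps > 1)) {
    warn(paste0(sum(gaps > 1), " calendar gap(s) in the daily series; ",
                "lag windows spanning a gap will be treated as missing"))
  }
  data
}

#' Season of a date
#'
#' The warm season runs April through September; October through March is
#' the cold season.
#'
#' @param date A `Date` vector.
#' @return Factor with levels `warm`, `cold`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(date, "%m"))
  factor(ifelse(m >= 4 & m <= 9, "warm", "cold"), levels = c("warm", "cold"))
}

#' Add a season column to a daily series
#'
#' @param data A daily-series tibble.
#' @return `data` with a `season` factor column.
#' @export
add_season <- function(data) {
  mutate(data, season = season_of(.data$date))
}

#' Summary statistics per variable
#'
#' Mean, SD and five-number summary of each numeric variable of a daily
#' series. Quantiles use linear interpolation between order statistics
#' (R's default type-7 rule); `iqr = q3 - q1`. For admission-count columns
#' the `total` column carries the period sum.
#'
#' @param data A daily-series tibble.
#' @param vars Variables to summarise; defaults to every standard numeric
#'   column present.
#' @return A tibble with one row per variable: `variable`, `n` (non-missing
#'   days), `total` (sum, admission counts only), `mean`, `sd`, `min`, `q1`,
#'   `q2`, `q3`, `max`, `iqr`.
#' @export
daily_summary <- function(data, vars = NULL) {
  if (nrow(data) == 0) abort("empty daily series", class = "airadmit_validation_error")
  if (is.null(vars)) {
    vars <- intersect(setdiff(daily_series_cols(), "date"), names(data))
  }
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    qs <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble(
      variable = v,
      n = length(x),
      total = if (grepl("^admissions", v)) sum(x) else NA_real_,
      mean = mean(x), sd = sd(x),
      min = min(x), q1 = qs[1], q2 = qs[2], q3 = qs[3], max = max(x),
      iqr = qs[3] - qs[1]
    )
  })
}

#' Pearson correlations between pollutant series
#'
#' @param data A daily-series tibble.
#' @param pollutants Columns to correlate (default the four pollutants).
#' @param use Passed to [stats::cor()]; default uses pairwise complete
#'   observations.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   columns yield `NA` entries and a warning.
#' @export
pollutant_correlations <- function(data, pollutants = pollutant_cols(),
                                   use = "pairwise.complete.obs") {
  pollutants <- intersect(pollutants, names(data))
  m <- as.matrix(data[, pollutants, drop = FALSE])
  if (sum(complete.cases(m)) < 3) {
    abort("need at least 3 complete rows", class = "airadmit_validation_error")
  }
  degenerate <- vapply(pollutants, function(p) sd(m[, p], na.rm = TRUE) == 0,
                       logical(1))
  r <- suppressWarnings(cor(m, use = use))
  diag(r) <- 1
  if (any(degenerate)) {
    warn(paste0("zero-variance column(s): ",
                paste(pollutants[degenerate], collapse = ", "),
                "; correlations undefined (NA)"))
  }
  r
}
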