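#' Construct a daily series
#'
#' @param dates `Date` vector, strictly increasing.
#' @param daily_mean Numeric vector of daily means.
#' @param n_hours_used Integer vector, hours contributing to each mean.
#' @param variable_name Label carried over from the hourly series.
#' @return An object of class `daily_series`.
#' @export
daily_series <- function(dates, daily_mean, n_hours_used,
                         variable_name = "value") {
  stopifnot(
    inherits(dates, "Date"),
    length(dates) == length(daily_mean),
    length(dates) == length(n_hours_used)
  )
  if (length(dates) && is.unsorted(dates, strictly = TRUE)) {
    stop("dates must be strictly increasing")
  }
  if (any(n_hours_used < 1 | n_hours_used > 24)) {
    stop("n_hours_used must be between 1 and 24")
  }
  structure(
    list(
      dates = dates, daily_mean = as.numeric(daily_mean),
      n_hours_used = as.integer(n_hours_used),
      variable_name = variable_name
    ),
    class = "daily_series"
  )
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf(
    "<daily_series '%s': %d days>\n", x$variable_name, length(x$dates)
  ))
  invisible(x)
}

#' 24-hour means from an hourly series
#'
#' Aggregates a cleaned hourly series to one arithmetic mean per calendar
#' day (UTC). Days with too few valid hours are excluded: a day is retained
#' only when at least `min_completeness * 24` hourly records are present.
#'
#' @param series An [hourly_series].
#' @param min_completeness Required fraction of the 24 hours, in `(0, 1]`.
#'   The default 0.75 (18 of 24 hours) is the usual validity rule for daily
#'   air-quality aggregates.
#' @return A [daily_series].
#' @export
daily_means <- function(series, min_completeness = 0.75) {
  stopifnot(inherits(series, "hourly_series"))
  if (!is.numeric(min_completeness) || length(min_completeness) != 1 ||
    min_completeness <= 0 || min_completeness > 1) {
    stop("parameter error: min_completeness must be in (0, 1]")
  }
  if (length(series) == 0L) {
    return(daily_series(as.Date(character()), numeric(0), integer(0),
      series$variable_name))
  }
  day <- as.Date(series$timestamps, tz = "UTC")
  means <- tapply(series$values, day, mean)
  hours <- tapply(series$values, day, length)
  keep <- hours >= min_completeness * 24
  dates <- as.Date(names(means))[keep]
  ord <- order(dates)
  daily_series(dates[ord], as.numeric(means[keep])[ord],
    as.integer(hours[keep])[ord], series$variable_name)
}

#' Annual (whole-series) exposure summary
#'
#' Mean, sample standard deviation (n-1 denominator), minimum, maximum and
#' the number of observations, computed over daily means by default or over
#' raw hourly values when given an hourly series.
#'
#' @param x A [daily_series] or [hourly_series].
#' @return A one-row data frame `mean, sd, min, max, n`.
#' @export
annual_summary <- function(x) UseMethod("annual_summary")

.summary_row <- function(v) {
  if (length(v) == 0L) stop("empty-input error: no observations to summarise")
  data.frame(
    mean = mean(v),
    sd = if (length(v) > 1) stats::sd(v) else 0,
    min = min(v), max = max(v), n = length(v)
  )
}

#' @export
annual_summary.daily_series <- function(x) {
  out <- .summary_row(x$daily_mean)
  names(out)[names(out) == "n"] <- "n_days"
  out
}

#' @export
annual_summary.hourly_series <- function(x) {
  out <- .summary_row(x$values)
  names(out)[names(out) == "n"] <- "n_hours"
  out
}

#' Binned exposure distribution
#'
#' Assigns daily means to half-open concentration strata `[lower, upper)`
#' of a fixed width, with edges aligned to multiples of the width, and
#' returns each stratum's midpoint and the fraction of days falling in it.
#' This is the categorical exposure distribution over which the
#' population-attributable proportion is aggregated.
#'
#' @param daily A [daily_series].
#' @param bin_width Stratum width in ug/m3 (default 1).
#' @return A data frame `lower, upper, midpoint, proportion`; proportions
#'   sum to 1.
#' @export
bin_distribution <- function(daily, bin_width = 1) {
  stopifnot(inherits(daily, "daily_series"))
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    stop("parameter error: bin_width must be > 0")
  }
  v <- daily$daily_mean
  if (length(v) == 0L) stop("empty-input error: no daily means to bin")
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  idx <- findInterval(v, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  keep <- counts > 0L # only strata covering observed days
  lower <- breaks[-length(breaks)][keep]
  upper <- breaks[-1L][keep]
  data.frame(
    lower = lower, upper = upper,
    midpoint = (lower + upper) / 2,
    proportion = counts[keep] / length(v)
  )
}

#' Single-stratum exposure distribution at the annual mean
#'
#' Degenerate one-category distribution placing all weight on the annual
#' mean concentration; used for the annual-mean assessment mode.
#'
#' @param daily A [daily_series].
#' @return A one-row data frame in the [bin_distribution] layout.
#' @export
annual_mean_category <- function(daily) {
  m <- annual_summary(daily)$mean
  data.frame(lower = m, upper = m, midpoint = m, proportion = 1)
}

#' Exposure summary table for several cities
#'
#' @param series_by_city Named list of [daily_series] (or [hourly_series]).
#' @param variable Label written in the `variable` column.
#' @return Data frame `city, variable, max, min, mean, sd`, one row per city.
#' @export
exposure_summary_table <- function(series_by_city, variable = "pm25") {
  rows <- lapply(names(series_by_city), function(city) {
    s <- annual_summary(series_by_city[[city]])
    data.frame(
      city = city, variable = variable,
      max = s$max, min = s$min, mean = s$mean, sd = s$sd
    )
  })
  do.call(rbind, rows)
}
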