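#' Construct an hourly series
#'
#' A lightweight container for one hourly monitoring series: a strictly
#' increasing timestamp vector, the measured values, the variable label and
#' the number of raw records removed during cleaning.
#'
#' @param timestamps `POSIXct` vector (UTC), strictly increasing.
#' @param values Numeric vector, same length as `timestamps`.
#' @param variable_name Label, e.g. `"pm25"` or `"tmpf"`.
#' @param n_dropped Number of raw records removed before construction.
#' @return An object of class `hourly_series`.
#' @export
hourly_series <- function(timestamps, values, variable_name, n_dropped = 0L) {
  stopifnot(inherits(timestamps, "POSIXct"), length(timestamps) == length(values))
  if (anyNA(timestamps)) stop("timestamps must not contain NA")
  if (is.unsorted(timestamps, strictly = TRUE)) {
    if (anyDuplicated(as.numeric(timestamps)) > 0) {
      stop("duplicate timestamp in series '", variable_name, "'")
    }
    stop("timestamps must be strictly increasing")
  }
  if (n_dropped < 0) stop("n_dropped must be >= 0")
  structure(
    list(
      timestamps = timestamps,
      values = as.numeric(values),
      variable_name = as.character(variable_name),
      n_dropped = as.integer(n_dropped)
    ),
    class = "hourly_series"
  )
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf(
    "<hourly_series '%s': %d records, %d dropped during cleaning>\n",
    x$variable_name, length(x$values), x$n_dropped
  ))
  if (length(x$values)) {
    cat(sprintf(
      "  %s .. %s | range [%.4g, %.4g]\n",
      format(min(x$timestamps), "%Y-%m-%d %H:%M"),
      format(max(x$timestamps), "%Y-%m-%d %H:%M"),
      min(x$values), max(x$values)
    ))
  }
  invisible(x)
}

#' @export
length.hourly_series <- function(x) length(x$values)

.parse_timestamps <- function(ts) {
  # accept ISO-8601 with either 'T' or space separator; seconds optional;
  # unparseable entries come back NA so the caller can name the row
  norm <- sub("T", " ", ts, fixed = TRUE)
  out <- as.POSIXct(strptime(norm, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  retry <- is.na(out)
  if (any(retry)) {
    out[retry] <- as.POSIXct(strptime(norm[retry], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  out
}

#' Remove non-positive records from a pollutant value vector
#'
#' Concentration monitors report zero or negative values as instrument
#' faults; both are removed for pollutant variables. Missing values are
#' unusable in either mode and are also removed.
#'
#' @param values Numeric vector.
#' @param pollutant If `TRUE`, drop values `<= 0` in addition to `NA`.
#' @return Logical vector: `TRUE` for records to keep.
#' @keywords internal
clean_keep <- function(values, pollutant = TRUE) {
  keep <- !is.na(values)
  if (pollutant) keep <- keep & values > 0
  keep
}

#' Read an hourly monitoring CSV
#'
#' Reads a two-column `timestamp,value` CSV, validates and sorts the
#' timestamps, and (for pollutant variables) removes zero and negative
#' concentration records, counting them in `n_dropped`. Meteorological
#' variables retain non-positive values: sub-zero temperatures are real.
#'
#' @param path CSV file with header columns `timestamp,value`.
#' @param variable_name Label stored on the returned series.
#' @param pollutant If `TRUE` (default), apply the non-positive-value
#'   cleaning rule; set `FALSE` for meteorological series.
#' @return An [hourly_series].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "timestamp,value",
#'   "2019-01-01T00:00:00,12.5",
#'   "2019-01-01T01:00:00,-3.0",
#'   "2019-01-01T02:00:00,14.1"
#' ), f)
#' s <- read_hourly(f, "pm25")
#' s$n_dropped # 1
read_hourly <- function(path, variable_name, pollutant = TRUE) {
  raw <- utils::read.csv(path, colClasses = c("character", "character"))
  if (!all(c("timestamp", "value") %in% names(raw))) {
    stop("input file must have header columns 'timestamp,value': ", path)
  }
  if (nrow(raw) == 0L) {
    return(hourly_series(as.POSIXct(character(), tz = "UTC"), numeric(0),
      variable_name,
      n_dropped = 0L
    ))
  }
  ts <- .parse_timestamps(raw$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf(
      "unparseable timestamp '%s' at data row %d of %s",
      raw$timestamp[bad], bad, path
    ))
  }
  if (anyDuplicated(as.numeric(ts)) > 0) {
    dup <- raw$timestamp[duplicated(as.numeric(ts))][1L]
    stop(sprintf("duplicate timestamp '%s' in %s", dup, path))
  }
  vals <- suppressWarnings(as.numeric(raw$value))
  keep <- clean_keep(vals, pollutant = pollutant)
  ord <- order(ts[keep])
  hourly_series(ts[keep][ord], vals[keep][ord], variable_name,
    n_dropped = sum(!keep)
  )
}

#' Clean an in-memory hourly series
#'
#' Applies the pollutant cleaning rule (drop `NA` and, in pollutant mode,
#' non-positive values) to an already-constructed series, accumulating the
#' drop count. Idempotent: cleaning a clean series changes nothing.
#'
#' @param series An [hourly_series].
#' @param pollutant Apply the non-positive rule (default `TRUE`).
#' @return A cleaned [hourly_series] with updated `n_dropped`.
#' @export
clean_series <- function(series, pollutant = TRUE) {
  stopifnot(inherits(series, "hourly_series"))
  keep <- clean_keep(series$values, pollutant = pollutant)
  hourly_series(
    series$timestamps[keep], series$values[keep], series$variable_name,
    n_dropped = series$n_dropped + sum(!keep)
  )
}

#' Write an hourly series back to CSV
#'
#' Inverse of [read_hourly] for the retained records: values are written
#' with 17 significant digits so the numeric round-trip is bit-exact.
#'
#' @param series An [hourly_series].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hourly <- function(series, path) {
  stopifnot(inherits(series, "hourly_series"))
  df <- data.frame(
    timestamp = format(series$timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = sprintf("%.17g", series$values)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.age_groups <- c("30+", "25+", "0-5")

.pop_column <- function(age_group) {
  switch(age_group,
    "30+" = "n_30plus",
    "25+" = "n_25plus",
    "0-5" = "n_under5",
    stop("unknown age group '", age_group, "' (expected one of ",
      paste(.age_groups, collapse = ", "), ")")
  )
}

#' Read a study configuration file
#'
#' Parses a YAML configuration describing cities (with population counts and
#' input CSV paths), concentration-response functions, and health endpoints
#' (baseline incidence per 100,000 with a CRF reference), and validates the
#' cross-references.
#'
#' @param path YAML file with top-level sections `cities`, `crfs`,
#'   `endpoints`.
#' @return A list with components:
#'   * `endpoints` — data frame `city, endpoint, age_group, baseline_incidence, crf`;
#'   * `populations` — data frame `city, n_total, n_30plus, n_25plus, n_under5`;
#'   * `crfs` — named list of [crf_spec] objects;
#'   * `paths` — named list of per-city input file paths (may be empty).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("cities", "crfs", "endpoints")) {
    if (is.null(cfg[[sec]])) stop("configuration error: missing section '", sec, "'")
  }

  crfs <- list()
  for (cr in cfg$crfs) {
    if (is.null(cr$name)) stop("configuration error: crf without a name")
    crfs[[cr$name]] <- switch(cr$form,
      log_linear = crf_log_linear(
        rr = cr$rr, rr_low = cr$rr_low %||% cr$rr,
        rr_high = cr$rr_high %||% cr$rr,
        increment = cr$increment %||% 10, cutoff = cr$cutoff %||% 10
      ),
      ier = crf_ier(
        alpha = cr$alpha, gamma = cr$gamma, delta = cr$delta,
        z_cf = cr$z_cf %||% 10,
        low = cr$low, high = cr$high
      ),
      implied_ap = crf_implied_ap(cr$ap),
      stop("configuration error: unknown CRF form '", cr$form, "'")
    )
  }

  pops <- do.call(rbind, lapply(cfg$cities, function(ci) {
    p <- ci$population
    if (is.null(p)) stop("configuration error: city '", ci$name, "' has no population block")
    data.frame(
      city = ci$name,
      n_total = p$total,
      n_30plus = p$age_30plus %||% NA_real_,
      n_25plus = p$age_25plus %||% NA_real_,
      n_under5 = p$age_under5 %||% NA_real_
    )
  }))
  bad <- vapply(seq_len(nrow(pops)), function(i) {
    at_risk <- unlist(pops[i, c("n_30plus", "n_25plus", "n_under5")])
    any(at_risk < 0 | at_risk > pops$n_total[i], na.rm = TRUE)
  }, logical(1))
  if (any(bad)) {
    stop("validation error: at-risk population outside [0, total] for city ",
      paste(pops$city[bad], collapse = ", "))
  }

  endpoints <- do.call(rbind, lapply(cfg$endpoints, function(ep) {
    data.frame(
      city = ep$city, endpoint = ep$name,
      age_group = ep$age_group,
      baseline_incidence = ep$baseline_incidence,
      crf = ep$crf
    )
  }))
  if (any(endpoints$baseline_incidence < 0)) {
    stop("validation error: negative baseline incidence")
  }
  if (anyDuplicated(endpoints[, c("city", "endpoint")]) > 0) {
    stop("validation error: duplicate (city, endpoint) pair in configuration")
  }
  missing_crf <- setdiff(endpoints$crf, names(crfs))
  if (length(missing_crf)) {
    stop("configuration error: endpoint references undefined CRF ",
      paste(sQuote(missing_crf), collapse = ", "))
  }
  missing_city <- setdiff(endpoints$city, pops$city)
  if (length(missing_city)) {
    stop("configuration error: endpoint for city without a population entry: ",
      paste(missing_city, collapse = ", "))
  }
  vapply(endpoints$age_group, .pop_column, character(1)) # validates labels

  paths <- lapply(cfg$cities, function(ci) ci$inputs)
  names(paths) <- vapply(cfg$cities, function(ci) ci$name, character(1))

  list(endpoints = endpoints, populations = pops, crfs = crfs, paths = paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
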