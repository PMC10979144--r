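# Shared builders for in-memory fixtures. Everything is generated in code;
# no binary files.

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# hourly series starting at a given instant, one value per hour
make_hourly <- function(values, start = "2019-01-01 00:00:00", name = "pm25") {
  ts <- as.POSIXct(start, tz = "UTC") + (seq_along(values) - 1) * 3600
  hourly_series(ts, values, name)
}

# daily series from a plain numeric vector
make_daily <- function(values, start = "2019-01-01", name = "pm25",
                       n_hours = 24L) {
  dates <- as.Date(start) + seq_along(values) - 1
  daily_series(dates, values, rep(n_hours, length(values)), name)
}

# brute-force attributable proportion: explicit loop over categories,
# recomputing the log-linear RR from first principles
ap_loop_oracle <- function(midpoints, proportions, rr, increment, cutoff) {
  num <- 0
  den <- 0
  for (i in seq_along(midpoints)) {
    excess <- max(0, midpoints[i] - cutoff)
    rr_c <- exp(log(rr) / increment * excess)
    num <- num + (rr_c - 1) * proportions[i]
    den <- den + rr_c * proportions[i]
  }
  num / den
}

# a minimal two-city YAML configuration written to a temp file
write_demo_config <- function(crf_for_natural = "allcause") {
  f <- tempfile(fileext = ".yml")
  writeLines(c(
    "cities:",
    "  - name: Arak",
    "    population: {total: 600000, age_30plus: 300000, age_25plus: 350000, age_under5: 45000}",
    "  - name: Ahvaz",
    "    population: {total: 1300000, age_30plus: 650000, age_25plus: 750000, age_under5: 100000}",
    "crfs:",
    "  - name: allcause",
    "    form: log_linear",
    "    rr: 1.062",
    "    rr_low: 1.04",
    "    rr_high: 1.083",
    "endpoints:",
    paste0("  - {city: Arak, name: natural, age_group: '30+', ",
      "baseline_incidence: 966.0, crf: ", crf_for_natural, "}"),
    "  - {city: Ahvaz, name: natural, age_group: '30+', baseline_incidence: 817.0, crf: allcause}"
  ), f)
  f
}
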