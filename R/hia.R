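#' Population attributable proportion over exposure categories
#'
#' Aggregates the attributable proportion over a categorical exposure
#' distribution:
#'
#'   AP = sum_c (RR(c) - 1) P(c)  /  sum_c RR(c) P(c)
#'
#' where `c` indexes concentration strata, `P(c)` is the fraction of the
#' population-time in stratum `c`, and RR is taken from the
#' concentration-response function. Evaluated separately at the low,
#' central and high RR curves. With a single category this reduces to the
#' familiar (RR - 1) / RR.
#'
#' @param categories Data frame with columns `midpoint` and `proportion`
#'   (as produced by [bin_distribution] or [annual_mean_category]);
#'   proportions must sum to 1.
#' @param spec A [crf_spec].
#' @return Named list `list(low =, central =, high =)` of AP fractions.
#' @export
attributable_proportion <- function(categories, spec) {
  if (is.null(categories) || nrow(categories) == 0L) {
    stop("empty-input error: no exposure categories")
  }
  stopifnot(all(c("midpoint", "proportion") %in% names(categories)))
  if (abs(sum(categories$proportion) - 1) > 1e-8) {
    stop("category proportions must sum to 1")
  }
  rr <- relative_risk(spec, categories$midpoint)
  ap_one <- function(r) {
    sum((r - 1) * categories$proportion) / sum(r * categories$proportion)
  }
  list(
    low = ap_one(rr$rr_low),
    central = ap_one(rr$rr_central),
    high = ap_one(rr$rr_high)
  )
}

#' Attributable rate per 100,000
#'
#' Scales a baseline incidence by the attributable proportion:
#' `IE = I * AP`, in cases per 100,000 at-risk persons per year.
#'
#' @param baseline_incidence `I`, cases per 100,000 per year (`>= 0`).
#' @param ap Attributable proportion, a fraction in `[0, 1)`.
#' @return Attributable cases per 100,000 (full precision; rounding is
#'   applied only at report emission).
#' @export
attributable_rate <- function(baseline_incidence, ap) {
  if (any(baseline_incidence < 0)) stop("baseline incidence must be >= 0")
  if (any(ap < 0 | ap >= 1)) stop("attributable proportion must lie in [0, 1)")
  baseline_incidence * ap
}

#' Excess cases in the at-risk population
#'
#' `NE = IE * N / 100,000`: the attributable rate (per 100,000) scaled to
#' the at-risk population size.
#'
#' @param ie Attributable rate, cases per 100,000.
#' @param n_at_risk At-risk population, persons (`>= 0`).
#' @return Expected number of excess cases (full precision).
#' @export
excess_cases <- function(ie, n_at_risk) {
  if (any(n_at_risk < 0)) stop("validation error: population must be >= 0")
  ie * n_at_risk / 1e5
}

#' Full health-impact assessment for a set of cities and endpoints
#'
#' Chains the exposure distribution, concentration-response function,
#' attributable proportion, attributable rate and excess cases for every
#' (city, endpoint) row of the endpoint table, carrying low/central/high
#' bounds through the whole chain. The endpoint's age group selects the
#' matching at-risk population count.
#'
#' @param exposures Named list, one [daily_series] per city.
#' @param endpoints Data frame `city, endpoint, age_group,
#'   baseline_incidence, crf` (see [read_config]).
#' @param populations Data frame `city, n_total, n_30plus, n_25plus,
#'   n_under5`.
#' @param crfs Named list of [crf_spec] objects.
#' @param mode `"binned"` evaluates AP over the binned daily distribution;
#'   `"annual_mean"` uses a single category at the annual mean.
#' @param bin_width Stratum width for `"binned"` mode (ug/m3).
#' @return Data frame with one row per (city, endpoint):
#'   `city, endpoint, n_at_risk, ap_low, ap, ap_high, ie_low, ie, ie_high,
#'   ne_low, ne, ne_high` — AP as fractions, IE per 100,000, NE in cases,
#'   all at full precision (see [format_impact_table] for report rounding).
#' @export
run_hia <- function(exposures, endpoints, populations, crfs,
                    mode = c("binned", "annual_mean"), bin_width = 1) {
  mode <- match.arg(mode)
  missing_city <- setdiff(endpoints$city, populations$city)
  if (length(missing_city)) {
    stop("configuration error: no population entry for city ",
      paste(missing_city, collapse = ", "))
  }
  missing_exp <- setdiff(endpoints$city, names(exposures))
  if (length(missing_exp)) {
    stop("configuration error: no exposure series for city ",
      paste(missing_exp, collapse = ", "))
  }

  cats_by_city <- lapply(exposures, function(d) {
    switch(mode,
      binned = bin_distribution(d, bin_width = bin_width),
      annual_mean = annual_mean_category(d)
    )
  })

  rows <- lapply(seq_len(nrow(endpoints)), function(i) {
    ep <- endpoints[i, ]
    spec <- crfs[[ep$crf]]
    if (is.null(spec)) {
      stop("configuration error: endpoint references undefined CRF '", ep$crf, "'")
    }
    ap <- attributable_proportion(cats_by_city[[ep$city]], spec)
    pop_row <- populations[populations$city == ep$city, ]
    n_at_risk <- pop_row[[.pop_column(ep$age_group)]]
    if (is.na(n_at_risk)) {
      stop("configuration error: city '", ep$city,
        "' lacks an at-risk count for age group ", ep$age_group)
    }
    ie <- lapply(ap, attributable_rate, baseline_incidence = ep$baseline_incidence)
    ne <- lapply(ie, excess_cases, n_at_risk = n_at_risk)
    data.frame(
      city = ep$city, endpoint = ep$endpoint, n_at_risk = n_at_risk,
      ap_low = ap$low, ap = ap$central, ap_high = ap$high,
      ie_low = ie$low, ie = ie$central, ie_high = ie$high,
      ne_low = ne$low, ne = ne$central, ne_high = ne$high
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round an impact table for reporting
#'
#' Applies the conventional report formatting: AP as a percentage with two
#' decimals, attributable rate per 100,000 with two decimals, excess cases
#' to the nearest whole case. The computation chain itself is never
#' rounded; use this only when emitting results.
#'
#' @param impacts Output of [run_hia].
#' @return Data frame with the same rows; `ap*` columns in percent.
#' @export
format_impact_table <- function(impacts) {
  out <- impacts
  for (col in c("ap_low", "ap", "ap_high")) out[[col]] <- round(100 * out[[col]], 2)
  for (col in c("ie_low", "ie", "ie_high")) out[[col]] <- round(out[[col]], 2)
  for (col in c("ne_low", "ne", "ne_high")) out[[col]] <- round(out[[col]])
  out
}
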