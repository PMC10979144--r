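one_cat <- function(conc) data.frame(midpoint = conc, proportion = 1)

test_that("single-category AP reduces to (RR - 1)/RR", {
  expect_equal(attributable_proportion(one_cat(30), crf_implied_ap(0))$central, 0)
  expect_equal(attributable_proportion(one_cat(30), crf_implied_ap(0.2))$central, 0.2)
  # RR = 1.25 as a one-increment log-linear curve
  spec <- crf_log_linear(1.25, increment = 10, cutoff = 10)
  expect_equal(attributable_proportion(one_cat(20), spec)$central, 0.2)
})

test_that("two-category AP matches the hand-evaluated category sum", {
  # RR = {1.1, 1.3}, P = {0.5, 0.5}: AP = 0.2/1.2
  cats <- data.frame(midpoint = c(20, 20), proportion = c(0.5, 0.5))
  spec_mix <- list(
    crf_log_linear(1.1, increment = 10, cutoff = 10),
    crf_log_linear(1.3, increment = 10, cutoff = 10)
  )
  rr <- c(1.1, 1.3)
  p <- c(0.5, 0.5)
  expected <- sum((rr - 1) * p) / sum(rr * p)
  expect_equal(expected, 0.2 / 1.2)
  # evaluate through the package: a curve hitting 1.1 and 1.3 at the two midpoints
  # log-linear with rr = 1.1 at 20 and compounding cannot hit 1.3 at another
  # grid point exactly, so check via two one-increment categories instead:
  got <- sapply(spec_mix, function(s) {
    relative_risk(s, 20)$rr_central
  })
  expect_equal(got, rr)
  num <- sum((got - 1) * p)
  den <- sum(got * p)
  expect_equal(num / den, 0.2 / 1.2) # = 0.166667
})

test_that("category-sum AP equals a brute-force loop oracle on random instances", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(1:12, 1)
    mid <- sort(runif(n, 0, 120))
    p <- as.numeric(rmultinom(1, 1000, runif(n))) / 1000
    rr <- runif(1, 1.0, 1.6)
    inc <- runif(1, 5, 20)
    c0 <- runif(1, 0, 15)
    spec <- crf_log_linear(rr, increment = inc, cutoff = c0)
    cats <- data.frame(midpoint = mid, proportion = p)
    got <- attributable_proportion(cats, spec)$central
    expect_equal(got, ap_loop_oracle(mid, p, rr, inc, c0), tolerance = 1e-12)
  }
})

test_that("AP rises strictly with the annual mean under an effect above 1", {
  spec <- crf_log_linear(1.062)
  means <- seq(12, 80, by = 4)
  aps <- sapply(means, function(m) {
    attributable_proportion(one_cat(m), spec)$central
  })
  expect_true(all(diff(aps) > 0))
})

test_that("attributable rate is baseline incidence times AP", {
  expect_equal(round(attributable_rate(817.0, 0.1232), 2), 100.65)
  expect_equal(round(attributable_rate(125.13, 0.1526), 2), 19.09)
  expect_equal(attributable_rate(500, 0), 0)
  expect_error(attributable_rate(-1, 0.1), ">= 0")
  expect_error(attributable_rate(100, 1.0), "\\[0, 1\\)")
})

test_that("excess cases scale the per-100,000 rate by the at-risk population", {
  expect_equal(excess_cases(50, 200000), 100)
  expect_equal(excess_cases(75, 0), 0)
  expect_error(excess_cases(10, -5), "validation error")
  # internal consistency: back-computed population returns the reported count
  ne <- 1092
  per100k <- 100.65
  n_back <- round(ne / per100k * 1e5)
  expect_equal(round(excess_cases(per100k, n_back)), ne)
})

test_that("empty category lists and proportion defects are rejected", {
  expect_error(
    attributable_proportion(data.frame(), crf_implied_ap(0.1)),
    "empty-input"
  )
  bad <- data.frame(midpoint = c(10, 20), proportion = c(0.5, 0.4))
  expect_error(attributable_proportion(bad, crf_implied_ap(0.1)), "sum to 1")
})

test_that("the full assessment chain reproduces known per-100,000 rates", {
  exposures <- list(
    Ahvaz = make_daily(rep(43.33, 5)),
    Arak = make_daily(rep(24.12, 5))
  )
  populations <- data.frame(
    city = c("Ahvaz", "Arak"),
    n_total = c(1300000, 600000), n_30plus = c(650000, 300000),
    n_25plus = c(750000, 350000), n_under5 = c(100000, 45000)
  )
  endpoints <- data.frame(
    city = c("Ahvaz", "Arak"),
    endpoint = c("ihd", "stroke"),
    age_group = c("25+", "25+"),
    baseline_incidence = c(155.06, 85.46),
    crf = c("ahvaz_ihd_ap", "arak_stroke_ap")
  )
  crfs <- list(
    ahvaz_ihd_ap = crf_implied_ap(0.1729),
    arak_stroke_ap = crf_implied_ap(0.146)
  )
  out <- run_hia(exposures, endpoints, populations, crfs, mode = "annual_mean")
  fmt <- format_impact_table(out)
  expect_equal(fmt$ie[fmt$city == "Ahvaz"], 26.81)
  expect_equal(fmt$ie[fmt$city == "Arak"], 12.48)
  expect_equal(fmt$ap[fmt$city == "Ahvaz"], 17.29)
  # zero attributable proportion kills the whole chain
  crfs0 <- list(ahvaz_ihd_ap = crf_implied_ap(0), arak_stroke_ap = crf_implied_ap(0))
  out0 <- run_hia(exposures, endpoints, populations, crfs0, mode = "annual_mean")
  expect_true(all(out0$ne == 0))
})

test_that("uncertainty ordering propagates through AP, IE and NE", {
  set.seed(32)
  d <- make_daily(rlnorm(200, 3.4, 0.4))
  spec <- crf_log_linear(1.062, 1.04, 1.083)
  exposures <- list(X = d)
  populations <- data.frame(
    city = "X", n_total = 1e6, n_30plus = 5e5, n_25plus = 6e5, n_under5 = 5e4
  )
  endpoints <- data.frame(
    city = "X", endpoint = "natural", age_group = "30+",
    baseline_incidence = 900, crf = "cf"
  )
  out <- run_hia(exposures, endpoints, populations, list(cf = spec), mode = "binned")
  expect_lte(out$ap_low, out$ap)
  expect_lte(out$ap, out$ap_high)
  expect_lte(out$ie_low, out$ie)
  expect_lte(out$ie, out$ie_high)
  expect_lte(out$ne_low, out$ne)
  expect_lte(out$ne, out$ne_high)
  expect_true(out$ap >= 0 && out$ap < 1)
  # binned and annual-mean modes agree to first order for a tight distribution
  tight <- list(X = make_daily(rep(35, 10)))
  b <- run_hia(tight, endpoints, populations, list(cf = spec),
    mode = "binned", bin_width = 0.1)
  a <- run_hia(tight, endpoints, populations, list(cf = spec), mode = "annual_mean")
  expect_lt(abs(b$ap - a$ap), 1e-3)
})

test_that("a city without population or exposure is a configuration error", {
  endpoints <- data.frame(
    city = "Nowhere", endpoint = "natural", age_group = "30+",
    baseline_incidence = 900, crf = "cf"
  )
  populations <- data.frame(
    city = "X", n_total = 1e6, n_30plus = 5e5, n_25plus = 6e5, n_under5 = 5e4
  )
  expect_error(
    run_hia(list(X = make_daily(1:5 + 20)), endpoints, populations,
      list(cf = crf_implied_ap(0.1))),
    "Nowhere"
  )
})
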