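#' Build the seasonal regression design
#'
#' Joins the daily PM2.5 response with daily meteorological covariates on
#' calendar date, adds a linear trend (days since the first retained date)
#' and 0/1 indicator columns for every calendar month present except the
#' reference month. Rows missing any covariate are dropped listwise and
#' counted.
#'
#' @param pm25 A [daily_series] of daily PM2.5 means (the response).
#' @param met Named list of [daily_series], one per covariate
#'   (e.g. temperature, relative humidity, wind direction, wind speed,
#'   pressure).
#' @param reference_month Month number (1-12) absorbed into the intercept.
#'   Defaults to the first calendar month appearing in the joined series.
#' @return An object of class `ts_design`: list with `data` (data frame
#'   `date, y, trend, <covariates...>, <month indicators...>`),
#'   `covariates`, `month_terms`, `reference_month`, `n_dropped_rows`.
#' @export
build_design <- function(pm25, met = list(), reference_month = NULL) {
  stopifnot(inherits(pm25, "daily_series"))
  if (length(met) && is.null(names(met))) stop("met must be a named list")

  dates <- pm25$dates
  for (m in met) dates <- dates[dates %in% m$dates]
  if (length(dates) == 0L) {
    stop("empty-design error: no dates shared by the response and all covariates")
  }
  dates <- sort(dates)
  n_dropped <- length(pm25$dates) - length(dates)

  df <- data.frame(
    date = dates,
    y = pm25$daily_mean[match(dates, pm25$dates)],
    trend = as.numeric(dates - dates[1L])
  )
  for (nm in names(met)) {
    df[[nm]] <- met[[nm]]$daily_mean[match(dates, met[[nm]]$dates)]
  }

  months_present <- as.integer(format(dates, "%m"))
  if (is.null(reference_month)) {
    reference_month <- months_present[1L]
  }
  stopifnot(reference_month %in% 1:12)
  month_terms <- character(0)
  for (m in sort(unique(months_present))) {
    if (m == reference_month) next
    term <- tolower(month.name[m])
    df[[term]] <- as.integer(months_present == m)
    month_terms <- c(month_terms, term)
  }

  structure(
    list(
      data = df,
      covariates = names(met),
      month_terms = month_terms,
      reference_month = reference_month,
      n_dropped_rows = n_dropped
    ),
    class = "ts_design"
  )
}

#' @export
print.ts_design <- function(x, ...) {
  cat(sprintf(
    "<ts_design: %d days, %d covariates, %d month indicators (reference %s), %d rows dropped>\n",
    nrow(x$data), length(x$covariates), length(x$month_terms),
    month.name[x$reference_month], x$n_dropped_rows
  ))
  invisible(x)
}

.design_matrix <- function(design) {
  terms <- c(design$covariates, "trend", design$month_terms)
  X <- cbind(`(Intercept)` = 1, as.matrix(design$data[, terms, drop = FALSE]))
  X
}

#' Fit the seasonal linear model by ordinary least squares
#'
#' Fits `y ~ covariates + trend + month indicators` by OLS (QR
#' decomposition via [stats::lm]). Standard errors come from
#' sigma^2 (X'X)^-1 with sigma^2 = RSS / (n - p); p-values are two-sided
#' from the t distribution with n - p degrees of freedom.
#'
#' @param design A `ts_design` from [build_design].
#' @return An object of class `regression_fit`: list with `coefficients`
#'   (data frame `term, estimate, se, t, p`), `sigma2`, `r_squared`,
#'   `n_used`, `df_residual`, and the underlying `lm` object.
#' @export
fit_ols <- function(design) {
  stopifnot(inherits(design, "ts_design"))
  X <- .design_matrix(design)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dependent <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("collinearity error: design matrix is rank deficient; dependent columns: ",
      paste(dependent, collapse = ", "))
  }
  if (nrow(X) < ncol(X) + 1L) {
    stop("too few rows to estimate ", ncol(X), " parameters with a residual df")
  }
  rhs_terms <- setdiff(colnames(X), "(Intercept)")
  fml <- stats::reformulate(
    if (length(rhs_terms)) sprintf("`%s`", rhs_terms) else "1",
    response = "y"
  )
  fit <- stats::lm(fml, data = design$data)
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(
    term = sub("^`|`$", "", rownames(ct)),
    estimate = ct[, 1], se = ct[, 2], t = ct[, 3], p = ct[, 4],
    row.names = NULL
  )
  tss <- sum((design$data$y - mean(design$data$y))^2)
  structure(
    list(
      coefficients = coefs,
      sigma2 = sm$sigma^2,
      r_squared = if (tss > 0) sm$r.squared else 0,
      n_used = nrow(X),
      df_residual = fit$df.residual,
      lm = fit
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit: n = %d, residual df = %d, R^2 = %.4f>\n",
    x$n_used, x$df_residual, x$r_squared
  ))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' 95% confidence intervals for a fitted model
#'
#' @param fit A `regression_fit`.
#' @param level Confidence level (default 0.95).
#' @return Data frame `term, lower, upper`.
#' @export
confint_fit <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "regression_fit"))
  q <- stats::qt(1 - (1 - level) / 2, df = fit$df_residual)
  with(fit$coefficients, data.frame(
    term = term, lower = estimate - q * se, upper = estimate + q * se
  ))
}

#' Rounded coefficient report
#'
#' Emits the conventional Est/SE/P report: rows ordered covariates, trend,
#' months (intercept first), estimates and standard errors rounded to two
#' decimals, p-values to three.
#'
#' @param fit A `regression_fit`.
#' @param covariates,month_terms Optional explicit term ordering; by
#'   default inferred from the coefficient names.
#' @return Data frame `term, est, se, p`.
#' @export
coefficient_table <- function(fit, covariates = NULL, month_terms = NULL) {
  stopifnot(inherits(fit, "regression_fit"))
  cf <- fit$coefficients
  months <- tolower(month.name)
  if (is.null(month_terms)) month_terms <- intersect(months, cf$term)
  if (is.null(covariates)) {
    covariates <- setdiff(cf$term, c("(Intercept)", "trend", month_terms))
  }
  ordering <- c("(Intercept)", covariates, intersect("trend", cf$term), month_terms)
  cf <- cf[match(ordering, cf$term), ]
  data.frame(
    term = cf$term,
    est = round(cf$estimate, 2),
    se = round(cf$se, 2),
    p = round(cf$p, 3),
    row.names = NULL
  )
}
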