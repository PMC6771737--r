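#' Construct a daily climate series
#'
#' @param dates `Date` vector, strictly increasing and gap-free (gaps are
#'   allowed only in the values, as `NA`).
#' @param values Numeric values, `NA` for missing days.
#' @param variable_name Label, e.g. `"precip"`.
#' @return A `"daily_climate"` data frame with columns `date`, `value`.
#' @export
daily_climate <- function(dates, values, variable_name = "climate") {
  dates <- as.Date(dates)
  if (length(dates) != length(values)) stop("dates and values differ in length")
  if (length(dates) > 1) {
    d <- diff(as.integer(dates))
    if (any(d <= 0)) stop("dates must be strictly increasing")
    if (any(d != 1)) stop("date axis must be contiguous (no calendar gaps)")
  }
  structure(data.frame(date = dates, value = as.numeric(values)),
            variable_name = variable_name,
            class = c("daily_climate", "data.frame"))
}

#' Fill missing days of a daily climate series by linear interpolation
#'
#' Missing runs are filled by linear interpolation on the date axis;
#' observed values are untouched. Missing values at either end are
#' extended with the nearest observed value. Interpolated values always
#' lie between the bracketing observations.
#'
#' @param series A `"daily_climate"` series.
#' @return The series with no missing values.
#' @export
interpolate_missing <- function(series) {
  v <- series$value
  ok <- !is.na(v)
  if (!any(ok)) stop("unrecoverable series: all values are missing")
  if (all(ok)) return(series)
  if (sum(ok) == 1) {          # single observation: nearest-value extension
    series$value <- rep(v[ok], length(v))
    return(series)
  }
  x <- as.numeric(series$date)
  series$value <- approx(x[ok], v[ok], xout = x, method = "linear",
                         rule = 2)$y
  series
}

# 14-day block boundaries for study year t: blocks start at Jan 1 of t-1;
# block 42 is truncated at Jul 31 of t. Always 42 windows regardless of
# leap days (the truncated final block absorbs calendar length).
fortnight_starts <- function(year) {
  as.Date(sprintf("%d-01-01", year - 1)) + 14L * (0:41)
}

#' Aggregate a daily series into year x lag-window means
#'
#' For study year t, the fortnight scheme averages consecutive 14-day
#' blocks starting 1 January of t-1 (window 1) with the final 42nd block
#' truncated at 31 July of t; the month scheme averages the 19 calendar
#' months January t-1 through July t.
#'
#' @param series A gap-free `"daily_climate"` series covering 1 January of
#'   `min(study_years) - 1` through 31 July of `max(study_years)`.
#' @param study_years Integer vector of study-year labels.
#' @param scheme `"fortnight"` (42 windows) or `"month"` (19 windows).
#' @return A `"climate_matrix"`: list with `values` (year x window
#'   matrix), `years`, `scheme`, `centered = FALSE`, `variable_name`.
#' @export
aggregate_windows <- function(series, study_years,
                              scheme = c("fortnight", "month")) {
  scheme <- match.arg(scheme)
  if (anyNA(series$value))
    stop("series has missing values; run interpolate_missing() first")
  study_years <- sort(as.integer(study_years))
  first <- as.Date(sprintf("%d-01-01", study_years[1] - 1))
  dmin <- min(series$date); dmax <- max(series$date)
  n_w <- if (scheme == "fortnight") 42L else 19L
  rows <- lapply(study_years, function(t) {
    last <- as.Date(sprintf("%d-07-31", t))
    if (dmin > as.Date(sprintf("%d-01-01", t - 1)) || dmax < last)
      stop("insufficient date coverage for study year ", t)
    if (scheme == "fortnight") {
      starts <- fortnight_starts(t)
      ends <- c(starts[-1] - 1L, last)
      vapply(seq_len(42L), function(w) {
        sel <- series$date >= starts[w] & series$date <= ends[w]
        mean(series$value[sel])
      }, numeric(1))
    } else {
      months <- seq(as.Date(sprintf("%d-01-01", t - 1)), by = "month",
                    length.out = 19L)
      vapply(seq_len(19L), function(w) {
        m0 <- months[w]
        m1 <- if (w < 19L) months[w + 1] - 1L else last
        sel <- series$date >= m0 & series$date <= m1
        mean(series$value[sel])
      }, numeric(1))
    }
  })
  values <- do.call(rbind, rows)
  dimnames(values) <- list(study_years, paste0("w", seq_len(n_w)))
  structure(list(values = values, years = study_years, scheme = scheme,
                 centered = FALSE,
                 variable_name = attr(series, "variable_name")),
            class = "climate_matrix")
}

#' Build a monthly-index climate matrix (e.g. NAO)
#'
#' Arranges a monthly large-scale index into the 19-window year x lag
#' matrix (January t-1 through July t) consumed by the monthly-index FLM.
#'
#' @param index Data frame with columns `year`, `month`, `value`.
#' @param study_years Integer study-year labels.
#' @return An uncentered `"climate_matrix"` with 19 windows.
#' @export
aggregate_monthly_index <- function(index, study_years) {
  study_years <- sort(as.integer(study_years))
  key <- paste(index$year, index$month)
  rows <- lapply(study_years, function(t) {
    yy <- c(rep(t - 1, 12), rep(t, 7))
    mm <- c(1:12, 1:7)
    v <- index$value[match(paste(yy, mm), key)]
    if (anyNA(v)) stop("insufficient monthly coverage for study year ", t)
    v
  })
  values <- do.call(rbind, rows)
  dimnames(values) <- list(study_years, paste0("w", 1:19))
  structure(list(values = values, years = study_years, scheme = "month",
                 centered = FALSE, variable_name = "index"),
            class = "climate_matrix")
}

#' Remove seasonality from a climate matrix by centering each window
#'
#' Subtracts each lag window's across-study-year mean, leaving the
#' interannual anomalies `C_tw`. The seasonal component is constant across
#' years and cannot explain interannual demographic variation; removing it
#' aids sampler convergence. Centering an already centered matrix is
#' rejected rather than silently reapplied.
#'
#' @param matrix A `"climate_matrix"` with `centered = FALSE` and at least
#'   two study years.
#' @return The centered matrix (every column mean is zero to within
#'   `1e-12` of the data scale).
#' @export
center_windows <- function(matrix) {
  if (!inherits(matrix, "climate_matrix")) stop("not a climate_matrix")
  if (isTRUE(matrix$centered)) stop("matrix is already centered")
  if (nrow(matrix$values) < 2)
    stop("degenerate centering: a single-year matrix would be all zeros")
  matrix$values <- scale(matrix$values, center = TRUE, scale = FALSE)[, ,
                                                                     drop = FALSE]
  attr(matrix$values, "scaled:center") <- NULL
  matrix$centered <- TRUE
  matrix
}

#' Scalar reference climate covariates
#'
#' Computes the a-priori-window reference covariates: `winter_nao` is the
#' December (t-1) to March (t) mean of a monthly index; `march_precip` is
#' the mean daily value over March of year t. The covariate is
#' standardized (mean 0, SD 1 across study years) before model entry so
#' the slope prior is scale-free.
#'
#' @param x For `winter_nao`, a data frame with columns `year`, `month`,
#'   `value`; for `march_precip`, a gap-free `"daily_climate"` series.
#' @param rule `"winter_nao"` or `"march_precip"`.
#' @param study_years Integer study-year labels.
#' @return Data frame with columns `year`, `raw` (pre-standardization
#'   mean) and `value` (standardized covariate).
#' @export
scalar_covariate <- function(x, rule = c("winter_nao", "march_precip"),
                             study_years) {
  rule <- match.arg(rule)
  study_years <- sort(as.integer(study_years))
  raw <- vapply(study_years, function(t) {
    if (rule == "winter_nao") {
      key <- paste(x$year, x$month)
      v <- x$value[match(c(paste(t - 1, 12), paste(t, 1:3)), key)]
      if (anyNA(v)) stop("missing monthly index values for study year ", t)
      mean(v)
    } else {
      if (anyNA(x$value)) stop("series has missing values")
      sel <- x$date >= as.Date(sprintf("%d-03-01", t)) &
        x$date <= as.Date(sprintf("%d-03-31", t))
      if (!any(sel)) stop("no March coverage for study year ", t)
      mean(x$value[sel])
    }
  }, numeric(1))
  s <- sd(raw)
  std <- if (!is.na(s) && s > 0) (raw - mean(raw)) / s else rep(0, length(raw))
  data.frame(year = study_years, raw = raw, value = std)
}
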