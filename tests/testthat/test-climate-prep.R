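mk_series <- function(values, start = "2000-01-01") {
  daily_climate(seq(as.Date(start), by = "day", length.out = length(values)),
                values, "test")
}

test_that("linear interpolation fills gaps and keeps observations", {
  expect_equal(interpolate_missing(mk_series(c(2, NA, 4)))$value, c(2, 3, 4))
  expect_equal(interpolate_missing(mk_series(c(1, NA, NA, 7)))$value,
               c(1, 3, 5, 7))
  s <- mk_series(c(1, 2, 3))
  expect_identical(interpolate_missing(s)$value, s$value)
  expect_error(interpolate_missing(mk_series(c(NA, NA))), "unrecoverable")
  # missing ends extended with the nearest observation
  expect_equal(interpolate_missing(mk_series(c(NA, 5, NA)))$value, c(5, 5, 5))
})

test_that("interpolated values stay within the bracketing observations", {
  set.seed(31)
  for (r in 1:20) {
    v <- rnorm(60)
    gap <- sort(sample(2:59, 10))
    vg <- v; vg[gap] <- NA
    out <- interpolate_missing(mk_series(vg))$value
    for (j in gap) {
      lo <- max(which(!is.na(vg[1:(j - 1)])))
      hi <- j + min(which(!is.na(vg[(j + 1):60])))
      expect_gte(out[j], min(vg[lo], vg[hi]) - 1e-12)
      expect_lte(out[j], max(vg[lo], vg[hi]) + 1e-12)
    }
  }
})

test_that("window schemes give 42 fortnights / 19 months, leap years included", {
  # span covering leap year 2000
  days <- seq(as.Date("1999-01-01"), as.Date("2001-07-31"), by = "day")
  s <- daily_climate(days, rep(7, length(days)), "const")
  for (yrs in list(2000L, 2000:2001)) {
    m <- aggregate_windows(s, yrs, "fortnight")
    expect_equal(ncol(m$values), 42L)
    expect_true(all(m$values == 7))
    mm <- aggregate_windows(s, yrs, "month")
    expect_equal(ncol(mm$values), 19L)
    expect_true(all(mm$values == 7))
  }
  expect_error(aggregate_windows(s, 2002L, "fortnight"), "2002")
})

test_that("fortnight means are plain arithmetic means of 14-day blocks", {
  days <- seq(as.Date("1999-01-01"), as.Date("2000-07-31"), by = "day")
  v <- rep(0, length(days)); v[1:28] <- 1:28
  m <- aggregate_windows(daily_climate(days, v, "x"), 2000L, "fortnight")
  expect_equal(unname(m$values[1, 1:2]), c(7.5, 21.5))
})

test_that("centering removes each window's across-year mean", {
  days <- seq(as.Date("1999-01-01"), as.Date("2003-07-31"), by = "day")
  set.seed(8)
  s <- daily_climate(days, rnorm(length(days), 10, 3), "x")
  m <- aggregate_windows(s, 2000:2003, "fortnight")
  cm <- center_windows(m)
  expect_true(cm$centered)
  expect_lt(max(abs(colMeans(cm$values))), 1e-12)
  expect_error(center_windows(cm), "already centered")
  # hand example: two years with window values 3 and 5
  m2 <- m; m2$values <- matrix(c(3, 5), 2, 1); m2$years <- 2000:2001
  expect_equal(as.numeric(center_windows(m2)$values), c(-1, 1))
  m1 <- m; m1$values <- m$values[1, , drop = FALSE]
  expect_error(center_windows(m1), "single-year|degenerate")
})

test_that("scalar reference covariates follow their window rules", {
  idx <- expand.grid(month = 1:12, year = 1999:2003)
  idx$value <- 2
  cov <- scalar_covariate(idx, "winter_nao", 2000:2003)
  expect_equal(cov$raw, rep(2, 4))
  expect_equal(cov$value, rep(0, 4))  # constant index -> all-zero covariate

  # hand-built 4-month winter index 1,2,3,4 -> mean 2.5
  idx2 <- data.frame(year = c(1999, 2000, 2000, 2000), month = c(12, 1, 2, 3),
                     value = 1:4)
  idx2 <- rbind(idx2, data.frame(year = c(2000, 2001, 2001, 2001),
                                 month = c(12, 1, 2, 3), value = c(5, 6, 7, 8)))
  cov2 <- scalar_covariate(idx2, "winter_nao", 2000:2001)
  expect_equal(cov2$raw, c(2.5, 6.5))
  expect_equal(sd(cov2$value), 1)

  days <- seq(as.Date("1999-01-01"), as.Date("2000-07-31"), by = "day")
  v <- rep(1, length(days))
  v[format(days, "%Y-%m") == "2000-03"] <- 2
  mp <- scalar_covariate(daily_climate(days, v, "precip"), "march_precip", 2000L)
  expect_equal(mp$raw, 2)
  expect_error(scalar_covariate(idx, "winter_nao", 2005L), "2005")
})

test_that("a monthly index arranges into the 19-window lag matrix", {
  idx <- expand.grid(month = 1:12, year = 1999:2001)
  idx$value <- idx$year * 100 + idx$month
  m <- aggregate_monthly_index(idx, 2000:2001)
  expect_equal(dim(m$values), c(2L, 19L))
  expect_equal(unname(m$values[1, 1]), 199901)   # January of t-1
  expect_equal(unname(m$values[1, 19]), 200007)  # July of t
  expect_error(aggregate_monthly_index(idx, 2002L), "2002")
})
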