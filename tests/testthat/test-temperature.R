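make_series <- function(df) {
  class(df) <- c("station_series", "data.frame")
  df
}

test_that("summer means average April-September and drop incomplete years", {
  df <- expand.grid(month = 1:12, year = 2000, station_id = "s1",
                    stringsAsFactors = FALSE)
  df$altitude_m <- 400
  df$mean_temp_c <- 10
  expect_equal(summer_mean(make_series(df))$value, 10)

  df$mean_temp_c[df$month %in% 4:9] <- c(8, 10, 12, 14, 12, 10)
  expect_equal(summer_mean(make_series(df))$value, 11)

  # missing July drops the station-year with a warning
  df_nojul <- df[df$month != 7, ]
  expect_warning(out <- summer_mean(make_series(df_nojul)), "incomplete")
  expect_equal(nrow(out), 0L)
})

test_that("coldest month is the minimum monthly mean", {
  df <- expand.grid(month = 1:12, year = 2001, station_id = "s1",
                    stringsAsFactors = FALSE)
  df$altitude_m <- 800
  df$mean_temp_c <- c(-5, -3, 0, 3, 8, 12, 15, 14, 10, 5, 0, -4)
  expect_equal(coldest_month_mean(make_series(df))$value, -5)

  df$mean_temp_c <- rep(7, 12)
  expect_equal(coldest_month_mean(make_series(df))$value, 7)

  # brute-force minimum over the record list
  set.seed(601)
  df$mean_temp_c <- rnorm(12, 5, 6)
  expect_equal(coldest_month_mean(make_series(df))$value, min(df$mean_temp_c))

  expect_error(coldest_month_mean(make_series(transform(df, month = 13))),
               "1..12")
})

test_that("LMM with variances pinned to zero reduces to pooled OLS", {
  st <- generate_station_series(5, 2000:2007, seed = 611)
  sm <- summer_mean(st)
  f0 <- fit_temperature_lmm(sm, ranef_variances = c(0, 0))
  yr <- sm$year - min(sm$year)
  ols <- lm(value ~ altitude_m * yr, data = sm)
  expect_equal(unname(f0$coefficients$estimate),
               unname(coef(ols)[c(1, 2, 3, 4)]), tolerance = 1e-8)
  expect_equal(unname(f0$varcomp[c("station", "year")]), c(0, 0))
})

test_that("REML log-likelihood matches the dense contrast oracle", {
  # 3 stations x 4 years toy series
  st <- generate_station_series(3, 2000:2003, noise_sd = 0.4,
                                station_sd = 0.5, year_sd = 0.3, seed = 621)
  sm <- summer_mean(st)
  f <- fit_temperature_lmm(sm)
  Zs <- f$Zs; Zy <- f$Zy
  Sigma <- f$varcomp["station"] * tcrossprod(Zs) +
    f$varcomp["year"] * tcrossprod(Zy) +
    f$varcomp["residual"] * diag(f$n)
  expect_equal(f$logLik, reml_contrast_loglik(f$X, f$y, Sigma),
               tolerance = 1e-8)

  # marginal variance of one observation = sum of the three components
  expect_equal(unname(diag(Sigma)[1]), unname(sum(f$varcomp)),
               tolerance = 1e-12)
})

test_that("LMM agrees with the reference implementation", {
  st <- generate_station_series(14, 1995:2010, trend_per_year = 0.07,
                                seed = 631)
  sm <- summer_mean(st)
  f <- fit_temperature_lmm(sm)
  sm$yr <- sm$year - min(sm$year)
  sm$alt <- sm$altitude_m
  ref <- suppressWarnings(
    lme4::lmer(value ~ alt * yr + (1 | station_id) + (1 | year),
               data = sm, REML = TRUE))
  fe <- lme4::fixef(ref)[c("(Intercept)", "alt", "yr", "alt:yr")]
  expect_equal(unname(f$coefficients$estimate), unname(fe), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(unname(f$varcomp["station"]),
               vc$vcov[vc$grp == "station_id"], tolerance = 1e-5)
  expect_equal(unname(f$varcomp["year"]),
               vc$vcov[vc$grp == "year"], tolerance = 1e-5)
  expect_equal(unname(f$varcomp["residual"]),
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-5)
})

test_that("the generating trend is recovered at the monitoring design size", {
  st <- generate_station_series(14, 1995:2010, trend_per_year = 0.07,
                                seed = 641)
  f <- fit_temperature_lmm(summer_mean(st))
  expect_lt(abs(f$coefficients["trend", "estimate"] - 0.07), 0.03)
})

test_that("null trend t-statistics are approximately calibrated", {
  big_t <- logical(60)
  for (i in seq_len(60)) {
    st <- generate_station_series(8, 2000:2007, trend_per_year = 0,
                                  noise_sd = 0.4, station_sd = 0.4,
                                  year_sd = 0.25, seed = 700 + i)
    f <- fit_temperature_lmm(summer_mean(st))
    big_t[i] <- abs(f$coefficients["trend", "t"]) > 2
  }
  # residual-df t reference is approximate; allow modest inflation
  expect_lte(mean(big_t), 0.15)
})

test_that("single-year series pin the year variance with a warning", {
  df <- expand.grid(month = 1:12, year = 2005,
                    station_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  df$altitude_m <- c(300, 900, 1500)[match(df$station_id, c("a", "b", "c"))]
  set.seed(651)
  df$mean_temp_c <- 12 - 0.005 * df$altitude_m + rnorm(nrow(df), 0, 0.3)
  sm <- summer_mean(make_series(df))
  expect_warning(f <- fit_temperature_lmm(sm), "pinned")
  expect_equal(unname(f$varcomp["year"]), 0)
})
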