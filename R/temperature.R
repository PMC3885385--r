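#' Summer (April-September) mean temperature per station-year
#'
#' The mean of the six monthly means from April to September. Station-years
#' missing any of the six months are dropped with a warning.
#'
#' @param series A `station_series` data.frame (`station_id`, `altitude_m`,
#'   `year`, `month`, `mean_temp_c`).
#' @return data.frame with `station_id`, `altitude_m`, `year`, `value`.
#' @export
summer_mean <- function(series) {
  .station_year_aggregate(series, months = 4:9, require_all = TRUE,
                          fun = mean, label = "summer mean")
}

#' Coldest-month mean temperature per station-year
#'
#' The minimum of the monthly mean temperatures within each calendar year;
#' any number of available months >= 1 is accepted.
#'
#' @inheritParams summer_mean
#' @return data.frame with `station_id`, `altitude_m`, `year`, `value`.
#' @export
coldest_month_mean <- function(series) {
  .station_year_aggregate(series, months = 1:12, require_all = FALSE,
                          fun = min, label = "coldest month")
}

.station_year_aggregate <- function(series, months, require_all, fun, label) {
  stopifnot(all(c("station_id", "altitude_m", "year", "month",
                  "mean_temp_c") %in% names(series)))
  if (any(series$month < 1 | series$month > 12)) {
    stop("months must lie in 1..12", call. = FALSE)
  }
  if (anyDuplicated(series[c("station_id", "year", "month")])) {
    stop("duplicate station-year-month records", call. = FALSE)
  }
  sub <- series[series$month %in% months, , drop = FALSE]
  key <- interaction(sub$station_id, sub$year, drop = TRUE)
  n_months <- tapply(sub$month, key, length)
  value <- tapply(sub$mean_temp_c, key, fun)
  first <- !duplicated(key)
  out <- data.frame(station_id = sub$station_id[first],
                    altitude_m = sub$altitude_m[first],
                    year = sub$year[first],
                    stringsAsFactors = FALSE)
  out$value <- as.numeric(value[match(interaction(out$station_id, out$year,
                                                  drop = TRUE), names(value))])
  if (require_all) {
    incomplete <- as.numeric(n_months[match(
      interaction(out$station_id, out$year, drop = TRUE),
      names(n_months))]) < length(months)
    if (any(incomplete)) {
      warning(sum(incomplete), " station-year(s) dropped from ", label,
              ": incomplete months", call. = FALSE)
      out <- out[!incomplete, , drop = FALSE]
    }
  }
  out <- out[order(out$station_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# REML/ML log-likelihood of y = X beta + station + year + e with crossed
# random intercepts, profiling beta and the residual scale. V(phi) =
# I + phi_s Zs Zs' + phi_y Zy Zy' (phi = variance ratios); dense Cholesky —
# the station x year layout keeps n small.
.lmm_objective <- function(log_phi, X, y, Zs, Zy, method, fixed_phi) {
  phi <- exp(log_phi)
  phi_s <- if (is.na(fixed_phi[1])) phi[1] else fixed_phi[1]
  phi_y <- if (is.na(fixed_phi[2])) phi[if (is.na(fixed_phi[1])) 2 else 1] else
    fixed_phi[2]
  n <- length(y)
  p <- ncol(X)
  V <- diag(n) + phi_s * tcrossprod(Zs) + phi_y * tcrossprod(Zy)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  ldet_V <- 2 * sum(log(diag(ch)))
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  xtvx <- crossprod(Xi)
  beta <- solve(xtvx, crossprod(Xi, yi))
  r <- yi - Xi %*% beta
  rss <- sum(r^2)
  if (method == "ML") {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * s2) + 1) + ldet_V)
  } else {
    s2 <- rss / (n - p)
    ldet_xtvx <- determinant(xtvx, logarithm = TRUE)$modulus
    ldet_xtx <- determinant(crossprod(X), logarithm = TRUE)$modulus
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + ldet_V +
                    ldet_xtvx - ldet_xtx)
  }
  list(logLik = as.numeric(ll), beta = beta, sigma2 = s2,
       phi_s = phi_s, phi_y = phi_y, xtvx = xtvx)
}

#' Mixed model for altitude-dependence of temperature trends
#'
#' Fits, by direct REML maximization of the Gaussian marginal likelihood,
#' the linear mixed model
#' `value ~ altitude + trend + altitude:trend + (1 | station) + (1 | year)`
#' where `trend` is the year centred at the first year of the window, so the
#' trend coefficient is in degrees C per year and the interaction in degrees
#' C per year per metre. Station and year enter as crossed random
#' intercepts; the covariance matrix is built densely (stations x years rows)
#' and profiled over beta and the residual scale. Fixed-effect t statistics
#' are estimate/SE with an approximate t reference on n - p degrees of
#' freedom.
#'
#' @param values Output of [summer_mean()] or [coldest_month_mean()]:
#'   `station_id`, `altitude_m`, `year`, `value`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param ranef_variances Optional length-2 numeric `c(station, year)` fixing
#'   random-intercept variances (on the variance scale) instead of
#'   estimating them; `NA` entries are estimated. `c(0, 0)` reduces the fit
#'   to pooled OLS.
#' @return A list of class `lmm_fit`: `coefficients` (with `se`, `t`, `p`),
#'   `varcomp` (station, year, residual variances), `logLik`, `method`,
#'   `n`, plus the model matrices.
#' @export
fit_temperature_lmm <- function(values, method = c("REML", "ML"),
                                ranef_variances = c(NA_real_, NA_real_)) {
  method <- match.arg(method)
  stopifnot(all(c("station_id", "altitude_m", "year", "value") %in%
                  names(values)))
  stations <- factor(values$station_id)
  years <- factor(values$year)
  if (nlevels(stations) < 2L) stop("need >= 2 stations", call. = FALSE)
  if (nlevels(years) == 1L) {
    if (is.na(ranef_variances[2])) {
      ranef_variances[2] <- 0
      warning("single year: year variance unidentifiable, pinned to 0",
              call. = FALSE)
    }
  } else if (nlevels(years) < 3L) {
    stop("need >= 3 years (or exactly 1, with the year variance pinned)",
         call. = FALSE)
  }
  yr <- values$year - min(values$year)
  X <- if (nlevels(years) == 1L) {
    # trend terms are unidentifiable from one year of data
    cbind(`(Intercept)` = 1, altitude = values$altitude_m)
  } else {
    cbind(`(Intercept)` = 1, altitude = values$altitude_m, trend = yr,
          `altitude:trend` = values$altitude_m * yr)
  }
  y <- values$value
  # indicator matrices built directly (model.matrix rejects single-level
  # factors, which the single-year path must tolerate)
  Zs <- outer(as.integer(stations), seq_len(nlevels(stations)), `==`) * 1
  Zy <- outer(as.integer(years), seq_len(nlevels(years)), `==`) * 1
  n <- length(y)
  p <- ncol(X)

  # fixed_phi holds variance *ratios* (variance / residual variance); a
  # user-supplied absolute variance of 0 is the only case where ratio = 0.
  fixed_phi <- c(NA_real_, NA_real_)
  if (!is.na(ranef_variances[1]) && ranef_variances[1] == 0) fixed_phi[1] <- 0
  if (!is.na(ranef_variances[2]) && ranef_variances[2] == 0) fixed_phi[2] <- 0
  if (any(!is.na(ranef_variances) & ranef_variances > 0)) {
    stop("only 0 or NA supported in `ranef_variances`", call. = FALSE)
  }
  n_free <- sum(is.na(fixed_phi))

  if (n_free == 0L) {
    best <- .lmm_objective(numeric(0), X, y, Zs, Zy, method, fixed_phi)
    log_phi <- numeric(0)
  } else {
    negll <- function(lp) {
      o <- .lmm_objective(lp, X, y, Zs, Zy, method, fixed_phi)
      if (is.null(o)) return(1e10)
      -o$logLik
    }
    lower <- rep(-15, n_free); upper <- rep(15, n_free)
    opt <- stats::optim(rep(0, n_free), negll, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1e4))
    if (opt$value >= 1e10) stop("mixed-model optimization failed", call. = FALSE)
    log_phi <- opt$par
    best <- .lmm_objective(log_phi, X, y, Zs, Zy, method, fixed_phi)
    pinned <- log_phi <= lower + 1e-6
    if (any(pinned)) {
      message("random-effect variance estimated at the zero boundary; ",
              "reported as 0")
      if (is.na(fixed_phi[1]) && pinned[1]) best$phi_s <- 0
      if (is.na(fixed_phi[2]) && pinned[n_free]) best$phi_y <- 0
    }
  }

  sigma2 <- best$sigma2
  vcov_beta <- sigma2 * solve(best$xtvx)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  est <- stats::setNames(as.numeric(best$beta), colnames(X))
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), n - p, lower.tail = FALSE)

  structure(list(
    coefficients = data.frame(estimate = est, se = se, t = tval, p = pval),
    varcomp = c(station = best$phi_s * sigma2, year = best$phi_y * sigma2,
                residual = sigma2),
    logLik = best$logLik,
    vcov = vcov_beta,
    method = method,
    n = n, p = p,
    n_stations = nlevels(stations), n_years = nlevels(years),
    X = X, y = y, Zs = Zs, Zy = Zy
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Crossed random-intercept LMM (", x$method, "), n = ", x$n,
      " (", x$n_stations, " stations x ", x$n_years, " years)\n", sep = "")
  cat("Variance components: station ", signif(x$varcomp["station"], 4),
      ", year ", signif(x$varcomp["year"], 4),
      ", residual ", signif(x$varcomp["residual"], 4), "\n", sep = "")
  cat("logLik (", x$method, "): ", format(x$logLik, digits = 8), "\n\n",
      sep = "")
  print(signif(as.matrix(x$coefficients), 4))
  invisible(x)
}
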