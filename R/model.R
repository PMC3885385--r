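#' Fixed-effect specification for the shift-altitude model
#'
#' The model regresses standardized shifts (m) on polynomials of centred
#' altitude plus, optionally, the raw altitudinal range within a square.
#' Altitude is centred at 500 m so the intercept is the predicted shift for a
#' community at 500 m. The polynomial hierarchy is enforced: a cubic term
#' implies the quadratic and linear terms.
#'
#' @param altitude_degree Polynomial degree of altitude, 0-3.
#' @param include_range Include the altitudinal-range covariate?
#' @param center Centering offset for altitude (m).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(altitude_degree = 3L, include_range = TRUE,
                       center = 500) {
  altitude_degree <- as.integer(altitude_degree)
  if (altitude_degree < 0L || altitude_degree > 3L) {
    stop("`altitude_degree` must be 0, 1, 2 or 3", call. = FALSE)
  }
  structure(list(altitude_degree = altitude_degree,
                 include_range = isTRUE(include_range),
                 center = center),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  terms <- c("(Intercept)",
             c("alt", "alt2", "alt3")[seq_len(x$altitude_degree)],
             if (x$include_range) "range")
  cat("Model spec: shift_m ~ ", paste(terms, collapse = " + "),
      "  (altitude centred at ", x$center, " m)\n", sep = "")
  invisible(x)
}

#' Build the design matrix and response for a shift-altitude model
#'
#' @param changes A `standardized_changes` table.
#' @param spec A [model_spec()].
#' @return List with `X` (design matrix: intercept, centred-altitude
#'   polynomials, raw range), `y` (shifts, m), `richness` (variance
#'   covariate), and `spec`.
#' @export
build_design <- function(changes, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("altitude_m", "shift_m",
            if (spec$include_range) "altitudinal_range_m")
  bad <- changes$square_id[!stats::complete.cases(changes[need])]
  if (length(bad) > 0L) {
    stop("missing covariates for square(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  a <- changes$altitude_m - spec$center
  X <- matrix(1, nrow(changes), 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$altitude_degree >= 1L) X <- cbind(X, alt = a)
  if (spec$altitude_degree >= 2L) X <- cbind(X, alt2 = a^2)
  if (spec$altitude_degree >= 3L) X <- cbind(X, alt3 = a^3)
  if (spec$include_range) X <- cbind(X, range = changes$altitudinal_range_m)
  list(X = X, y = changes$shift_m, richness = changes$richness, spec = spec)
}

# design row(s) for prediction at target altitudes, range held at range_value
.design_rows <- function(spec, targets, range_value) {
  a <- targets - spec$center
  X <- matrix(1, length(targets), 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$altitude_degree >= 1L) X <- cbind(X, alt = a)
  if (spec$altitude_degree >= 2L) X <- cbind(X, alt2 = a^2)
  if (spec$altitude_degree >= 3L) X <- cbind(X, alt3 = a^3)
  if (spec$include_range) X <- cbind(X, range = rep(range_value, length(targets)))
  X
}

#' Select the residual-variance structure by REML AIC
#'
#' Fits the full fixed-effect model under each candidate variance structure
#' (fixed, power of richness, constant plus power of richness), compares
#' their REML AICs, and returns the minimizer. AIC differences below `tol`
#' are treated as ties and resolved towards the structure with fewer
#' parameters.
#'
#' @param changes A `standardized_changes` table.
#' @param spec Full fixed-effect [model_spec()].
#' @param candidates Character vector of variance kinds to try.
#' @param tol AIC tie tolerance.
#' @return List with `variance` (the selected [var_structure()]), `aic`
#'   (named REML AICs of all candidates that converged), and `fits`.
#' @export
select_variance_structure <- function(changes, spec = model_spec(),
                                      candidates = c("fixed", "power",
                                                     "constpower"),
                                      tol = 1e-6) {
  d <- build_design(changes, spec)
  fits <- list()
  errors <- character(0)
  for (kind in candidates) {
    f <- tryCatch(fit_gls(d$X, d$y, d$richness, var_structure(kind), "REML"),
                  error = function(e) e)
    if (inherits(f, "error")) errors[kind] <- conditionMessage(f) else
      fits[[kind]] <- f
  }
  if (length(fits) == 0L) {
    stop("all candidate variance structures failed: ",
         paste(names(errors), errors, sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  aic <- vapply(fits, `[[`, 0, "aic_reml")
  npar <- vapply(names(fits), n_var_params, 0L)
  # ties towards fewer variance parameters
  ord <- order(npar)
  aic_o <- aic[ord]
  best_o <- 1L
  for (i in seq_along(aic_o)[-1L]) {
    if (aic_o[i] < aic_o[best_o] - tol) best_o <- i
  }
  best <- names(aic_o)[best_o]
  list(variance = fits[[best]]$variance, kind = best, aic = aic, fits = fits)
}

#' Backward fixed-effect selection by ML AIC
#'
#' Starts from the full model (linear + quadratic + cubic altitude +
#' altitudinal range) under the chosen variance structure, and iteratively
#' deletes the term whose removal most lowers the ML AIC, respecting the
#' polynomial hierarchy (only the highest-order altitude term present is
#' removable; the intercept never is). Stops when no deletion lowers the
#' AIC; the minimal adequate model is then refit by REML.
#'
#' @param changes A `standardized_changes` table.
#' @param variance A [var_structure()] kind selected beforehand.
#' @param spec Full starting [model_spec()].
#' @param tol AIC tie tolerance; deletions within `tol` of the current AIC
#'   are taken (simplicity wins ties).
#' @return List with `spec` (the minimal adequate [model_spec()]), `fit`
#'   (REML refit), and `path` (data.frame of the deletion trail with AICs).
#' @export
backward_select <- function(changes, variance = var_structure("fixed"),
                            spec = model_spec(), tol = 1e-6) {
  if (is.character(variance)) variance <- var_structure(variance)
  fit_ml <- function(sp) {
    d <- build_design(changes, sp)
    fit_gls(d$X, d$y, d$richness, variance, "ML")
  }
  current <- spec
  cur_fit <- fit_ml(current)
  path <- data.frame(step = "<full>", aic_ml = cur_fit$aic_ml,
                     stringsAsFactors = FALSE)
  repeat {
    cands <- list()
    if (current$altitude_degree >= 1L) {
      cands[[paste0("drop altitude degree ", current$altitude_degree)]] <-
        model_spec(current$altitude_degree - 1L, current$include_range,
                   current$center)
    }
    if (current$include_range) {
      cands[["drop range"]] <-
        model_spec(current$altitude_degree, FALSE, current$center)
    }
    if (length(cands) == 0L) break
    fits <- lapply(cands, fit_ml)
    aics <- vapply(fits, `[[`, 0, "aic_ml")
    best <- which.min(aics)
    if (aics[best] <= cur_fit$aic_ml + tol) {
      current <- cands[[best]]
      cur_fit <- fits[[best]]
      path <- rbind(path, data.frame(step = names(cands)[best],
                                     aic_ml = aics[best],
                                     stringsAsFactors = FALSE))
    } else break
  }
  d <- build_design(changes, current)
  final <- fit_gls(d$X, d$y, d$richness, variance, "REML")
  list(spec = current, fit = final, path = path)
}

#' REML likelihood-ratio test between nested GLS fits
#'
#' The statistic is twice the difference of REML log-likelihoods; the
#' reference is a chi-squared distribution with degrees of freedom equal to
#' the difference in estimated-parameter counts. Valid for comparing
#' variance structures under identical fixed effects (REML likelihoods are
#' not comparable across different fixed-effect sets).
#'
#' @param full,reduced `gls_fit` objects, `reduced` nested in `full`, both
#'   fit to the same data with identical fixed effects.
#' @return List with `statistic`, `df`, `p`.
#' @export
lrt_reml <- function(full, reduced) {
  stopifnot(inherits(full, "gls_fit"), inherits(reduced, "gls_fit"))
  if (full$n != reduced$n) stop("fits use different data", call. = FALSE)
  if (full$p != reduced$p ||
      !isTRUE(all.equal(unname(full$X), unname(reduced$X)))) {
    stop("REML comparison requires identical fixed effects", call. = FALSE)
  }
  df <- full$k - reduced$k
  if (df < 0L) stop("`reduced` has more parameters than `full`", call. = FALSE)
  stat <- max(0, 2 * (full$logLik_REML - reduced$logLik_REML))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Bootstrap confidence intervals and p-values for shift predictions
#'
#' Nonparametric case resampling: squares are resampled with replacement,
#' the already-selected model (fixed effects and variance structure; no
#' re-selection) is refit by REML, and the shift is predicted at each target
#' altitude with the altitudinal-range covariate held at its observed mean.
#' Intervals are percentile intervals; the two-sided p-value is
#' `2 * min(#{pred <= 0} + 1, #{pred >= 0} + 1) / (B + 1)`, so predictions
#' whose 95% interval excludes zero are judged significant at about the 5%
#' level. Iterates that fail to converge are redrawn (more than 10%
#' failures is an error). Deterministic given `seed`.
#'
#' By default the standardization constant b is held fixed at its full-data
#' estimate, as in the headline analysis. With `refit_b = TRUE` each
#' resample also re-estimates b from the resampled first-survey index
#' values and re-standardizes the raw changes, propagating the sampling
#' error of b into the intervals (a sensitivity variant, and the variant
#' used for coverage studies).
#'
#' @param changes A `standardized_changes` table.
#' @param spec Selected [model_spec()].
#' @param variance Selected [var_structure()].
#' @param targets Altitudes (m) at which to predict, default 500 and 2350.
#' @param B Number of bootstrap iterations.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param refit_b Re-estimate the standardization slope b within each
#'   resample (see Details). Requires the `index_survey1` column that
#'   [standardized_changes()] records.
#' @return A list of class `bootstrap_result`: `predictions` (data.frame
#'   with `altitude_m`, `estimate`, `lower`, `upper`, `p`), `B`,
#'   `n_redrawn`, `seed`, `fit` (full-data REML fit), and `draws`
#'   (targets x B matrix of per-iterate predictions).
#' @export
bootstrap_predictions <- function(changes, spec = model_spec(),
                                  variance = var_structure("fixed"),
                                  targets = c(500, 2350), B = 1000,
                                  seed = NULL, level = 0.95,
                                  refit_b = FALSE) {
  if (B < 1) stop("`B` must be >= 1", call. = FALSE)
  if (refit_b && is.null(changes$index_survey1)) {
    stop("`refit_b = TRUE` needs the `index_survey1` column", call. = FALSE)
  }
  if (is.character(variance)) variance <- var_structure(variance)
  if (!is.null(seed)) set.seed(seed)
  d <- build_design(changes, spec)
  full_fit <- fit_gls(d$X, d$y, d$richness, variance, "REML")
  range_mean <- mean(changes$altitudinal_range_m)
  newX <- .design_rows(spec, targets, range_mean)
  point <- predict(full_fit, newX)

  # warm-start every refit at the full-data variance parameters
  warm <- switch(full_fit$variance$kind,
                 fixed = NULL,
                 power = full_fit$var_params$delta,
                 constpower = c(full_fit$var_params$delta,
                                log(full_fit$var_params$const)))
  n <- nrow(changes)
  draws <- matrix(NA_real_, length(targets), B)
  n_redrawn <- 0L
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    y_star <- d$y[idx]
    if (refit_b) {
      slope_star <- tryCatch(
        fit_altitude_slope(changes$index_survey1[idx],
                           changes$altitude_m[idx]),
        error = function(e) NULL)
      if (is.null(slope_star) || slope_star$b >= 0) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 0.1 * B) {
          stop("more than 10% of bootstrap iterates failed (", n_redrawn,
               " failures)", call. = FALSE)
        }
        next
      }
      y_star <- -changes$raw_delta[idx] / slope_star$b
    }
    fit_b <- tryCatch(
      fit_gls(d$X[idx, , drop = FALSE], y_star, d$richness[idx],
              variance, "REML", restarts = 0L, start = warm),
      error = function(e) NULL)
    if (is.null(fit_b)) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 0.1 * B) {
        stop("more than 10% of bootstrap iterates failed to converge (",
             n_redrawn, " failures)", call. = FALSE)
      }
      next
    }
    draws[, b] <- predict(fit_b, newX)
    b <- b + 1L
  }
  alpha <- 1 - level
  lower <- apply(draws, 1, stats::quantile, probs = alpha / 2, names = FALSE)
  upper <- apply(draws, 1, stats::quantile, probs = 1 - alpha / 2,
                 names = FALSE)
  pvals <- apply(draws, 1, function(z) {
    min(1, 2 * min(sum(z <= 0) + 1, sum(z >= 0) + 1) / (B + 1))
  })
  structure(list(
    predictions = data.frame(altitude_m = targets, estimate = point,
                             lower = lower, upper = upper, p = pvals),
    B = B, n_redrawn = n_redrawn, seed = seed, level = level,
    range_value = range_mean, fit = full_fit, draws = draws
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap predictions (B = ", x$B, ", ",
      round(100 * x$level), "% percentile intervals)\n", sep = "")
  print(transform(x$predictions,
                  estimate = signif(estimate, 4),
                  lower = signif(lower, 4), upper = signif(upper, 4),
                  p = signif(p, 3)))
  if (x$n_redrawn > 0) cat(x$n_redrawn, "iterate(s) redrawn\n")
  invisible(x)
}

#' Refit the selected model excluding outlying shifts
#'
#' Robustness utility: drops squares whose absolute standardized shift
#' exceeds a threshold (or whose ids are listed) and refits the selected
#' model, so the stability of the altitude effects can be checked against
#' extreme shift values from species-poor squares.
#'
#' @param changes A `standardized_changes` table.
#' @param spec Selected [model_spec()].
#' @param variance Selected [var_structure()].
#' @param threshold Drop squares with `|shift_m| > threshold` (ignored when
#'   `exclude_ids` is given).
#' @param exclude_ids Square ids to drop.
#' @return List with `fit` (REML refit without the outliers), `excluded`
#'   (ids dropped), and `changes` (the reduced table).
#' @export
refit_without_outliers <- function(changes, spec = model_spec(),
                                   variance = var_structure("fixed"),
                                   threshold = NULL, exclude_ids = NULL) {
  if (is.null(exclude_ids)) {
    if (is.null(threshold)) stop("give `threshold` or `exclude_ids`",
                                 call. = FALSE)
    exclude_ids <- changes$square_id[abs(changes$shift_m) > threshold]
  }
  reduced <- changes[!(changes$square_id %in% exclude_ids), , drop = FALSE]
  class(reduced) <- class(changes)
  d <- build_design(reduced, spec)
  if (is.character(variance)) variance <- var_structure(variance)
  fit <- fit_gls(d$X, d$y, d$richness, variance, "REML")
  list(fit = fit, excluded = exclude_ids, changes = reduced)
}
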