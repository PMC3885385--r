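#' Variance structures for richness-dependent residual spread
#'
#' Residual SD of observation i is `sigma * g(richness_i)`, with
#' `g` one of: `"fixed"` (g = 1, the homoscedastic linear model),
#' `"power"` (g = richness^delta), or `"constpower"`
#' (g = const + richness^delta, const > 0). Indices computed from richer
#' communities are more precise, so delta is typically negative.
#'
#' @param kind `"fixed"`, `"power"` or `"constpower"`.
#' @param delta Power exponent (fitted when NULL).
#' @param const Constant term for `"constpower"` (fitted when NULL).
#' @return A list of class `var_structure`.
#' @export
var_structure <- function(kind = c("fixed", "power", "constpower"),
                          delta = NULL, const = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, delta = delta, const = const),
            class = "var_structure")
}

n_var_params <- function(kind) {
  switch(kind, fixed = 0L, power = 1L, constpower = 2L)
}

# relative residual SD g(richness) for parameter vector theta
# theta: power -> delta; constpower -> (delta, log const)
.g_of <- function(kind, theta, richness) {
  switch(kind,
         fixed = rep(1, length(richness)),
         power = richness^theta[1],
         constpower = exp(theta[2]) + richness^theta[1])
}

# Profiled log-likelihood of the weighted regression at variance
# parameters theta. Beta and sigma are concentrated out. REML uses the
# orthonormal-error-contrast likelihood (Harville form, including the
# + log|X'X|/2 term so the value equals the exact contrast density).
# ldet_xtx = log|X'X| is precomputed by the caller; log|X'WX| comes free
# from the QR of the weighted design.
.gls_objective <- function(theta, kind, X, y, richness, method,
                           ldet_xtx = 0) {
  g <- .g_of(kind, theta, richness)
  if (any(!is.finite(g)) || any(g <= 0)) return(NULL)
  n <- length(y)
  p <- ncol(X)
  sw <- 1 / g
  if (any(!is.finite(sw))) return(NULL)
  fit <- tryCatch(stats::.lm.fit(X * sw, y * sw), error = function(e) NULL)
  if (is.null(fit) || fit$rank < p) return(NULL)
  rss <- sum(fit$residuals^2)
  if (method == "ML") {
    s2 <- rss / n
    ll <- -0.5 * n * (log(2 * pi * s2) + 1) - sum(log(g))
  } else {
    s2 <- rss / (n - p)
    rdiag <- diag(fit$qr)[seq_len(p)]
    ldet_xwx <- 2 * sum(log(abs(rdiag)))
    ll <- -0.5 * (n - p) * (log(2 * pi * s2) + 1) - sum(log(g)) -
      0.5 * ldet_xwx + 0.5 * ldet_xtx
  }
  beta <- fit$coefficients
  beta[fit$pivot] <- fit$coefficients
  list(logLik = as.numeric(ll), coefficients = beta,
       sigma = sqrt(s2), g = g, w = sw^2, rss = rss)
}

#' Fit a Gaussian GLS with a richness-dependent variance function
#'
#' Maximizes the Gaussian likelihood of `y = X beta + e`,
#' `e_i ~ N(0, (sigma g(richness_i))^2)`, by profiling `beta` and `sigma`
#' (weighted least squares at fixed variance parameters) and numerically
#' optimizing the variance parameters. The REML criterion is the exact
#' likelihood of orthonormal error contrasts. Variance parameters start at
#' `delta = 0` (and `const = 1`) with jittered restarts; the homoscedastic
#' `"fixed"` structure reduces to OLS.
#'
#' @param X Design matrix (first column the intercept; see [build_design()]).
#' @param y Response vector (standardized shifts, m).
#' @param richness Variance covariate (> 0), required for power structures.
#' @param variance A [var_structure()] or its kind as a string.
#' @param method `"REML"` (default) or `"ML"`.
#' @param restarts Number of jittered restarts for the variance optimizer.
#' @param start Optional starting value(s) for the variance parameters
#'   (delta, or c(delta, log const)); defaults to delta = 0, log const = 0.
#'   Useful for warm-starting bootstrap refits.
#' @return An object of class `gls_fit`: coefficients with SEs and `vcov`,
#'   `sigma`, variance parameters, `logLik`/`logLik_ML`/`logLik_REML`,
#'   `aic` (2k - 2 logLik at the fitting criterion, with k counting beta,
#'   variance parameters and sigma), fitted relative SDs `g`, and the inputs.
#' @export
fit_gls <- function(X, y, richness = NULL, variance = var_structure("fixed"),
                    method = c("REML", "ML"), restarts = 3L, start = NULL) {
  method <- match.arg(method)
  if (is.character(variance)) variance <- var_structure(variance)
  kind <- variance$kind
  X_raw <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X_raw)
  if (n <= p + n_var_params(kind)) {
    stop("need more observations than estimated parameters", call. = FALSE)
  }
  if (qr(X_raw)$rank < p) stop("design matrix is singular", call. = FALSE)
  # column scaling for numerical stability (polynomial altitude columns span
  # many orders of magnitude); both likelihood criteria are invariant to it
  col_scale <- apply(abs(X_raw), 2, max)
  col_scale[col_scale == 0] <- 1
  X <- sweep(X_raw, 2, col_scale, "/")
  if (kind != "fixed") {
    if (is.null(richness)) stop("`richness` required for variance kind ", kind,
                                call. = FALSE)
    if (any(!is.finite(richness)) || any(richness <= 0)) {
      stop("`richness` must be positive and finite", call. = FALSE)
    }
  }

  ldet_xtx <- 2 * sum(log(abs(diag(qr.R(qr(X))))))
  if (kind == "fixed") {
    theta <- numeric(0)
    best <- .gls_objective(theta, kind, X, y, richness = rep(1, n),
                           method = method, ldet_xtx = ldet_xtx)
  } else {
    negll <- function(th) {
      o <- .gls_objective(th, kind, X, y, richness, method, ldet_xtx)
      if (is.null(o)) return(1e10)
      -o$logLik
    }
    base_start <- if (!is.null(start)) start else
      if (kind == "power") 0 else c(0, 0)
    if (length(base_start) != n_var_params(kind)) {
      stop("`start` must have ", n_var_params(kind),
           " variance parameter(s)", call. = FALSE)
    }
    starts <- list(base_start)
    for (r in seq_len(restarts)) {
      jit <- 0.5 * r * c(1, -1)[(r %% 2) + 1]
      starts[[r + 1L]] <- base_start + jit
    }
    # the exponent and log-constant are box-constrained to a generous but
    # finite region: unconstrained search can drift to degenerate
    # two-regime variance fits (delta -> -Inf) that overweight a handful
    # of observations and destabilize bootstrap refits
    lo <- c(-5, -10)[seq_along(starts[[1L]])]
    hi <- c(5, 10)[seq_along(starts[[1L]])]
    starts <- lapply(starts, function(s) pmin(pmax(s, lo), hi))
    opts <- lapply(starts, function(s) {
      if (length(s) == 1L) {
        o <- stats::optim(s, negll, method = "Brent", lower = lo, upper = hi)
      } else {
        o <- stats::optim(s, negll, method = "L-BFGS-B", lower = lo,
                          upper = hi, control = list(factr = 1e5))
      }
      o
    })
    vals <- vapply(opts, `[[`, 0, "value")
    if (all(vals >= 1e10)) {
      stop("variance-parameter optimization failed to find a finite ",
           "likelihood; starts tried: ",
           paste(vapply(starts, paste, "", collapse = "/"), collapse = ", "),
           call. = FALSE)
    }
    theta <- opts[[which.min(vals)]]$par
    best <- .gls_objective(theta, kind, X, y, richness, method, ldet_xtx)
  }
  if (is.null(best)) stop("GLS fit failed", call. = FALSE)

  # both criteria at the same variance parameters, for reporting
  rich_eff <- if (kind == "fixed") rep(1, n) else richness
  ll_ml <- if (method == "ML") best$logLik else
    .gls_objective(theta, kind, X, y, rich_eff, "ML", ldet_xtx)$logLik
  ll_reml <- if (method == "REML") best$logLik else
    .gls_objective(theta, kind, X, y, rich_eff, "REML", ldet_xtx)$logLik

  k <- p + n_var_params(kind) + 1L
  beta <- best$coefficients / col_scale
  xwx <- crossprod(X * sqrt(best$w))
  vcov_beta <- best$sigma^2 * solve(xwx) / tcrossprod(col_scale)
  dimnames(vcov_beta) <- list(colnames(X_raw), colnames(X_raw))
  se <- sqrt(diag(vcov_beta))

  var_params <- switch(kind,
    fixed = list(),
    power = list(delta = theta[1]),
    constpower = list(delta = theta[1], const = exp(theta[2])))

  structure(list(
    coefficients = stats::setNames(as.numeric(beta), colnames(X_raw)),
    se = stats::setNames(se, colnames(X_raw)),
    vcov = vcov_beta,
    sigma = best$sigma,
    var_params = var_params,
    variance = var_structure(kind,
                             delta = var_params$delta,
                             const = var_params$const),
    logLik = best$logLik,
    logLik_ML = ll_ml,
    logLik_REML = ll_reml,
    aic = 2 * k - 2 * best$logLik,
    aic_ml = 2 * k - 2 * ll_ml,
    aic_reml = 2 * k - 2 * ll_reml,
    k = k, n = n, p = p,
    fitted = as.numeric(X_raw %*% beta),
    residuals = as.numeric(y - X_raw %*% beta),
    g = best$g,
    method = method,
    X = X_raw, y = y, richness = richness
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Generalized least squares fit (", x$method, ")\n", sep = "")
  cat("Variance structure:", x$variance$kind)
  if (length(x$var_params) > 0) {
    cat(" (", paste(names(x$var_params),
                    signif(unlist(x$var_params), 4),
                    sep = " = ", collapse = ", "), ")", sep = "")
  }
  cat("\nlogLik:", format(x$logLik, digits = 6),
      " AIC:", format(x$aic, digits = 6),
      " sigma:", format(x$sigma, digits = 4), "\n\n")
  tab <- cbind(Estimate = x$coefficients, `Std.Error` = x$se,
               `t` = x$coefficients / x$se)
  print(signif(tab, 4))
  invisible(x)
}

#' Predict from a GLS fit at new design rows
#'
#' @param object A `gls_fit`.
#' @param newX Matrix with the same columns as the training design.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.gls_fit <- function(object, newX, ...) {
  newX <- as.matrix(newX)
  as.numeric(newX %*% object$coefficients)
}
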