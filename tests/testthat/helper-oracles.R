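# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: dense matrix algebra, two-pass
# formulas, and explicit error-contrast likelihoods.

# log-density of y ~ N(mu, Sigma), dense
dense_gaussian_loglik <- function(y, mu, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# exact REML log-likelihood: Gaussian density of orthonormal error
# contrasts A'y with A spanning the orthogonal complement of col(X)
reml_contrast_loglik <- function(X, y, Sigma) {
  n <- length(y)
  p <- ncol(X)
  Q <- qr.Q(qr(X), complete = TRUE)
  A <- Q[, (p + 1):n, drop = FALSE]
  z <- drop(crossprod(A, y))
  S <- crossprod(A, Sigma %*% A)
  dense_gaussian_loglik(z, rep(0, length(z)), S)
}

# profiled ML log-likelihood of a heteroscedastic regression evaluated by
# brute force on a grid of variance parameters: for each candidate g-vector
# the best beta is weighted LS and the best sigma is closed-form
grid_best_loglik <- function(X, y, g_candidates) {
  n <- length(y)
  best <- -Inf
  for (g in g_candidates) {
    w <- 1 / g^2
    beta <- solve(crossprod(X, X * w), crossprod(X, y * w))
    rss <- sum(w * (y - X %*% beta)^2)
    s2 <- rss / n
    ll <- -0.5 * n * (log(2 * pi * s2) + 1) - sum(log(g))
    if (ll > best) best <- ll
  }
  best
}

# two-pass sample SD, independent of stats::sd
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# closed-form OLS slope/intercept via the normal equations, long-hand
normal_equation_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  c(intercept = a, slope = b)
}

# small standardized-changes table built directly (bypasses the survey
# pipeline) for model-layer tests
make_changes <- function(n, altitudes, shifts, richness = NULL,
                         ranges = NULL) {
  out <- data.frame(
    square_id = sprintf("q%03d", seq_len(n)),
    altitude_m = altitudes,
    altitudinal_range_m = if (is.null(ranges))
      seq(30, 700, length.out = n) else ranges,
    richness = if (is.null(richness)) rep(20, n) else richness,
    raw_delta = NA_real_,
    quotient_m = -shifts,
    shift_m = shifts,
    stringsAsFactors = FALSE
  )
  class(out) <- c("standardized_changes", "data.frame")
  out
}

# default butterfly-like study conditions used by simulation tests
butterfly_pool <- function(seed, n_species = 660) {
  generate_species_pool(n_species, sti_bounds = c(7, 16), seed = seed)
}
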