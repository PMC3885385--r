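test_that("build_design centres altitude at 500 m", {
  ch <- make_changes(3, c(500, 2350, 1000), c(10, -5, 2), ranges = c(0, 0, 0))
  d <- build_design(ch, model_spec(3, TRUE))
  expect_equal(colnames(d$X),
               c("(Intercept)", "alt", "alt2", "alt3", "range"))
  expect_equal(unname(d$X[1, ]), c(1, 0, 0, 0, 0))       # square at 500 m
  expect_equal(unname(d$X[2, 2:4]), c(1850, 1850^2, 1850^3))
  expect_equal(d$y, ch$shift_m)

  ch_bad <- ch
  ch_bad$altitude_m[2] <- NA
  class(ch_bad) <- class(ch)
  expect_error(build_design(ch_bad, model_spec(1, FALSE)), "q002")

  expect_error(model_spec(4), "altitude_degree")
})

test_that("variance-structure selection finds the generating structure", {
  # homoscedastic data -> fixed variance wins in most replicates;
  # strong power heteroscedasticity -> a power-type structure wins
  n <- 500
  picks_hom <- character(30)
  picks_het <- character(30)
  for (i in seq_len(30)) {
    set.seed(400 + i)
    rich <- runif(n, 2, 60)
    alt <- runif(n, 300, 2800)
    hom <- make_changes(n, alt, rnorm(n, 0, 30), richness = rich)
    het <- make_changes(n, alt, rnorm(n, 0, 3 * rich), richness = rich)
    picks_hom[i] <- select_variance_structure(hom, model_spec(1, FALSE))$kind
    picks_het[i] <- select_variance_structure(het, model_spec(1, FALSE))$kind
  }
  expect_gte(mean(picks_hom == "fixed"), 0.8)
  expect_gte(mean(picks_het != "fixed"), 0.95)
})

test_that("single-candidate selection is the identity", {
  ch <- make_changes(30, runif(30, 300, 2800), rnorm(30))
  out <- select_variance_structure(ch, model_spec(1, FALSE),
                                   candidates = "power")
  expect_equal(out$kind, "power")
})

test_that("backward selection respects hierarchy and finds signal", {
  # pure noise: the intercept-only model is the modal outcome and noise
  # terms are rarely retained (each survives only when its AIC penalty of
  # 2 is beaten, P(chi2_1 > 2) ~ 0.16)
  n <- 214
  n_noise_min <- 0L
  n_terms <- integer(50)
  for (i in seq_len(50)) {
    set.seed(430 + i)
    ch <- make_changes(n, runif(n, 300, 2800), rnorm(n, 0, 50),
                       ranges = runif(n, 30, 700))
    sel <- backward_select(ch, "fixed")
    n_terms[i] <- sel$spec$altitude_degree + sel$spec$include_range
    if (n_terms[i] == 0L) n_noise_min <- n_noise_min + 1L
    expect_true(sel$spec$altitude_degree %in% 0:3)
  }
  expect_gte(n_noise_min, 20L)
  expect_lte(mean(n_terms), 1)

  # a strong cubic signal is retained
  retained <- 0L
  for (i in seq_len(10)) {
    set.seed(460 + i)
    a <- runif(n, 300, 2800) - 500
    y <- 1e-8 * a^3 + rnorm(n, 0, 5)
    ch <- make_changes(n, a + 500, y)
    sel <- backward_select(ch, "fixed")
    if (sel$spec$altitude_degree == 3L) retained <- retained + 1L
  }
  expect_gte(retained, 8L)
})

test_that("REML LRT matches its definition and calibrates under the null", {
  set.seed(471)
  n <- 100
  rich <- runif(n, 2, 60)
  X <- cbind(1, x = rnorm(n))
  y <- 1 + rnorm(n, 0, 2)
  full <- fit_gls(X, y, rich, "power", "REML")
  red <- fit_gls(X, y, rich, "fixed", "REML")
  out <- lrt_reml(full, red)
  expect_equal(out$statistic,
               max(0, 2 * (full$logLik_REML - red$logLik_REML)),
               tolerance = 1e-10)
  expect_equal(out$df, 1L)

  same <- lrt_reml(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # different fixed effects are rejected
  X2 <- cbind(1, x = rnorm(n))
  other <- fit_gls(X2, y, rich, "fixed", "REML")
  expect_error(lrt_reml(full, other), "identical fixed effects")

  # type-I error under a true null (delta = 0): close to nominal since the
  # power exponent is unconstrained (no boundary effect)
  reject <- logical(300)
  for (i in seq_len(300)) {
    set.seed(500 + i)
    yy <- rnorm(n, 0, 2)
    fu <- fit_gls(X, yy, rich, "power", "REML", restarts = 0L)
    re <- fit_gls(X, yy, rich, "fixed", "REML")
    reject[i] <- lrt_reml(fu, re)$p < 0.05
  }
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.09)
})

test_that("bootstrap predictions are consistent and seed-deterministic", {
  # degenerate noise: interval collapses onto the point prediction
  n <- 40
  a <- seq(300, 2700, length.out = n)
  ch <- make_changes(n, a, 30 - 0.01 * (a - 500))
  b1 <- bootstrap_predictions(ch, model_spec(1, FALSE), "fixed",
                              targets = c(500, 2350), B = 50, seed = 1)
  expect_equal(b1$predictions$estimate[1], 30, tolerance = 1e-8)
  width <- b1$predictions$upper - b1$predictions$lower
  expect_lt(width[1], 1e-6 * abs(b1$predictions$estimate[1]))

  # same seed, same numbers; different B leaves the point estimate alone
  set.seed(510)
  ch2 <- make_changes(100, runif(100, 300, 2800), rnorm(100, 10, 40))
  r1 <- bootstrap_predictions(ch2, model_spec(1, FALSE), "fixed", B = 99,
                              seed = 7)
  r2 <- bootstrap_predictions(ch2, model_spec(1, FALSE), "fixed", B = 99,
                              seed = 7)
  expect_identical(r1$predictions, r2$predictions)
  r3 <- bootstrap_predictions(ch2, model_spec(1, FALSE), "fixed", B = 299,
                              seed = 8)
  expect_equal(r1$predictions$estimate, r3$predictions$estimate,
               tolerance = 1e-12)

  # percentile rule: CI excluding zero <=> p < 0.05 (B chosen so the
  # quantile and counting rules align)
  for (row in seq_len(nrow(r3$predictions))) {
    excl <- r3$predictions$lower[row] > 0 || r3$predictions$upper[row] < 0
    expect_equal(excl, r3$predictions$p[row] < 0.05)
  }
})

test_that("prediction at 500 m equals the intercept without range term", {
  set.seed(521)
  ch <- make_changes(80, runif(80, 300, 2800), rnorm(80, 20, 30))
  b <- bootstrap_predictions(ch, model_spec(2, FALSE), "fixed",
                             targets = 500, B = 20, seed = 3)
  expect_equal(b$predictions$estimate[1],
               unname(b$fit$coefficients["(Intercept)"]), tolerance = 1e-10)
})

test_that("outlier refits drop the flagged squares only", {
  set.seed(531)
  ch <- make_changes(50, runif(50, 300, 2800), c(rnorm(48, 10, 20), 900, -800))
  out <- refit_without_outliers(ch, model_spec(1, FALSE), "fixed",
                                threshold = 500)
  expect_equal(sort(out$excluded), sort(ch$square_id[49:50]))
  expect_equal(nrow(out$changes), 48L)
  expect_s3_class(out$fit, "gls_fit")
})
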