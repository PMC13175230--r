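test_that("log-linear WLLS is exact on noiseless mono-exponential data", {
  # two points define the log-line exactly
  fit <- fit_loglinear_wlls(c(200, 800), c(exp(-0.2), exp(-0.8)))
  expect_equal(fit$D, 1.0e-3, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)
  # constant signal: zero slope
  fit <- fit_loglinear_wlls(c(0, 300, 600), rep(0.7, 3))
  expect_equal(fit$D, 0)
  expect_equal(fit$intercept, 0.7)
  # three-point mono-exponential round trip
  b <- c(200, 500, 800)
  fit <- fit_loglinear_wlls(b, 0.85 * exp(-b * 2.0e-3))
  expect_equal(fit$D, 2.0e-3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.85, tolerance = 1e-10)
})

test_that("single-iteration WLLS with equal weights is OLS on the log-signal", {
  set.seed(12)
  b <- c(200, 400, 600, 800)
  s <- exp(-b * 1.2e-3) * exp(rnorm(4, 0, 0.05))
  # equal weights: constant signals in the weight role
  fit <- fit_loglinear_wlls(b, s, iterations = 1)
  # oracle: lm weighted by the observed signal squared
  ols <- stats::lm(log(s) ~ b, weights = s^2)
  expect_equal(fit$D, -unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, exp(unname(coef(ols)[1])), tolerance = 1e-10)
})

test_that("WLLS excludes non-positive signals and fails below 2 usable points", {
  expect_warning(fit <- fit_loglinear_wlls(c(200, 500, 800),
                                           c(0.8, -0.1, 0.4)),
                 "non-positive")
  expect_length(fit, 2L)
  expect_error(suppressWarnings(
    fit_loglinear_wlls(c(200, 500), c(0.8, -0.1))), "2 distinct")
})

test_that("segmented fit recovers a noiseless kidney-like curve with the documented bias signs", {
  p <- kidney_like()  # f 0.15, D 1.5e-3, D* 50e-3
  b <- get_preset("kidney")$minimal_b
  s <- ivim_signal(p, b)
  fit <- segmented_fit(b, s, fit_options(b_threshold = 200))
  e <- fit$estimates
  # step-1 oracle: residual perfusion inflates D, deflates f
  expect_gte(e[["D"]], p$D)
  expect_lte(e[["f"]], p$f)
  expect_lt(abs(e[["D"]] - p$D) / p$D, 0.005)
  expect_lt(abs(e[["f"]] - p$f) / p$f, 0.005)
  expect_true(fit$converged)
})

test_that("segmented step-2 Dstar agrees with a golden-section oracle", {
  p <- kidney_like()
  b <- get_preset("kidney")$minimal_b
  s <- ivim_signal(p, b)
  fit <- segmented_fit(b, s, fit_options(b_threshold = 200))
  e <- fit$estimates
  # brute-force 1-D scan over Dstar with the step-1 values frozen
  sse <- function(ds) {
    m <- e[["S0"]] * (e[["f"]] * exp(-b * ds) +
                      (1 - e[["f"]]) * exp(-b * e[["D"]]))
    sum((s - m)^2)
  }
  oracle <- optimize(sse, c(e[["D"]], 0.5), tol = 1e-12)$minimum
  expect_equal(e[["Dstar"]], oracle, tolerance = 1e-4)
  expect_lt(abs(e[["Dstar"]] - 50e-3) / 50e-3, 0.05)
})

test_that("segmented fit flags f = 0 on mono-exponential input", {
  b <- get_preset("kidney")$minimal_b
  s <- 0.9 * exp(-b * 1.2e-3)
  fit <- segmented_fit(b, s, fit_options(b_threshold = 200))
  expect_true("f_clipped" %in% fit$flags)
  expect_equal(fit$estimates[["f"]], 0)
  expect_equal(fit$estimates[["D"]], 1.2e-3, tolerance = 1e-6)
  expect_true(is.na(fit$estimates[["Dstar"]]))
})

test_that("segmented fit enforces its design preconditions", {
  opts <- fit_options(b_threshold = 200)
  expect_error(segmented_fit(c(0, 50, 200), c(1, 0.9, 0.7), opts),
               "2 distinct")
  expect_error(segmented_fit(c(50, 200, 800), c(0.9, 0.7, 0.4), opts),
               "b = 0")
  expect_error(segmented_fit(c(0, 200, 800), c(1, 0.7, 0.4), opts),
               "between 0 and")
})

test_that("segmented refit-f variant re-solves f with D frozen", {
  p <- kidney_like()
  b <- get_preset("kidney")$minimal_b
  s <- ivim_signal(p, b)
  fit <- segmented_fit(b, s, fit_options(method = "segmented_refit_f",
                                         b_threshold = 200))
  e <- fit$estimates
  expect_lt(abs(e[["f"]] - p$f) / p$f, 0.005)
  expect_lt(abs(e[["Dstar"]] - p$Dstar) / p$Dstar, 0.05)
})

test_that("segmentation bias signs hold across all organ presets (noiseless)", {
  for (org in ivim_organs()) {
    pre <- get_preset(org)
    p <- preset_params(pre)
    s <- ivim_signal(p, pre$minimal_b)
    fit <- segmented_fit(pre$minimal_b, s,
                         fit_options(b_threshold = pre$b_threshold))
    expect_gte(fit$estimates[["D"]], p$D)
    expect_lte(fit$estimates[["f"]], p$f)
  }
})

test_that("segmentation bias shrinks as Dstar grows at fixed threshold", {
  b <- get_preset("kidney")$minimal_b
  bias_D <- bias_f <- numeric(0)
  for (ds in c(20e-3, 50e-3, 100e-3)) {
    p <- ivim_params(0.15, 1.5e-3, ds)
    fit <- segmented_fit(b, ivim_signal(p, b),
                         fit_options(b_threshold = 200))
    bias_D <- c(bias_D, fit$estimates[["D"]] - p$D)
    bias_f <- c(bias_f, p$f - fit$estimates[["f"]])
  }
  expect_true(all(diff(bias_D) < 0))
  expect_true(all(diff(bias_f) < 0))
})

test_that("full NLLS round-trips noiseless data and needs 4 distinct b", {
  p <- ivim_params(0.2, 1.1e-3, 30e-3, S0 = 50)
  b <- c(0, 20, 60, 150, 400, 800)
  s <- ivim_signal(p, b)
  fit <- full_nlls_fit(b, s)
  for (nm in c("S0", "f", "D", "Dstar"))
    expect_lt(abs(fit$estimates[[nm]] - p[[nm]]) / p[[nm]], 1e-3)
  expect_error(full_nlls_fit(c(0, 100, 800), c(1, 0.8, 0.4)),
               "4 distinct")
  # init at truth on noiseless data: immediate convergence, residual ~ 0
  fit2 <- full_nlls_fit(b, s, init = p)
  expect_true(fit2$converged)
  expect_lt(fit2$rss, 1e-20)
})

test_that("full NLLS agrees with a coarse 4-D grid-search oracle", {
  p <- ivim_params(0.2, 1.5e-3, 40e-3, S0 = 1)
  b <- c(0, 30, 100, 300, 600, 900)
  s <- ivim_signal(p, b)
  grid <- expand.grid(f = seq(0.05, 0.4, by = 0.05),
                      D = seq(0.5e-3, 3e-3, by = 0.25e-3),
                      Ds = seq(0.01, 0.08, by = 0.01),
                      S0 = seq(0.9, 1.1, by = 0.05))
  sse <- apply(grid, 1, function(g)
    sum((s - biexp_oracle(g[1], g[2], g[3], g[4], b))^2))
  best <- grid[which.min(sse), ]
  fit <- full_nlls_fit(b, s)
  expect_lt(abs(fit$estimates[["f"]] - best$f), 0.05)
  expect_lt(abs(fit$estimates[["D"]] - best$D), 0.25e-3)
  expect_lt(abs(fit$estimates[["Dstar"]] - best$Ds), 0.01)
})
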