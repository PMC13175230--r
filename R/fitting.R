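#' Fitting options for IVIM estimation
#'
#' @param method One of `"segmented_fix_df"` (two-step fit, D and f frozen
#'   from step 1; the consensus default), `"segmented_refit_f"` (D frozen,
#'   f re-solved with D* and S0), or `"full_nlls"` (simultaneous bounded
#'   nonlinear least squares of all four parameters).
#' @param b_threshold Threshold b-value (s/mm2) separating the
#'   diffusion-only regime from the perfusion-contaminated regime; 200 for
#'   all organs except brain (300).
#' @param wlls_iterations Number of weighted-linear iterations for the
#'   high-b log-linear step; iteration 1 weights by the observed signals,
#'   later iterations by the model-predicted signals.
#' @param dstar_init_multiplier Initial guess for D* as a multiple of the
#'   fitted D (default 10).
#' @param bounds Optional list with `lower`/`upper` named vectors over
#'   `S0`, `f`, `D`, `Dstar`; defaults cover the literature organ ranges
#'   with margin (`f` in `[0,1]`, `D` in `[1e-5, 5e-3]`, `Dstar` in
#'   `[D, 0.5]` mm2/s, `S0` in `(0, 2 max(signal)]`).
#' @return A `fit_options` object.
#' @export
fit_options <- function(method = c("segmented_fix_df", "segmented_refit_f",
                                   "full_nlls"),
                        b_threshold = 200,
                        wlls_iterations = 2,
                        dstar_init_multiplier = 10,
                        bounds = NULL) {
  method <- match.arg(method)
  stopifnot(b_threshold >= 0, wlls_iterations >= 1,
            dstar_init_multiplier > 0)
  if (!is.null(bounds)) {
    stopifnot(is.list(bounds), all(c("lower", "upper") %in% names(bounds)))
    if (any(bounds$lower >= bounds$upper[names(bounds$lower)]))
      stop("bounds must satisfy lower < upper")
    if (!is.na(bounds$lower["f"]) &&
        (bounds$lower["f"] < 0 || bounds$upper["f"] > 1))
      stop("f bounds must lie within [0, 1]")
  }
  structure(list(method = method, b_threshold = b_threshold,
                 wlls_iterations = as.integer(wlls_iterations),
                 dstar_init_multiplier = dstar_init_multiplier,
                 bounds = bounds),
            class = "fit_options")
}

default_bounds <- function(max_signal) {
  list(lower = c(S0 = 1e-12, f = 0, D = 1e-5, Dstar = 1e-5),
       upper = c(S0 = 2 * max_signal, f = 1, D = 5e-3, Dstar = 0.5))
}

resolve_bounds <- function(options, max_signal) {
  b <- default_bounds(max_signal)
  if (!is.null(options$bounds)) {
    for (side in c("lower", "upper")) {
      user <- options$bounds[[side]]
      b[[side]][names(user)] <- user
    }
  }
  b
}

fit_result <- function(estimates, flags = character(0), rss = NA_real_,
                       converged = TRUE, options = NULL) {
  structure(list(estimates = estimates, flags = flags, rss = rss,
                 converged = converged, options = options),
            class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("IVIM fit (%s): f = %.4g, D = %.4g, D* = %.4g, S0 = %.4g\n",
              if (is.null(x$options)) "?" else x$options$method,
              e["f"], e["D"], e["Dstar"], e["S0"]))
  cat(sprintf("  RSS %.4g, converged %s%s\n", x$rss, x$converged,
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Coerce a fit result to an IVIM parameter object
#'
#' Fails if any estimate is undefined (e.g. D* after an f = 0 clip).
#' @param x An `ivim_fit` result.
#' @return An [ivim_params()] object.
#' @export
as_ivim_params <- function(x) {
  stopifnot(inherits(x, "ivim_fit"))
  e <- x$estimates
  if (any(is.na(e)))
    stop("fit result contains undefined estimates: ",
         paste(names(e)[is.na(e)], collapse = ", "))
  ivim_params(f = e[["f"]], D = e[["D"]], Dstar = e[["Dstar"]],
              S0 = e[["S0"]])
}

#' Iterative weighted linear least squares on the log-signal
#'
#' Fits `ln S = ln(intercept) - b D` by weighted linear regression. Weights
#' equal the squared signal amplitudes (the correct first-order weighting for
#' log-transformed data with additive noise): the first iteration uses the
#' observed signals, each further iteration refreshes the weights from the
#' current model-predicted signals.
#'
#' @param bvalues Numeric vector of b-values (>= 2 distinct).
#' @param signals Numeric vector of signal values; non-positive entries are
#'   dropped with a warning (the logarithm is undefined there).
#' @param iterations Number of weighted fits (>= 1).
#' @return A list with `D` (slope magnitude, mm2/s) and `intercept`
#'   (extrapolated signal at b = 0).
#' @examples
#' fit_loglinear_wlls(c(200, 500, 800), exp(-c(200, 500, 800) * 1.5e-3))
#' @export
fit_loglinear_wlls <- function(bvalues, signals, iterations = 2) {
  stopifnot(is.numeric(bvalues), is.numeric(signals),
            length(bvalues) == length(signals), iterations >= 1)
  keep <- is.finite(signals) & signals > 0 & is.finite(bvalues)
  if (any(!keep)) {
    warning("excluding ", sum(!keep),
            " sample(s) with non-positive or missing signal")
    bvalues <- bvalues[keep]; signals <- signals[keep]
  }
  if (length(unique(bvalues)) < 2L)
    stop("need at least 2 distinct b-values with positive signal")
  y <- log(signals)
  w <- signals^2
  for (i in seq_len(iterations)) {
    # weighted straight-line fit, closed form
    sw <- sum(w); mb <- sum(w * bvalues) / sw; my <- sum(w * y) / sw
    sxx <- sum(w * (bvalues - mb)^2)
    slope <- if (sxx > 0) sum(w * (bvalues - mb) * (y - my)) / sxx else 0
    ic <- my - slope * mb
    if (i < iterations) w <- exp(2 * (ic + slope * bvalues))
  }
  list(D = -slope, intercept = exp(ic))
}

# residuals and Jacobian of the biexponential model in the
# (S0, f, D, delta = Dstar - D) parameterization used by the bounded fits
ivim_resid <- function(par, b, s, fixed) {
  p <- c(par, fixed)
  Ds <- p[["D"]] + p[["delta"]]
  s - p[["S0"]] * (p[["f"]] * exp(-b * Ds) +
                   (1 - p[["f"]]) * exp(-b * p[["D"]]))
}

ivim_jac <- function(par, b, s, fixed) {
  p <- c(par, fixed)
  S0 <- p[["S0"]]; f <- p[["f"]]; D <- p[["D"]]; Ds <- D + p[["delta"]]
  eDs <- exp(-b * Ds); eD <- exp(-b * D)
  cols <- list(
    S0 = -(f * eDs + (1 - f) * eD),
    f = -S0 * (eDs - eD),
    D = S0 * b * (f * eDs + (1 - f) * eD),
    delta = S0 * f * b * eDs)
  do.call(cbind, cols[names(par)])
}

run_lm <- function(par, lower, upper, b, s, fixed) {
  fit <- minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper,
    fn = ivim_resid, jac = ivim_jac, b = b, s = s, fixed = fixed,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  list(par = fit$par, rss = fit$deviance,
       converged = fit$info %in% 1:4)
}

#' Segmented (two-step) IVIM fit
#'
#' The consensus estimation routine. Step 1 fits the mono-exponential
#' diffusion decay to the b-values at or above `b_threshold` by iterative
#' WLLS ([fit_loglinear_wlls()]), giving `D` and the extrapolated intercept;
#' the perfusion fraction follows as
#' `f = 1 - intercept / mean(signal at b = 0)` (the measured b = 0 signal,
#' not a fitted S0). Step 2 fits the full biexponential to all b-values with
#' `D` frozen — and, for `segmented_fix_df`, `f` and `S0` frozen too — to
#' estimate `Dstar`, initialized at `dstar_init_multiplier * D`.
#'
#' A negative step-1 `f` is clipped to 0 and flagged (`"f_clipped"`); `Dstar`
#' is then undefined and reported as `NA`. Step-2 non-convergence is flagged
#' (`"step2_no_convergence"`) with the step-1 values still returned.
#'
#' @param bvalues,signals Numeric vectors (same length). Requires at least
#'   2 distinct b-values >= `b_threshold`, at least one b = 0 measurement,
#'   and at least one b strictly between 0 and the threshold.
#' @param options A [fit_options()] object.
#' @return An `ivim_fit` with estimates `S0`, `f`, `D`, `Dstar`.
#' @export
segmented_fit <- function(bvalues, signals, options = fit_options()) {
  stopifnot(inherits(options, "fit_options"),
            length(bvalues) == length(signals))
  thr <- options$b_threshold
  hi <- bvalues >= thr
  if (length(unique(bvalues[hi])) < 2L)
    stop("need at least 2 distinct b-values >= b_threshold = ", thr)
  if (!any(bvalues == 0))
    stop("need at least one b = 0 measurement")
  if (!any(bvalues > 0 & bvalues < thr))
    stop("need at least one b-value strictly between 0 and b_threshold")
  bounds <- resolve_bounds(options, max(signals))

  step1 <- fit_loglinear_wlls(bvalues[hi], signals[hi],
                              options$wlls_iterations)
  s0_meas <- mean(signals[bvalues == 0])
  D <- min(max(step1$D, bounds$lower[["D"]]), bounds$upper[["D"]])
  f <- 1 - step1$intercept / s0_meas
  flags <- character(0)
  if (D != step1$D) flags <- c(flags, "D_at_bound")
  if (f <= 1e-12) {  # at or below zero: no resolvable perfusion signal
    flags <- c(flags, "f_clipped")
    est <- c(S0 = s0_meas, f = 0, D = D, Dstar = NA_real_)
    mono <- s0_meas * exp(-bvalues * D)
    return(fit_result(est, flags, rss = sum((signals - mono)^2),
                      converged = TRUE, options = options))
  }
  f <- min(f, bounds$upper[["f"]])

  ds_init <- min(max(options$dstar_init_multiplier * D, D),
                 bounds$upper[["Dstar"]])
  if (options$method == "segmented_refit_f") {
    lm <- run_lm(
      par = c(S0 = s0_meas, f = f, delta = ds_init - D),
      lower = c(S0 = bounds$lower[["S0"]], f = bounds$lower[["f"]],
                delta = 0),
      upper = c(S0 = bounds$upper[["S0"]], f = bounds$upper[["f"]],
                delta = bounds$upper[["Dstar"]]),
      b = bvalues, s = signals, fixed = c(D = D))
    est <- c(S0 = lm$par[["S0"]], f = lm$par[["f"]], D = D,
             Dstar = D + lm$par[["delta"]])
  } else {
    lm <- run_lm(
      par = c(delta = ds_init - D),
      lower = c(delta = 0), upper = c(delta = bounds$upper[["Dstar"]]),
      b = bvalues, s = signals, fixed = c(S0 = s0_meas, f = f, D = D))
    est <- c(S0 = s0_meas, f = f, D = D, Dstar = D + lm$par[["delta"]])
  }
  if (!lm$converged) flags <- c(flags, "step2_no_convergence")
  fit_result(est, flags, rss = lm$rss, converged = lm$converged,
             options = options)
}

#' Simultaneous nonlinear least-squares IVIM fit
#'
#' Bounded Levenberg-Marquardt minimization of the biexponential residuals
#' over all four parameters. Internally the model is parameterized in
#' `(S0, f, D, Dstar - D)` so the box constraint enforces `Dstar >= D`.
#' When no initial values are supplied, they are taken from a segmented fit
#' of the same data.
#'
#' @param bvalues,signals Numeric vectors; at least 4 distinct b-values.
#' @param init Optional [ivim_params()] starting point.
#' @param options A [fit_options()]; its `b_threshold` is used for the
#'   initializing segmented fit and its `bounds` for the box constraints.
#' @return An `ivim_fit`. On non-convergence the flag
#'   `"no_convergence"` is set and the initial values are carried.
#' @export
full_nlls_fit <- function(bvalues, signals, init = NULL,
                          options = fit_options(method = "full_nlls")) {
  stopifnot(length(bvalues) == length(signals))
  if (length(unique(bvalues)) < 4L)
    stop("need at least 4 distinct b-values for a 4-parameter fit, got ",
         length(unique(bvalues)))
  bounds <- resolve_bounds(options, max(signals))
  flags <- character(0)
  if (is.null(init)) {
    seg_opts <- fit_options(method = "segmented_fix_df",
                            b_threshold = options$b_threshold,
                            wlls_iterations = options$wlls_iterations,
                            dstar_init_multiplier =
                              options$dstar_init_multiplier,
                            bounds = options$bounds)
    seg <- try(segmented_fit(bvalues, signals, seg_opts), silent = TRUE)
    if (!inherits(seg, "try-error") && !any(is.na(seg$estimates))) {
      e <- seg$estimates
      init <- ivim_params(f = max(e[["f"]], 1e-3), D = e[["D"]],
                          Dstar = max(e[["Dstar"]], e[["D"]] * 1.01),
                          S0 = e[["S0"]])
    } else {
      s0g <- mean(signals[bvalues == min(bvalues)])
      init <- ivim_params(f = 0.1, D = 1e-3, Dstar = 10e-3, S0 = s0g)
      flags <- c(flags, "heuristic_init")
    }
  }
  stopifnot(inherits(init, "ivim_params"))
  clip <- function(x, lo, hi) min(max(x, lo), hi)
  par0 <- c(S0 = clip(init$S0, bounds$lower[["S0"]], bounds$upper[["S0"]]),
            f = clip(init$f, bounds$lower[["f"]], bounds$upper[["f"]]),
            D = clip(init$D, bounds$lower[["D"]], bounds$upper[["D"]]),
            delta = clip(init$Dstar - init$D, 0, bounds$upper[["Dstar"]]))
  lm <- run_lm(
    par = par0,
    lower = c(S0 = bounds$lower[["S0"]], f = bounds$lower[["f"]],
              D = bounds$lower[["D"]], delta = 0),
    upper = c(S0 = bounds$upper[["S0"]], f = bounds$upper[["f"]],
              D = bounds$upper[["D"]], delta = bounds$upper[["Dstar"]]),
    b = bvalues, s = signals, fixed = numeric(0))
  if (!lm$converged) {
    flags <- c(flags, "no_convergence")
    est <- c(S0 = init$S0, f = init$f, D = init$D, Dstar = init$Dstar)
    r <- signals - ivim_signal(init, bvalues)
    return(fit_result(est, flags, rss = sum(r^2), converged = FALSE,
                      options = options))
  }
  est <- c(S0 = lm$par[["S0"]], f = lm$par[["f"]], D = lm$par[["D"]],
           Dstar = lm$par[["D"]] + lm$par[["delta"]])
  fit_result(est, flags, rss = lm$rss, converged = TRUE, options = options)
}
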