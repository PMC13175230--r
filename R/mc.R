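#' Monte Carlo fit-error simulation
#'
#' Generates `n_reps` noisy realizations of the IVIM signal at the given
#' parameters and b-value set, fits each with the requested method, and
#' summarizes per-parameter recovery: relative bias
#' `(mean(est) - truth) / truth`, relative dispersion `sd(est) / truth`, and
#' the total relative error `sqrt(bias^2 + dispersion^2)` (the default
#' combination of bias and dispersion; override via `metric`).
#'
#' Replicates whose fit does not converge, or whose estimate of a parameter
#' is undefined (e.g. D* after an f = 0 clip in the segmented fit), are
#' excluded from that parameter's moments; the affected fractions are
#' reported. A failure fraction above 50% flags the result unreliable.
#'
#' @param params True [ivim_params()].
#' @param bvalues B-value multiset to simulate.
#' @param noise A [noise_spec()]; its `seed` (or the `seed` argument, which
#'   takes precedence) makes the simulation reproducible.
#' @param options [fit_options()] selecting the estimator.
#' @param n_reps Number of replicates (>= 100).
#' @param seed Integer seed (overrides `noise$seed`).
#' @param metric Function `(bias, dispersion) -> total error`; default
#'   `sqrt(bias^2 + dispersion^2)`.
#' @return An `mc_result`: list with `bias`, `dispersion`, `total_error`
#'   (each named over `f`, `D`, `Dstar`, `S0`), `n_used` per parameter,
#'   `failed_fraction`, `unreliable`, plus the simulation metadata.
#' @examples
#' \donttest{
#' p <- preset_params(get_preset("kidney"))
#' simulate_errors(p, get_preset("kidney")$minimal_b,
#'                 noise_spec("gaussian", 25), n_reps = 200, seed = 1)
#' }
#' @export
simulate_errors <- function(params, bvalues,
                            noise = noise_spec("gaussian", 25),
                            options = fit_options(), n_reps = 1000,
                            seed = NULL,
                            metric = function(b, s) sqrt(b^2 + s^2)) {
  stopifnot(inherits(params, "ivim_params"), inherits(noise, "noise_spec"),
            inherits(options, "fit_options"), n_reps >= 100)
  if (is.null(seed)) seed <- noise$seed
  clean <- ivim_signal(params, bvalues)
  nb <- length(bvalues)
  sigma <- if (is.finite(noise$snr)) params$S0 / noise$snr else 0
  draws <- with_seed(seed, {
    z <- matrix(stats::rnorm(2L * n_reps * nb, 0, 1), nrow = 2L * n_reps)
    z
  })
  est <- matrix(NA_real_, n_reps, 4,
                dimnames = list(NULL, c("S0", "f", "D", "Dstar")))
  converged <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    e1 <- draws[2L * r - 1L, ] * sigma
    noisy <- if (noise$model == "rician")
      sqrt((clean + e1)^2 + (draws[2L * r, ] * sigma)^2)
    else clean + e1
    # per-replicate warnings (e.g. WLLS dropping a noise-negative sample at
    # low SNR) are routine; failures are tracked through the flags instead
    fit <- try(suppressWarnings(switch(options$method,
      full_nlls = full_nlls_fit(bvalues, noisy, options = options),
      segmented_fit(bvalues, noisy, options))), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      est[r, ] <- fit$estimates[colnames(est)]
      converged[r] <- fit$converged
    }
  }
  truth <- c(S0 = params$S0, f = params$f, D = params$D,
             Dstar = params$Dstar)
  usable <- est
  usable[!converged, ] <- NA_real_
  n_used <- colSums(is.finite(usable))
  mu <- colMeans(usable, na.rm = TRUE)
  sdv <- apply(usable, 2, stats::sd, na.rm = TRUE)
  bias <- (mu - truth) / truth
  disp <- sdv / truth
  total <- metric(bias, disp)
  failed <- 1 - mean(converged & is.finite(est[, "Dstar"]))
  structure(list(
    bias = bias[c("f", "D", "Dstar", "S0")],
    dispersion = disp[c("f", "D", "Dstar", "S0")],
    total_error = total[c("f", "D", "Dstar", "S0")],
    sd = sdv[c("f", "D", "Dstar", "S0")],
    n_used = n_used[c("f", "D", "Dstar", "S0")],
    failed_fraction = failed, unreliable = failed > 0.5,
    n_reps = n_reps, snr = noise$snr, noise_model = noise$model,
    method = options$method, seed = seed),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo (%d reps, %s noise, SNR %g, %s fit)%s\n",
              x$n_reps, x$noise_model, x$snr, x$method,
              if (x$unreliable) " [UNRELIABLE: >50% failures]" else ""))
  for (p in c("f", "D", "Dstar")) {
    cat(sprintf("  %-5s bias %+6.1f%%  dispersion %6.1f%%  total %6.1f%%  (n=%d)\n",
                p, 100 * x$bias[[p]], 100 * x$dispersion[[p]],
                100 * x$total_error[[p]], x$n_used[[p]]))
  }
  invisible(x)
}

#' Minimal SNR achieving a target total relative error
#'
#' Runs [simulate_errors()] at each SNR of an ascending grid — with common
#' random numbers across SNR levels, so the error-versus-SNR curve is not
#' jittered by independent sampling — and returns, per parameter, the
#' smallest grid SNR whose total relative error is at or below `target`.
#' The overall minimal SNR is the maximum over the parameters. No
#' interpolation between grid points is attempted.
#'
#' @param params True [ivim_params()].
#' @param bvalues B-value multiset.
#' @param target Target total relative error as a fraction (default 0.20).
#' @param options [fit_options()].
#' @param snr_grid Ascending SNR grid to scan.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param n_reps Replicates per SNR level.
#' @param seed Integer seed (shared across SNR levels).
#' @return A `min_snr_result`: per-parameter minimal SNR (`NA` with the
#'   max-SNR error reported when the target is unattainable on the grid),
#'   the overall minimal SNR, and the full error-versus-SNR table.
#' @export
min_snr_for_error <- function(params, bvalues, target = 0.20,
                              options = fit_options(),
                              snr_grid = c(10, 15, 20, 25, 35, 50, 75, 100,
                                           150, 200),
                              noise_model = "gaussian",
                              n_reps = 1000, seed = 1L) {
  stopifnot(target > 0, all(diff(snr_grid) > 0))
  tab <- lapply(snr_grid, function(s) {
    mc <- simulate_errors(params, bvalues,
                          noise_spec(noise_model, s), options,
                          n_reps = n_reps, seed = seed)
    mc$total_error[c("f", "D", "Dstar")]
  })
  err <- do.call(rbind, tab)
  rownames(err) <- snr_grid
  min_snr <- apply(err, 2, function(col) {
    ok <- which(col <= target)
    if (length(ok)) snr_grid[ok[1]] else NA_real_
  })
  overall <- if (anyNA(min_snr)) NA_real_ else max(min_snr)
  structure(list(min_snr = min_snr, overall = overall, target = target,
                 errors = err, snr_grid = snr_grid,
                 error_at_max_snr = err[nrow(err), ],
                 n_reps = n_reps, seed = seed),
            class = "min_snr_result")
}

#' @export
print.min_snr_result <- function(x, ...) {
  cat(sprintf("Minimal SNR for total relative error <= %.0f%%:\n",
              100 * x$target))
  for (p in colnames(x$errors)) {
    v <- x$min_snr[[p]]
    if (is.na(v))
      cat(sprintf("  %-5s above grid (%.1f%% at SNR %g)\n", p,
                  100 * x$error_at_max_snr[[p]], max(x$snr_grid)))
    else cat(sprintf("  %-5s SNR >= %g\n", p, v))
  }
  cat("  overall:", if (is.na(x$overall)) "above grid" else
    paste("SNR >=", x$overall), "\n")
  invisible(x)
}
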