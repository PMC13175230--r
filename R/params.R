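#' IVIM parameter set
#'
#' Bundles the parameters of the biexponential intravoxel incoherent motion
#' (IVIM) signal model: the pseudo-diffusion (perfusion) signal fraction `f`,
#' the tissue diffusion coefficient `D`, the pseudo-diffusion coefficient
#' `Dstar`, and the unweighted signal `S0` at b = 0.
#'
#' Units follow the field convention: b-values in s/mm2, `D` and `Dstar` in
#' mm2/s, so a typical tissue `D` is around 1e-3. `S0` is in arbitrary signal
#' units.
#'
#' `Dstar > D` is required for the identifiability-dependent operations
#' (segmented fitting interpretation, Fisher information); a violation is
#' not an error at construction time but is flagged so downstream code can
#' reject it with a specific message.
#'
#' @param f Pseudo-diffusion signal fraction, in `[0, 1]`.
#' @param D Tissue diffusion coefficient (mm2/s), > 0.
#' @param Dstar Pseudo-diffusion coefficient (mm2/s), > 0.
#' @param S0 Signal at b = 0 (arbitrary units), > 0.
#' @return An object of class `ivim_params`: a named list with elements
#'   `f`, `D`, `Dstar`, `S0`.
#' @examples
#' p <- ivim_params(f = 0.1, D = 1e-3, Dstar = 10e-3)
#' ivim_signal(p, c(0, 200, 800))
#' @export
ivim_params <- function(f, D, Dstar, S0 = 1) {
  stopifnot(is.numeric(f), is.numeric(D), is.numeric(Dstar), is.numeric(S0),
            length(f) == 1L, length(D) == 1L, length(Dstar) == 1L,
            length(S0) == 1L)
  if (is.na(f) || f < 0 || f > 1)
    stop("'f' must lie in [0, 1], got ", f)
  if (is.na(D) || D <= 0)
    stop("'D' must be > 0 (mm2/s), got ", D)
  if (is.na(Dstar) || Dstar <= 0)
    stop("'Dstar' must be > 0 (mm2/s), got ", Dstar)
  if (is.na(S0) || S0 <= 0)
    stop("'S0' must be > 0, got ", S0)
  structure(list(f = as.numeric(f), D = as.numeric(D),
                 Dstar = as.numeric(Dstar), S0 = as.numeric(S0)),
            class = "ivim_params")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf(
    "IVIM parameters: f = %.4g, D = %.4g mm2/s, D* = %.4g mm2/s, S0 = %.4g\n",
    x$f, x$D, x$Dstar, x$S0))
  if (!ivim_identifiable(x))
    cat("  note: D* <= D; pseudo-diffusion compartment not identifiable\n")
  invisible(x)
}

#' Check the D* > D identifiability condition
#'
#' Segmented fitting and the Cramer-Rao analysis both rest on the assumption
#' that the pseudo-diffusion compartment decays much faster than the tissue
#' compartment; at minimum `Dstar > D` must hold.
#'
#' @param params An [ivim_params()] object.
#' @return `TRUE` if `Dstar > D`, else `FALSE`.
#' @export
ivim_identifiable <- function(params) {
  stopifnot(inherits(params, "ivim_params"))
  params$Dstar > params$D
}

#' Noise specification for simulated DWI signals
#'
#' SNR is defined at b = 0: the noise standard deviation is
#' `sigma = S0 / snr`, constant across b-values. Gaussian noise adds
#' `N(0, sigma^2)` to each signal; Rician noise forms the magnitude
#' `sqrt((s + e1)^2 + e2^2)` with independent Gaussian `e1`, `e2`, the
#' distribution of magnitude-reconstructed MR images.
#'
#' @param model `"gaussian"` or `"rician"`.
#' @param snr Signal-to-noise ratio at b = 0; > 0. `Inf` means noise-free.
#' @param seed Optional integer seed making draws reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("gaussian", "rician"), snr = 25, seed = NULL) {
  if (!is.character(model) || !(model[1L] %in% c("gaussian", "rician")))
    stop("unknown noise model '", model[1L],
         "'; supported models: gaussian, rician")
  model <- model[1L]
  stopifnot(is.numeric(snr), length(snr) == 1L)
  if (is.na(snr) || snr <= 0) stop("'snr' must be > 0, got ", snr)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(model = model, snr = as.numeric(snr), seed = seed),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Noise: %s, SNR %.4g%s\n", x$model, x$snr,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. seed = NULL uses (and advances) the global
# stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
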