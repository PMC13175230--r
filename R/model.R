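#' Biexponential IVIM signal
#'
#' Evaluates the intravoxel incoherent motion signal model
#' \deqn{S(b) = S_0 \left[ f e^{-b D^*} + (1 - f) e^{-b D} \right]}
#' at the requested diffusion weightings. The first term is the fast-decaying
#' pseudo-diffusion (perfusion) compartment, the second the tissue water
#' compartment.
#'
#' @param params An [ivim_params()] object.
#' @param bvalues Numeric vector of b-values (s/mm2), all >= 0.
#' @return Numeric vector of signal values, one per b-value.
#' @examples
#' p <- ivim_params(f = 0.1, D = 1e-3, Dstar = 10e-3)
#' ivim_signal(p, c(0, 200, 800))
#' @export
ivim_signal <- function(params, bvalues) {
  stopifnot(inherits(params, "ivim_params"), is.numeric(bvalues))
  bad <- which(is.na(bvalues) | bvalues < 0)
  if (length(bad))
    stop("negative or missing b-value at index ",
         paste(bad, collapse = ", "))
  params$S0 * (params$f * exp(-bvalues * params$Dstar) +
               (1 - params$f) * exp(-bvalues * params$D))
}

#' Add measurement noise to a signal vector
#'
#' Gaussian noise adds `N(0, sigma^2)`; Rician noise returns the magnitude
#' `sqrt((s + e1)^2 + e2^2)` of the complex signal with independent Gaussian
#' quadrature components. In both cases `sigma = s0 / spec$snr`: SNR is
#' anchored at the unweighted (b = 0) signal level and constant across
#' b-values.
#'
#' @param signal Numeric vector of noise-free signal values.
#' @param spec A [noise_spec()].
#' @param s0 Signal scale defining sigma (typically the model `S0`).
#' @return Numeric vector of noisy signals, same length as `signal`.
#' @export
add_noise <- function(signal, spec, s0) {
  stopifnot(is.numeric(signal), inherits(spec, "noise_spec"),
            is.numeric(s0), length(s0) == 1L, s0 > 0)
  if (!is.finite(spec$snr)) return(signal)  # snr = Inf: sigma = 0
  sigma <- s0 / spec$snr
  n <- length(signal)
  with_seed(spec$seed, {
    switch(spec$model,
      gaussian = signal + stats::rnorm(n, 0, sigma),
      rician = {
        e1 <- stats::rnorm(n, 0, sigma)
        e2 <- stats::rnorm(n, 0, sigma)
        sqrt((signal + e1)^2 + e2^2)
      })
  })
}

#' T2-corrected perfusion fraction
#'
#' The measured IVIM `f` is a *signal* fraction at the acquisition TE: the
#' blood and tissue compartments are weighted by their respective T2 decays,
#' \deqn{f_{meas} = \frac{f\, e^{-TE/T2_{blood}}}
#'   {f\, e^{-TE/T2_{blood}} + (1-f)\, e^{-TE/T2_{tissue}}}.}
#' Given both T2 values, this function inverts that weighting to recover the
#' relaxation-free compartment fraction (a blood *volume* fraction under the
#' two-compartment assumption).
#'
#' @param f_measured Measured signal fraction, in `[0, 1]`.
#' @param te Echo time (ms), >= 0.
#' @param t2_tissue Tissue T2 (ms), > 0.
#' @param t2_blood Blood T2 (ms), > 0.
#' @return Corrected fraction in `[0, 1]`.
#' @examples
#' t2_corrected_f(0.2, te = 60, t2_tissue = 50, t2_blood = 150)
#' @export
t2_corrected_f <- function(f_measured, te, t2_tissue, t2_blood) {
  stopifnot(is.numeric(f_measured), is.numeric(te),
            is.numeric(t2_tissue), is.numeric(t2_blood))
  if (any(f_measured < 0 | f_measured > 1))
    stop("'f_measured' must lie in [0, 1]")
  if (any(te < 0)) stop("'te' must be >= 0")
  if (any(t2_tissue <= 0) || any(t2_blood <= 0))
    stop("T2 values must be > 0")
  wb <- exp(-te / t2_blood)
  wt <- exp(-te / t2_tissue)
  # closed-form inversion of the forward weighting
  f <- f_measured * wt / (wb - f_measured * (wb - wt))
  pmin(pmax(f, 0), 1)
}

#' b-value suppressing the pseudo-diffusion term
#'
#' Returns the diffusion weighting at which the perfusion compartment has
#' decayed by a given factor: `b = ln(factor) / Dstar`. With the default
#' factor of 20 (`exp(-b Dstar) ~ 0.05`) this is approximately `3 / Dstar`,
#' the rule used to justify the segmented-fitting threshold b-value.
#'
#' @param dstar Pseudo-diffusion coefficient (mm2/s), > 0.
#' @param factor Suppression factor, > 1 (default 20).
#' @return b-value in s/mm2.
#' @examples
#' suppression_bvalue(0.011)  # brain-like D*: about 272 s/mm2
#' @export
suppression_bvalue <- function(dstar, factor = 20) {
  stopifnot(is.numeric(dstar), is.numeric(factor))
  if (any(dstar <= 0)) stop("'dstar' must be > 0, got ", dstar[dstar <= 0][1L])
  if (any(factor < 1)) stop("'factor' must be >= 1")
  log(factor) / dstar
}
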