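# Independent scalar evaluation of the biexponential model, used as the
# oracle wherever a test must not trust ivim_signal() itself.
biexp_oracle <- function(f, D, Dstar, S0, b) {
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))
}

# forward T2 relaxation weighting of a compartment fraction
t2_weighting_oracle <- function(f, te, t2_tissue, t2_blood) {
  wb <- exp(-te / t2_blood)
  wt <- exp(-te / t2_tissue)
  f * wb / (f * wb + (1 - f) * wt)
}

kidney_like <- function() ivim_params(f = 0.15, D = 1.5e-3, Dstar = 50e-3)
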