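#' Fisher information matrix of the IVIM model under Gaussian noise
#'
#' For independent Gaussian measurements with common standard deviation
#' `sigma`, the information matrix over the free parameters
#' `(S0, f, D, Dstar)` is `(1/sigma^2) * sum_b grad(b) grad(b)^T` with
#' \deqn{\partial S/\partial S_0 = S/S_0,\quad
#'   \partial S/\partial f = S_0 (e^{-bD^*} - e^{-bD}),}
#' \deqn{\partial S/\partial D = -S_0 (1-f)\, b\, e^{-bD},\quad
#'   \partial S/\partial D^* = -S_0 f\, b\, e^{-bD^*}.}
#' Repeated b-values contribute additively.
#'
#' @param params An [ivim_params()]; `f` strictly inside `(0, 1)` and
#'   `Dstar != D` are required for invertibility.
#' @param bvalues Numeric vector of b-values (repeats allowed).
#' @param sigma Noise standard deviation (signal units).
#' @return A 4x4 matrix with dimnames `S0, f, D, Dstar`.
#' @export
fisher_information <- function(params, bvalues, sigma) {
  stopifnot(inherits(params, "ivim_params"), is.numeric(bvalues),
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (any(bvalues < 0)) stop("b-values must be >= 0")
  if (params$f <= 0)
    stop("singular information: f = 0 leaves Dstar unidentifiable ",
         "(dS/dDstar is identically zero)")
  if (params$f >= 1)
    stop("singular information: f = 1 leaves D unidentifiable")
  if (params$Dstar == params$D)
    stop("singular information: Dstar = D collapses the model to a ",
         "mono-exponential")
  if (length(unique(bvalues)) < 4L)
    stop("singular information: need at least 4 distinct b-values for 4 ",
         "free parameters, got ", length(unique(bvalues)))
  g <- ivim_gradients(params, bvalues)
  J <- (g %*% t(g)) / sigma^2
  dimnames(J) <- list(c("S0", "f", "D", "Dstar"), c("S0", "f", "D", "Dstar"))
  J
}

# 4 x nb matrix of model gradients, rows S0, f, D, Dstar
ivim_gradients <- function(params, bvalues) {
  S0 <- params$S0; f <- params$f; D <- params$D; Ds <- params$Dstar
  eDs <- exp(-bvalues * Ds); eD <- exp(-bvalues * D)
  rbind(f * eDs + (1 - f) * eD,
        S0 * (eDs - eD),
        -S0 * (1 - f) * bvalues * eD,
        -S0 * f * bvalues * eDs)
}

#' Cramer-Rao lower-bound uncertainties
#'
#' Inverts the Gaussian-noise Fisher information at `sigma = S0 / snr` and
#' reports the per-parameter lower-bound standard deviations together with
#' the design error metric: the sum of the *relative* uncertainties in D and
#' D* and the *absolute* uncertainty in f (absolute, so the metric does not
#' diverge as f approaches 0).
#'
#' @param params An [ivim_params()].
#' @param bvalues Numeric vector of b-values (repeats allowed).
#' @param snr Signal-to-noise ratio at b = 0 (> 0).
#' @return A `crlb_result`: list with `sigma` (named lower-bound SDs),
#'   `relative` (`sigma_D/D`, `sigma_Dstar/Dstar`, and `sigma_f/f`),
#'   `sigma_f_abs`, and scalar `cost`.
#' @examples
#' p <- ivim_params(0.12, 2e-3, 40e-3)
#' crlb_uncertainties(p, c(0, 30, 70, 100, 200, 800), snr = 25)
#' @export
crlb_uncertainties <- function(params, bvalues, snr) {
  stopifnot(is.numeric(snr), length(snr) == 1L, snr > 0)
  sigma <- params$S0 / snr
  J <- fisher_information(params, bvalues, sigma)
  # assess conditioning on the unit-diagonal-scaled matrix: the raw J mixes
  # units (S0 ~ 1, D ~ 1e-3) and its raw condition number is meaningless
  d <- diag(J)
  if (any(d <= 0))
    stop("singular information matrix for this b-value set: a parameter ",
         "has no signal sensitivity at these measurements")
  sc <- sqrt(d)
  Jn <- J / tcrossprod(sc)
  if (rcond(Jn) < 1e-12)
    stop("singular information matrix for this b-value set ",
         "(condition number too small): parameters are not jointly ",
         "identifiable from these measurements")
  co <- solve(Jn) / tcrossprod(sc)
  s <- sqrt(pmax(diag(co), 0))
  names(s) <- colnames(J)
  rel <- c(f = s[["f"]] / params$f, D = s[["D"]] / params$D,
           Dstar = s[["Dstar"]] / params$Dstar)
  structure(list(sigma = s, relative = rel, sigma_f_abs = s[["f"]],
                 cost = rel[["D"]] + rel[["Dstar"]] + s[["f"]],
                 snr = snr, bvalues = sort(bvalues)),
            class = "crlb_result")
}

#' @export
print.crlb_result <- function(x, ...) {
  cat("CRLB at SNR", x$snr, "for b = {",
      paste(x$bvalues, collapse = " "), "}\n")
  cat(sprintf("  sigma: S0 %.3g, f %.3g, D %.3g, D* %.3g\n",
              x$sigma[["S0"]], x$sigma[["f"]], x$sigma[["D"]],
              x$sigma[["Dstar"]]))
  cat(sprintf("  relative: f %.1f%%, D %.1f%%, D* %.1f%%; cost %.4g\n",
              100 * x$relative[["f"]], 100 * x$relative[["D"]],
              100 * x$relative[["Dstar"]], x$cost))
  invisible(x)
}

#' Specification of a b-value design problem
#'
#' Describes the search space for [optimize_bvalues()] and the prior grid
#' over which [design_cost()] averages: candidate b-values, the number of
#' measurements, the always-included fixed set (typically the abbreviated
#' tier), the SNR, and the parameter prior (mean and SD per parameter,
#' spanned from one SD below to one SD above the mean by `grid_points`
#' points per parameter).
#'
#' Prior grid points whose `f` falls at or below zero are floored at
#' `f_floor` (the design metric is built to stay finite for small f, and a
#' zero f is singular).
#'
#' @param prior List with named numeric vectors `f`, `D`, `Dstar`, each
#'   `c(mean =, sd =)` (as in `get_preset(...)$prior`).
#' @param fixed_b Fixed b-values always included in the design.
#' @param candidate_b Candidate grid for the free values (default 0 to 1000
#'   in steps of 10 s/mm2).
#' @param n_total Total number of b-values in the design (default 6).
#' @param snr Design SNR (default 25, the reference worst case).
#' @param grid_points Prior grid resolution per parameter (default 3:
#'   mean - SD, mean, mean + SD).
#' @param f_floor Lower floor for f on the prior grid (default 0.01).
#' @return A `design_spec` object.
#' @export
design_spec <- function(prior, fixed_b, candidate_b = seq(0, 1000, by = 10),
                        n_total = 6, snr = 25, grid_points = 3,
                        f_floor = 0.01) {
  stopifnot(is.list(prior), all(c("f", "D", "Dstar") %in% names(prior)),
            is.numeric(fixed_b), is.numeric(candidate_b),
            n_total >= length(fixed_b), snr > 0, grid_points >= 1,
            f_floor > 0)
  if (!all(fixed_b %in% candidate_b))
    stop("all fixed b-values must lie on the candidate grid")
  spec <- structure(list(prior = prior, fixed_b = sort(fixed_b),
                         candidate_b = sort(unique(candidate_b)),
                         n_total = as.integer(n_total), snr = snr,
                         grid_points = as.integer(grid_points),
                         f_floor = f_floor),
                    class = "design_spec")
  grid <- prior_grid(spec)  # validates invariants
  if (any(grid$Dstar <= grid$D))
    stop("prior grid contains points with Dstar <= D; the design problem ",
         "is not identifiable there")
  spec
}

#' Design spec from an organ preset
#'
#' Convenience wrapper fixing the abbreviated-tier b-values and using the
#' preset's priors and reference SNR.
#' @param preset An [get_preset()] result.
#' @param ... Overrides passed to [design_spec()].
#' @export
design_spec_from_preset <- function(preset, ...) {
  stopifnot(inherits(preset, "organ_preset"))
  args <- list(prior = preset$prior, fixed_b = preset$abbreviated_b,
               snr = preset$reference_snr)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(design_spec, args)
}

# expand the prior into its evaluation grid (data.frame f, D, Dstar)
prior_grid <- function(spec) {
  off <- if (spec$grid_points == 1) 0
         else seq(-1, 1, length.out = spec$grid_points)
  g <- expand.grid(
    f = spec$prior$f[["mean"]] + off * spec$prior$f[["sd"]],
    D = spec$prior$D[["mean"]] + off * spec$prior$D[["sd"]],
    Dstar = spec$prior$Dstar[["mean"]] + off * spec$prior$Dstar[["sd"]],
    KEEP.OUT.ATTRS = FALSE)
  g$f <- pmax(g$f, spec$f_floor)
  if (any(g$D <= 0) || any(g$Dstar <= 0))
    stop("prior grid contains non-positive D or Dstar")
  g
}

#' Grid-averaged design cost of a b-value set
#'
#' The scalar objective of the b-value optimization: the mean over the
#' prior grid of `sigma_D/D + sigma_Dstar/Dstar + sigma_f` at the spec's
#' SNR.
#'
#' @param bvalues Candidate b-value multiset (repeats allowed).
#' @param spec A [design_spec()].
#' @return Scalar cost.
#' @export
design_cost <- function(bvalues, spec) {
  stopifnot(inherits(spec, "design_spec"))
  grid <- prior_grid(spec)
  costs <- vapply(seq_len(nrow(grid)), function(i) {
    p <- ivim_params(f = grid$f[i], D = grid$D[i], Dstar = grid$Dstar[i])
    crlb_uncertainties(p, bvalues, spec$snr)$cost
  }, numeric(1))
  mean(costs)
}

#' Grid-averaged per-parameter uncertainties of a b-value set
#'
#' Averages the CRLB uncertainties over the prior grid, reporting the mean
#' relative uncertainty of each parameter (and the mean absolute
#' `sigma_f`). This is the quantity in which two candidate designs are
#' compared parameter by parameter.
#'
#' @inheritParams design_cost
#' @return Named vector `f`, `D`, `Dstar` (mean relative uncertainties, as
#'   fractions), plus `f_abs` (mean absolute sigma_f) and `cost`.
#' @export
design_uncertainties <- function(bvalues, spec) {
  stopifnot(inherits(spec, "design_spec"))
  grid <- prior_grid(spec)
  m <- vapply(seq_len(nrow(grid)), function(i) {
    p <- ivim_params(f = grid$f[i], D = grid$D[i], Dstar = grid$Dstar[i])
    u <- crlb_uncertainties(p, bvalues, spec$snr)
    c(u$relative[["f"]], u$relative[["D"]], u$relative[["Dstar"]],
      u$sigma_f_abs, u$cost)
  }, numeric(5))
  avg <- rowMeans(m)
  c(f = avg[1], D = avg[2], Dstar = avg[3], f_abs = avg[4], cost = avg[5])
}

#' Optimal b-value multiset by exhaustive search
#'
#' Fills the free slots (`n_total` minus the fixed set) by exhaustive
#' enumeration of candidate-grid multisets — repetition allowed, including
#' repeated b = 0 — minimizing [design_cost()]. Deterministic: enumeration
#' is lexicographic and ties resolve to the lexicographically smallest
#' multiset.
#'
#' @param spec A [design_spec()].
#' @return A list of class `bvalue_design` with `bvalues` (sorted optimal
#'   multiset), `cost`, and the `spec`.
#' @examples
#' \donttest{
#' spec <- design_spec_from_preset(get_preset("kidney"),
#'                                 candidate_b = seq(0, 1000, by = 50))
#' optimize_bvalues(spec)
#' }
#' @export
optimize_bvalues <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  n_free <- spec$n_total - length(spec$fixed_b)
  if (length(spec$candidate_b) == 0) stop("empty candidate grid")
  if (n_free == 0) {
    # cost is only defined when the fixed set alone identifies all four
    # parameters (>= 4 distinct b-values)
    cost <- tryCatch(design_cost(spec$fixed_b, spec),
                     error = function(e) NA_real_)
    return(structure(list(bvalues = sort(spec$fixed_b), cost = cost,
                          spec = spec),
                     class = "bvalue_design"))
  }
  grid <- prior_grid(spec)
  npts <- nrow(grid); ngrid <- length(spec$candidate_b)
  sigma <- 1 / spec$snr  # S0 = 1 on the prior grid
  info <- array(0, c(4, 4, npts * ngrid))
  jfixed <- array(0, c(4, 4, npts))
  divis <- matrix(0, npts, 3)
  for (p in seq_len(npts)) {
    par <- ivim_params(f = grid$f[p], D = grid$D[p], Dstar = grid$Dstar[p])
    g <- ivim_gradients(par, spec$candidate_b)
    for (j in seq_len(ngrid))
      info[, , (p - 1) * ngrid + j] <- tcrossprod(g[, j]) / sigma^2
    gf <- ivim_gradients(par, spec$fixed_b)
    jfixed[, , p] <- (gf %*% t(gf)) / sigma^2
    divis[p, ] <- c(1, grid$D[p], grid$Dstar[p])  # f absolute, D/D* relative
  }
  res <- crlb_scan(info, jfixed, divis, ngrid, n_free)
  if (!is.finite(res$cost))
    stop("no feasible design found: every candidate multiset gave a ",
         "singular information matrix")
  bv <- sort(c(spec$fixed_b, spec$candidate_b[res$indices]))
  structure(list(bvalues = bv, cost = res$cost, spec = spec),
            class = "bvalue_design")
}

#' @export
print.bvalue_design <- function(x, ...) {
  cat("Optimal b-value set: {", paste(x$bvalues, collapse = " "),
      "} s/mm2\n")
  cat(sprintf("  design cost %.4g at SNR %g (fixed: {%s})\n", x$cost,
              x$spec$snr, paste(x$spec$fixed_b, collapse = " ")))
  invisible(x)
}
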