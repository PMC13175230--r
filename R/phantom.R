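#' Generate a digital IVIM phantom
#'
#' Builds a synthetic DWI series from an organ preset: voxelwise true
#' parameters are drawn from the preset's literature prior (truncated to
#' valid ranges: f in `[f_floor, 1]`, D > 0, D* > D), the noise-free signal
#' follows the biexponential model at the tier's b-values, and noise is
#' added per the [noise_spec()]. When `n_directions = 3`, three
#' direction-encoded volumes are generated per b-value (sharing a frame id,
#' so [collapse_trace()] recombines them); the phantom is isotropic, so the
#' three share the same clean signal and differ only by noise.
#'
#' The ground truth (per-voxel parameter maps and the label map) is
#' retained, making the phantom usable as an end-to-end oracle for the
#' fitting pipeline.
#'
#' @param preset [get_preset()] output.
#' @param geometry List with `dim` (length-3 integer) and optional `labels`
#'   (3D integer array, 0 = background); default a single ROI filling the
#'   volume.
#' @param noise A [noise_spec()].
#' @param tier `"minimal"`, `"abbreviated"`, or a numeric b-vector.
#' @param n_directions 1 (trace only) or 3 (direction volumes per b).
#' @param S0 True unweighted signal level (arbitrary units).
#' @param seed Integer seed for the parameter draws and noise (overrides
#'   `noise$seed`).
#' @return A list with `series` (a [dwi_series()]) and `truth` (class
#'   `phantom_truth`: maps `f`, `D`, `Dstar`, `S0`, the `labels` map, the
#'   noise spec, preset name and seed).
#' @examples
#' ph <- generate_phantom(get_preset("kidney"),
#'                        geometry = list(dim = c(4, 4, 1)),
#'                        noise = noise_spec("rician", 50), seed = 7)
#' ph$series
#' @export
generate_phantom <- function(preset, geometry = list(dim = c(10, 10, 1)),
                             noise = noise_spec("gaussian", 25),
                             tier = "minimal", n_directions = 1,
                             S0 = 100, seed = NULL) {
  stopifnot(inherits(preset, "organ_preset"), inherits(noise, "noise_spec"),
            n_directions %in% c(1, 3))
  dm <- as.integer(geometry$dim)
  stopifnot(length(dm) == 3L, all(dm >= 1))
  labels <- if (!is.null(geometry$labels)) geometry$labels
            else array(1L, dm)
  stopifnot(identical(dim(labels), dm))
  bset <- if (is.numeric(tier)) tier
          else switch(match.arg(tier, c("minimal", "abbreviated")),
                      minimal = preset$minimal_b,
                      abbreviated = preset$abbreviated_b)
  if (is.null(seed)) seed <- noise$seed
  nvox <- prod(dm)
  inroi <- which(labels > 0)

  truth <- with_seed(seed, {
    draw_trunc <- function(n, mean, sd, lo, hi = Inf) {
      x <- stats::rnorm(n, mean, sd)
      bad <- which(x <= lo | x >= hi)
      while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[x[bad] <= lo | x[bad] >= hi]
      }
      x
    }
    f <- draw_trunc(length(inroi), preset$prior$f[["mean"]],
                    preset$prior$f[["sd"]], 0.01, 1)
    D <- draw_trunc(length(inroi), preset$prior$D[["mean"]],
                    preset$prior$D[["sd"]], 1e-5)
    Ds <- pmax(draw_trunc(length(inroi), preset$prior$Dstar[["mean"]],
                          preset$prior$Dstar[["sd"]], 1e-4), D * 2)
    list(f = f, D = D, Dstar = Ds)
  })
  fmap <- Dmap <- Dsmap <- S0map <- array(NA_real_, dm)
  fmap[inroi] <- truth$f; Dmap[inroi] <- truth$D
  Dsmap[inroi] <- truth$Dstar; S0map[inroi] <- S0

  nb <- length(bset)
  bvol <- rep(bset, each = n_directions)
  frames <- rep(seq_len(nb), each = n_directions)
  dirs <- if (n_directions == 3)
    matrix(rep(diag(3), nb), nrow = 3)  # orthogonal unit directions
  else NULL
  nvol <- length(bvol)

  clean <- matrix(0, nvox, nvol)
  for (i in seq_along(inroi)) {
    p <- ivim_params(f = truth$f[i], D = truth$D[i],
                     Dstar = truth$Dstar[i], S0 = S0)
    clean[inroi[i], ] <- ivim_signal(p, bvol)
  }
  sigma <- if (is.finite(noise$snr)) S0 / noise$snr else 0
  noisy <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    if (sigma == 0) clean
    else if (noise$model == "rician") {
      e1 <- matrix(stats::rnorm(nvox * nvol, 0, sigma), nvox)
      e2 <- matrix(stats::rnorm(nvox * nvol, 0, sigma), nvox)
      sqrt((clean + e1)^2 + e2^2)
    } else {
      pmax(clean + matrix(stats::rnorm(nvox * nvol, 0, sigma), nvox), 0)
    }
  })
  series <- dwi_series(array(noisy, c(dm, nvol)), bvol, directions = dirs,
                       mask = array(labels > 0, dm), frames = frames)
  truth_obj <- structure(list(f = fmap, D = Dmap, Dstar = Dsmap,
                              S0 = S0map, labels = labels, noise = noise,
                              organ = preset$organ, tier = bset,
                              seed = seed),
                         class = "phantom_truth")
  list(series = series, truth = truth_obj)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom truth (%s): %d ROI voxels, %s noise SNR %g, b = {%s}\n",
              x$organ, sum(x$labels > 0), x$noise$model, x$noise$snr,
              paste(x$tier, collapse = " ")))
  invisible(x)
}
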