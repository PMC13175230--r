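#' 4D diffusion-weighted series
#'
#' Binds a 4D signal array (x, y, z, volume) to its per-volume b-table,
#' optional unit direction vectors, optional brain/organ mask, and a list of
#' volumes excluded from analysis (e.g. after manual signal-void
#' inspection). `frames` groups volumes that are directional acquisitions of
#' the same measurement (same b, different gradient direction); the trace
#' collapse combines volumes within a frame by geometric mean.
#'
#' @param data 4D numeric array; signals >= 0.
#' @param bvalues Per-volume b-values (length = 4th dimension).
#' @param directions Optional 3 x nvol matrix of unit gradient directions.
#' @param mask Optional 3D logical/0-1 array matching the spatial dims.
#' @param excluded Integer indices of volumes to drop from analysis.
#' @param voxel_size Numeric length-3 voxel dimensions (mm).
#' @param frames Optional per-volume integer frame ids (defaults to one
#'   frame per volume, i.e. no direction grouping).
#' @return A `dwi_series` object.
#' @export
dwi_series <- function(data, bvalues, directions = NULL, mask = NULL,
                       excluded = integer(0), voxel_size = c(2, 2, 2),
                       frames = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L, is.numeric(bvalues))
  nvol <- dim(data)[4]
  if (length(bvalues) != nvol)
    stop("volume count (", nvol, ") != b-table length (", length(bvalues),
         ")")
  if (any(data < 0, na.rm = TRUE)) stop("signals must be >= 0")
  if (!is.null(directions)) {
    if (!is.matrix(directions) || nrow(directions) != 3L ||
        ncol(directions) != nvol)
      stop("directions must be a 3 x ", nvol, " matrix")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask)[1:3], dim(data)[1:3]))
      stop("mask dimensions must match the spatial dimensions")
    mask <- array(as.logical(mask), dim(mask))
  }
  excluded <- as.integer(excluded)
  if (length(excluded) && (any(excluded < 1) || any(excluded > nvol)))
    stop("excluded volume indices out of range 1..", nvol)
  if (is.null(frames)) frames <- seq_len(nvol)
  stopifnot(length(frames) == nvol)
  structure(list(data = data, bvalues = as.numeric(bvalues),
                 directions = directions, mask = mask,
                 excluded = excluded, voxel_size = voxel_size,
                 frames = as.integer(frames)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI series: %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat("  b-values:", paste(sort(unique(x$bvalues)), collapse = " "),
      "s/mm2\n")
  if (!is.null(x$directions)) cat("  with gradient directions\n")
  if (length(x$excluded))
    cat("  excluded volumes:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Collapse directional volumes to trace-weighted values
#'
#' Volumes sharing a frame id (three orthogonal directions at the same b)
#' are combined by geometric mean — the rotation-invariant trace-weighted
#' signal, equivalent to averaging log-signals. Excluded volumes are dropped
#' first; a frame losing all its volumes is dropped with a warning.
#'
#' @param series A [dwi_series()].
#' @return A `dwi_series` with one volume per surviving frame and no
#'   direction table.
#' @export
collapse_trace <- function(series) {
  stopifnot(inherits(series, "dwi_series"))
  keep <- setdiff(seq_along(series$bvalues), series$excluded)
  if (!length(keep)) stop("all volumes are excluded")
  frames <- series$frames[keep]
  ufr <- unique(frames)
  lost <- setdiff(unique(series$frames), ufr)
  if (length(lost))
    warning("frame(s) ", paste(lost, collapse = ", "),
            " lost all volumes to exclusion and were dropped")
  d <- dim(series$data)
  out <- array(NA_real_, c(d[1:3], length(ufr)))
  bout <- numeric(length(ufr))
  for (i in seq_along(ufr)) {
    vols <- keep[frames == ufr[i]]
    b <- unique(series$bvalues[vols])
    if (length(b) != 1L)
      stop("frame ", ufr[i], " mixes b-values: ", paste(b, collapse = ", "))
    bout[i] <- b
    sub <- series$data[, , , vols, drop = FALSE]
    # geometric mean across the 4th margin
    out[, , , i] <- exp(apply(log(sub), 1:3, mean))
  }
  dwi_series(out, bout, mask = series$mask,
             voxel_size = series$voxel_size)
}

#' Voxelwise IVIM fitting of a DWI series
#'
#' Collapses directional volumes to trace-weighted signals, drops excluded
#' volumes, and fits every voxel inside the mask with the requested method.
#' Voxels with any non-positive trace signal at a fitted b-value are skipped
#' and flagged rather than clipped (the log-domain step is undefined there).
#'
#' @param series A [dwi_series()].
#' @param options [fit_options()]; when a `preset` is given and no explicit
#'   options, the preset's threshold b-value is used.
#' @param preset Optional [get_preset()] result supplying the threshold.
#' @return An `ivim_maps` object: named list of 3D arrays `f`, `D`,
#'   `Dstar`, `S0`, `rss`, plus an integer `flag` map (0 ok, 1 outside
#'   mask/skipped, 2 fit failure, 3 f clipped at 0) and the collapsed
#'   b-table.
#' @export
fit_volume <- function(series, options = NULL, preset = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  if (is.null(options)) {
    thr <- if (!is.null(preset)) preset$b_threshold else 200
    options <- fit_options(b_threshold = thr)
  }
  tr <- collapse_trace(series)
  b <- tr$bvalues
  need_hi <- length(unique(b[b >= options$b_threshold])) >= 2L
  if (!any(b == 0) || !need_hi || !any(b > 0 & b < options$b_threshold))
    stop("collapsed b-table {", paste(sort(b), collapse = " "),
         "} cannot support the fit: need b = 0, >= 2 distinct b >= ",
         options$b_threshold, " and one b in between")
  d <- dim(tr$data)[1:3]
  mask <- if (!is.null(tr$mask)) tr$mask else array(TRUE, d)
  maps <- list(f = array(NA_real_, d), D = array(NA_real_, d),
               Dstar = array(NA_real_, d), S0 = array(NA_real_, d),
               rss = array(NA_real_, d))
  flag <- array(1L, d)
  idx <- which(mask)
  nvox <- prod(d)
  sig_mat <- matrix(tr$data, nrow = nvox)
  for (v in idx) {
    s <- sig_mat[v, ]
    if (any(!is.finite(s)) || any(s <= 0)) {
      flag[v] <- 1L
      next
    }
    fit <- try(switch(options$method,
      full_nlls = full_nlls_fit(b, s, options = options),
      segmented_fit(b, s, options)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      flag[v] <- 2L
      next
    }
    e <- fit$estimates
    maps$f[v] <- e[["f"]]; maps$D[v] <- e[["D"]]
    maps$Dstar[v] <- e[["Dstar"]]; maps$S0[v] <- e[["S0"]]
    maps$rss[v] <- fit$rss
    flag[v] <- if ("f_clipped" %in% fit$flags) 3L
               else if (!fit$converged) 2L else 0L
  }
  structure(c(maps, list(flag = flag, bvalues = b, options = options)),
            class = "ivim_maps")
}

#' @export
print.ivim_maps <- function(x, ...) {
  d <- dim(x$f)
  ok <- sum(x$flag == 0)
  cat(sprintf("IVIM parameter maps: %d x %d x %d (%d voxels fitted cleanly)\n",
              d[1], d[2], d[3], ok))
  cat(sprintf("  median f %.3g, D %.3g, D* %.3g\n",
              stats::median(x$f[x$flag == 0]),
              stats::median(x$D[x$flag == 0]),
              stats::median(x$Dstar[x$flag == 0])))
  invisible(x)
}
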