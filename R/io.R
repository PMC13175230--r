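#' Write a DWI series to NIfTI + FSL gradient tables
#'
#' Writes the 4D signal volume as NIfTI (`.nii` or `.nii.gz`), the b-table
#' as a one-line whitespace-separated `.bval` file and, when directions are
#' present, a 3-row `.bvec` file (the FSL dialect). Optionally a BIDS-style
#' JSON sidecar echoes the b-table and voxel size.
#'
#' @param series A [dwi_series()].
#' @param prefix Output path prefix: writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec` (if directions), `<prefix>.json`
#'   (if `sidecar`).
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @return Invisibly, the named vector of paths written.
#' @export
write_dwi <- function(series, prefix, sidecar = TRUE) {
  stopifnot(inherits(series, "dwi_series"))
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(series$data,
                         pixdim = c(series$voxel_size, 1))
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  writeLines(paste(format(series$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval)
  paths <- c(nii = nii, bval = bval)
  if (!is.null(series$directions)) {
    bvec <- paste0(prefix, ".bvec")
    writeLines(apply(series$directions, 1, paste, collapse = " "), bvec)
    paths <- c(paths, bvec = bvec)
  }
  if (sidecar) {
    js <- paste0(prefix, ".json")
    jsonlite::write_json(
      list(bvalues = series$bvalues, voxel_size = series$voxel_size,
           excluded_volumes = series$excluded,
           frames = series$frames),
      js, auto_unbox = FALSE, digits = NA)
    paths <- c(paths, json = js)
  }
  invisible(paths)
}

#' Read a DWI series from NIfTI + FSL gradient tables
#'
#' @param nii Path to the 4D NIfTI volume.
#' @param bval Path to the FSL `.bval` file (defaults to `nii` with the
#'   extension swapped).
#' @param bvec Optional path to the `.bvec` file.
#' @param json Optional path to a JSON sidecar (restores frames and
#'   exclusions written by [write_dwi()]).
#' @param mask Optional path to a 3D NIfTI mask.
#' @return A [dwi_series()].
#' @export
read_dwi <- function(nii, bval = NULL, bvec = NULL, json = NULL,
                     mask = NULL) {
  img <- RNifti::readNifti(nii)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) arr <- array(arr, c(dim(arr), 1L))
  if (is.null(bval)) bval <- sub("\\.nii(\\.gz)?$", ".bval", nii)
  bvals <- scan(bval, what = numeric(), quiet = TRUE)
  if (length(bvals) != dim(arr)[4])
    stop("b-table length (", length(bvals), ") != volume count (",
         dim(arr)[4], ")")
  dirs <- NULL
  if (!is.null(bvec) && file.exists(bvec)) {
    rows <- lapply(readLines(bvec), function(l)
      scan(text = l, what = numeric(), quiet = TRUE))
    dirs <- do.call(rbind, rows)
    if (nrow(dirs) != 3L || ncol(dirs) != dim(arr)[4])
      stop(".bvec must have 3 rows of ", dim(arr)[4], " entries")
  }
  frames <- NULL; excl <- integer(0)
  if (!is.null(json) && file.exists(json)) {
    side <- jsonlite::fromJSON(json)
    if (!is.null(side$frames)) frames <- side$frames
    if (!is.null(side$excluded_volumes))
      excl <- as.integer(side$excluded_volumes)
  }
  mk <- if (!is.null(mask)) {
    m <- as.array(RNifti::readNifti(mask))
    array(m > 0, dim(m))
  } else NULL
  vx <- attr(img, "pixdim")
  if (is.null(vx) || length(vx) < 3) vx <- c(1, 1, 1)
  dwi_series(arr, bvals, directions = dirs, mask = mk, excluded = excl,
             voxel_size = vx[1:3], frames = frames)
}

#' Write parameter maps to NIfTI
#'
#' One 3D NIfTI per parameter (`f`, `D`, `Dstar`, `S0`, `rss`, `flag`).
#' @param maps An `ivim_maps` object from [fit_volume()].
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of paths written.
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "ivim_maps"))
  paths <- character(0)
  for (nm in c("f", "D", "Dstar", "S0", "rss", "flag")) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]] * 1.0), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Per-ROI statistics of parameter maps
#'
#' For each ROI label and each parameter map, reports the mean, standard
#' deviation, median, interquartile range (Q3 - Q1, linear-interpolation
#' quantiles, R type 7) and voxel count over the voxels with a clean fit
#' flag. Empty labels are omitted with a warning.
#'
#' @param maps Named list of 3D arrays (e.g. an `ivim_maps` object, or the
#'   truth maps of a phantom); entries that are not numeric 3D arrays are
#'   ignored.
#' @param labels 3D integer label map (0 = background).
#' @param flag Optional 3D integer flag map; only voxels with flag 0 enter
#'   the statistics (taken from `maps$flag` if present).
#' @return A data.frame with columns `roi`, `parameter`, `mean`, `sd`,
#'   `median`, `iqr`, `n`.
#' @export
roi_stats <- function(maps, labels, flag = NULL) {
  stopifnot(is.array(labels))
  if (is.null(flag) && !is.null(maps$flag)) flag <- maps$flag
  keep <- vapply(maps, function(m)
    is.numeric(m) && is.array(m) && identical(dim(m), dim(labels)),
    logical(1))
  params <- names(maps)[keep & names(maps) %in%
                          c("f", "D", "Dstar", "S0", "rss")]
  rois <- sort(setdiff(unique(as.integer(labels)), 0L))
  out <- list()
  empty <- integer(0)
  for (r in rois) {
    sel <- labels == r
    if (!is.null(flag)) sel <- sel & flag == 0L
    if (!any(sel)) {
      empty <- c(empty, r)
      next
    }
    for (p in params) {
      v <- maps[[p]][sel]
      v <- v[is.finite(v)]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        roi = r, parameter = p, mean = mean(v), sd = stats::sd(v),
        median = q[2], iqr = q[3] - q[1], n = length(v))
    }
  }
  if (length(empty))
    warning("ROI label(s) with no usable voxels omitted: ",
            paste(empty, collapse = ", "))
  if (!length(out))
    return(data.frame(roi = integer(0), parameter = character(0),
                      mean = numeric(0), sd = numeric(0),
                      median = numeric(0), iqr = numeric(0),
                      n = integer(0)))
  do.call(rbind, out)
}
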