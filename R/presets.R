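# Consensus acquisition constants per organ system. The tiered b-value sets
# and threshold b-values are the published consensus recommendations; TR,
# averages, resolution and slice-thickness ranges follow the recommendation
# table (where that table merges columns ambiguously the values here are the
# documented defaults and every one is overridable on the protocol side).
.organ_table <- list(
  brain = list(
    abbreviated_b = c(0, 300, 1000),
    minimal_b = c(0, 0, 70, 300, 400, 1000),
    b_threshold = 300, tr_min = 4, averages_min = 1L,
    fat_suppression = "SPIR",
    resolution_range = c(1, 3), slice_range = c(1.2, 3)),
  breast = list(
    abbreviated_b = c(0, 200, 800),
    minimal_b = c(0, 30, 70, 200, 330, 800),
    b_threshold = 200, tr_min = 4, averages_min = 1L,
    fat_suppression = "SPAIR",
    resolution_range = c(1.8, 3), slice_range = c(2, 4)),
  kidney = list(
    abbreviated_b = c(0, 200, 800),
    minimal_b = c(0, 30, 70, 100, 200, 800),
    b_threshold = 200, tr_min = 3, averages_min = 1L,
    fat_suppression = "SPAIR",
    resolution_range = c(2, 3), slice_range = c(2.5, 5)),
  liver = list(
    abbreviated_b = c(0, 200, 500),
    minimal_b = c(0, 10, 20, 100, 200, 500),
    b_threshold = 200, tr_min = 3, averages_min = 1L,
    fat_suppression = "SPAIR",
    resolution_range = c(2, 4), slice_range = c(4, 6)),
  muscle = list(
    abbreviated_b = c(0, 200, 600),
    minimal_b = c(0, 40, 70, 200, 300, 600),
    b_threshold = 200, tr_min = 4, averages_min = 2L,
    fat_suppression = "SPAIR",
    resolution_range = c(1.8, 3), slice_range = c(4, 6)),
  pancreas = list(
    abbreviated_b = c(0, 200, 600),
    minimal_b = c(0, 0, 50, 200, 290, 600),
    b_threshold = 200, tr_min = 3, averages_min = 1L,
    fat_suppression = "SPAIR",
    resolution_range = c(2, 3), slice_range = c(2, 4))
)

#' Supported organ systems
#' @return Character vector of organ names.
#' @export
ivim_organs <- function() names(.organ_table)

#' Consensus organ preset
#'
#' Returns the per-organ consensus constants: the tiered b-value sets
#' (abbreviated: 3 values; minimal: 6 values; the advanced tier is any
#' superset of the minimal tier), the segmented-fitting threshold b-value,
#' acquisition minima and ranges, the reference SNR (25), and literature
#' parameter priors (mean and between-study SD for f, D, D*).
#'
#' Priors ship as clearly labeled synthetic placeholders in
#' `inst/extdata/organ_priors.json`; pass `priors_file` to substitute
#' study-specific constants (same JSON layout).
#'
#' @param organ One of [ivim_organs()].
#' @param priors_file Optional path to a JSON priors file overriding the
#'   packaged constants.
#' @return An `organ_preset` object.
#' @examples
#' get_preset("kidney")$minimal_b
#' @export
get_preset <- function(organ, priors_file = NULL) {
  if (!is.character(organ) || length(organ) != 1L ||
      !(organ %in% names(.organ_table)))
    stop("unknown organ '", paste(organ, collapse = ","),
         "'; supported organs: ",
         paste(names(.organ_table), collapse = ", "))
  path <- if (is.null(priors_file))
    system.file("extdata", "organ_priors.json", package = "ivimtools",
                mustWork = TRUE)
  else priors_file
  priors <- jsonlite::fromJSON(path)
  if (is.null(priors[[organ]]))
    stop("priors file '", path, "' has no entry for organ '", organ, "'")
  pr <- priors[[organ]]
  base <- .organ_table[[organ]]
  structure(c(list(organ = organ), base,
              list(te_rule = "minimum", n_directions_min = 3L,
                   reference_snr = 25,
                   prior = list(
                     f = c(mean = pr$f$mean, sd = pr$f$sd),
                     D = c(mean = pr$D$mean, sd = pr$D$sd),
                     Dstar = c(mean = pr$Dstar$mean, sd = pr$Dstar$sd)))),
            class = "organ_preset")
}

#' @export
print.organ_preset <- function(x, ...) {
  cat("Organ preset:", x$organ, "\n")
  cat("  abbreviated b:", paste(x$abbreviated_b, collapse = " "), "\n")
  cat("  minimal b:    ", paste(x$minimal_b, collapse = " "), "\n")
  cat(sprintf("  b_threshold %g s/mm2, TR >= %g s, averages >= %d, %s\n",
              x$b_threshold, x$tr_min, x$averages_min, x$fat_suppression))
  p <- x$prior
  cat(sprintf("  priors: f %.3g+/-%.3g, D %.3g+/-%.3g, D* %.3g+/-%.3g mm2/s\n",
              p$f["mean"], p$f["sd"], p$D["mean"], p$D["sd"],
              p$Dstar["mean"], p$Dstar["sd"]))
  invisible(x)
}

#' Prior mid-point of a preset as IVIM parameters
#' @param preset An `organ_preset`.
#' @param S0 Signal scale for the returned parameter set.
#' @return An [ivim_params()] at the prior means.
#' @export
preset_params <- function(preset, S0 = 1) {
  stopifnot(inherits(preset, "organ_preset"))
  ivim_params(f = preset$prior$f[["mean"]], D = preset$prior$D[["mean"]],
              Dstar = preset$prior$Dstar[["mean"]], S0 = S0)
}

#' Describe an acquisition protocol
#'
#' A container for the acquisition settings a site actually uses, checked
#' against the consensus preset by [check_protocol()] and inventoried by
#' [reporting_checklist()]. Every field except `organ` and `bvalues` is
#' optional (`NA`/`NULL` means "not provided"), mirroring how protocols
#' arrive in practice.
#'
#' @param organ Organ system name.
#' @param bvalues Acquired b-values (with repeats), s/mm2.
#' @param n_directions Number of diffusion directions.
#' @param n_averages Number of signal averages.
#' @param tr Repetition time (s).
#' @param te Echo time (ms).
#' @param delta_big Diffusion gradient separation, capital delta (ms).
#' @param delta_small Diffusion gradient duration, lowercase delta (ms).
#' @param max_gradient Maximum gradient strength (mT/m).
#' @param slew Slew rate (T/m/s).
#' @param field_strength Main field (T).
#' @param fat_suppression Fat suppression technique (text).
#' @param voxel_size In-plane voxel size (mm).
#' @param slice_thickness Slice thickness (mm).
#' @param echo_train_length,echo_spacing,bandwidth,acceleration_factor,
#'   oversampling,slice_gap,slice_order,reconstruction EPI readout and
#'   reconstruction descriptors (numbers or text; reporting only).
#' @return An `acquisition_protocol` object.
#' @export
acquisition_protocol <- function(organ, bvalues, n_directions = NA,
                                 n_averages = NA, tr = NA, te = NA,
                                 delta_big = NA, delta_small = NA,
                                 max_gradient = NA, slew = NA,
                                 field_strength = NA,
                                 fat_suppression = NA_character_,
                                 voxel_size = NA, slice_thickness = NA,
                                 echo_train_length = NA, echo_spacing = NA,
                                 bandwidth = NA, acceleration_factor = NA,
                                 oversampling = NA, slice_gap = NA,
                                 slice_order = NA_character_,
                                 reconstruction = NA_character_) {
  stopifnot(is.character(organ), length(organ) == 1L, is.numeric(bvalues))
  if (any(bvalues < 0)) stop("b-values must be >= 0")
  if (!is.na(tr) && tr <= 0) stop("'tr' must be > 0 s")
  if (!is.na(te) && te <= 0) stop("'te' must be > 0 ms")
  if (!is.na(n_directions) && n_directions < 1) stop("'n_directions' >= 1")
  if (!is.na(n_averages) && n_averages < 1) stop("'n_averages' >= 1")
  structure(list(
    organ = organ, bvalues = as.numeric(bvalues),
    n_directions = n_directions, n_averages = n_averages, tr = tr, te = te,
    delta_big = delta_big, delta_small = delta_small,
    max_gradient = max_gradient, slew = slew,
    field_strength = field_strength, fat_suppression = fat_suppression,
    voxel_size = voxel_size, slice_thickness = slice_thickness,
    echo_train_length = echo_train_length, echo_spacing = echo_spacing,
    bandwidth = bandwidth, acceleration_factor = acceleration_factor,
    oversampling = oversampling, slice_gap = slice_gap,
    slice_order = slice_order, reconstruction = reconstruction),
    class = "acquisition_protocol")
}

#' Read / write an acquisition protocol (YAML or JSON)
#'
#' The file is a flat mapping of [acquisition_protocol()] fields; the format
#' is chosen by file extension (`.yaml`/`.yml` or `.json`).
#' @param path File path.
#' @return `read_protocol` returns an `acquisition_protocol`.
#' @export
read_protocol <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::fromJSON(path)
          else stop("unsupported protocol format '.", ext,
                    "'; use .yaml or .json")
  do.call(acquisition_protocol, vals)
}

#' @rdname read_protocol
#' @param protocol An `acquisition_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  vals <- Filter(function(v) !(length(v) == 1L && is.na(v)),
                 unclass(protocol))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(vals, path)
  else if (ext == "json")
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported protocol format '.", ext, "'")
  invisible(path)
}

# multiset containment: every element of `required` (with multiplicity)
# present in `have`
multiset_contains <- function(have, required) {
  th <- table(have); tr <- table(required)
  all(names(tr) %in% names(th)) &&
    all(th[names(tr)] >= tr)
}

finding <- function(severity, field, observed, recommended, citation) {
  data.frame(severity = severity, field = field,
             observed = as.character(observed),
             recommended = as.character(recommended),
             citation = citation, stringsAsFactors = FALSE)
}

#' Check a protocol against the consensus recommendations
#'
#' Verifies tier containment of the b-value multiset (abbreviated is a
#' subset of minimal; advanced must still contain the minimal set), the TR
#' minimum, the averages minimum (2 for skeletal muscle, else 1), the
#' 3-direction trace-weighting minimum, and — as warnings, since they cannot
#' affect fitting — fat suppression and resolution/slice-thickness ranges.
#' Non-compliance never raises; one finding per checked field is returned.
#'
#' @param protocol An [acquisition_protocol()].
#' @param preset The matching [get_preset()] output.
#' @param tier `"abbreviated"`, `"minimal"` or `"advanced"`.
#' @return A data.frame of findings with columns `severity`
#'   (`pass`/`warn`/`fail`), `field`, `observed`, `recommended`, `citation`.
#' @examples
#' pr <- get_preset("kidney")
#' p <- acquisition_protocol("kidney", pr$minimal_b, n_directions = 3,
#'                           n_averages = 1, tr = 4)
#' check_protocol(p, pr, "minimal")
#' @export
check_protocol <- function(protocol, preset,
                           tier = c("minimal", "abbreviated", "advanced")) {
  stopifnot(inherits(protocol, "acquisition_protocol"),
            inherits(preset, "organ_preset"))
  tier <- match.arg(tier)
  if (protocol$organ != preset$organ)
    stop("protocol organ '", protocol$organ,
         "' does not match preset organ '", preset$organ, "'")
  required <- switch(tier, abbreviated = preset$abbreviated_b,
                     minimal = preset$minimal_b, advanced = preset$minimal_b)
  out <- list()
  ok <- multiset_contains(protocol$bvalues, required)
  out$b <- finding(if (ok) "pass" else "fail", "bvalues",
                   paste(sort(protocol$bvalues), collapse = " "),
                   paste0("contains {", paste(sort(required), collapse = " "),
                          "} (", tier, " tier)"),
                   "preset$minimal_b")
  chk_num <- function(field, observed, minimum, citation,
                      severity_fail = "fail") {
    if (is.na(observed))
      finding("warn", field, "not provided", paste(">=", minimum), citation)
    else
      finding(if (observed >= minimum) "pass" else severity_fail,
              field, observed, paste(">=", minimum), citation)
  }
  out$tr <- chk_num("tr", protocol$tr, preset$tr_min, "preset$tr_min")
  out$avg <- chk_num("n_averages", protocol$n_averages, preset$averages_min,
                     "preset$averages_min")
  out$dir <- chk_num("n_directions", protocol$n_directions,
                     preset$n_directions_min, "preset$n_directions_min")
  chk_range <- function(field, observed, range, citation) {
    if (is.na(observed))
      finding("warn", field, "not provided",
              sprintf("%g-%g mm", range[1], range[2]), citation)
    else
      finding(if (observed >= range[1] && observed <= range[2])
                "pass" else "warn",
              field, observed, sprintf("%g-%g mm", range[1], range[2]),
              citation)
  }
  out$res <- chk_range("voxel_size", protocol$voxel_size,
                       preset$resolution_range, "preset$resolution_range")
  out$sl <- chk_range("slice_thickness", protocol$slice_thickness,
                      preset$slice_range, "preset$slice_range")
  fs <- protocol$fat_suppression
  out$fat <- if (is.na(fs))
    finding("warn", "fat_suppression", "not provided",
            preset$fat_suppression, "preset$fat_suppression")
  else
    finding(if (toupper(fs) == preset$fat_suppression) "pass" else "warn",
            "fat_suppression", fs, preset$fat_suppression,
            "preset$fat_suppression")
  do.call(rbind, unname(out))
}

# the items good-practice reporting asks for; one entry each, fixed count
.checklist_items <- c(
  tr = "TR (s)", te = "TE (ms)",
  delta_big = "diffusion gradient separation (Delta, ms)",
  delta_small = "diffusion gradient duration (delta, ms)",
  max_gradient = "maximum gradient strength (mT/m)",
  slew = "slew rate (T/m/s)",
  fat_suppression = "fat suppression technique",
  voxel_size = "acquired voxel size (mm)",
  echo_train_length = "echo train length",
  echo_spacing = "echo spacing (ms)",
  bandwidth = "receiver bandwidth (Hz/px)",
  acceleration_factor = "parallel acceleration factor",
  oversampling = "oversampling factors and directions",
  slice_gap = "slice gap (mm)",
  slice_order = "slice acquisition order",
  reconstruction = "reconstruction settings (interpolation, zero filling, filtering)",
  preprocessing = "pre-processing steps applied",
  fit_algorithm = "fit algorithm",
  fit_initial_guess = "fit initial guess",
  fit_constraints = "fit constraints/bounds")

#' Good-practice reporting checklist
#'
#' Inventories the acquisition-timing, readout, reconstruction,
#' pre-processing and fitting details that should accompany published IVIM
#' results, marking each as provided or missing. The item list is fixed, so
#' counts are comparable across protocols.
#'
#' @param protocol An [acquisition_protocol()] (may be minimally populated).
#' @param fit_metadata Optional named list with `preprocessing`,
#'   `fit_algorithm`, `fit_initial_guess`, `fit_constraints` entries (e.g.
#'   assembled from a [fit_options()] echo).
#' @return A `reporting_checklist` object: a data.frame with columns
#'   `item`, `description`, `provided`, `value`, printable as Markdown via
#'   [format()].
#' @export
reporting_checklist <- function(protocol = NULL, fit_metadata = NULL) {
  get_val <- function(key) {
    v <- if (key %in% c("preprocessing", "fit_algorithm",
                        "fit_initial_guess", "fit_constraints"))
      fit_metadata[[key]]
    else if (!is.null(protocol)) protocol[[key]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) NA_character_
    else paste(format(v), collapse = "; ")
  }
  vals <- vapply(names(.checklist_items), get_val, character(1))
  out <- data.frame(item = names(.checklist_items),
                    description = unname(.checklist_items),
                    provided = !is.na(vals),
                    value = unname(vals), stringsAsFactors = FALSE)
  class(out) <- c("reporting_checklist", "data.frame")
  out
}

#' @export
format.reporting_checklist <- function(x, ...) {
  lines <- c("# IVIM reporting checklist", "",
             sprintf("%d of %d items provided", sum(x$provided), nrow(x)),
             "")
  lines <- c(lines, sprintf("- [%s] %s%s",
                            ifelse(x$provided, "x", " "), x$description,
                            ifelse(x$provided, paste0(": ", x$value), "")))
  paste(lines, collapse = "\n")
}

#' @export
print.reporting_checklist <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
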