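#' Pipeline configuration
#'
#' Builds the validated configuration for a pipeline run. Defaults follow
#' the reference workflow where it states values (Savitzky-Golay order 3 /
#' window 7, green-up slope threshold 0.015, end-of-senescence slope
#' threshold -0.01, daily median aggregation); the remaining keys are
#' documented package choices. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Named list of class `pf_config`.
#' @section Keys:
#' \describe{
#'   \item{sowing_date}{Date of sowing (DAS 0). Default `"2015-04-10"`.}
#'   \item{timestamp_pattern}{`strftime` pattern in frame names.}
#'   \item{tz}{Camera clock time zone.}
#'   \item{day_window}{Daylight window in local hours, `c(8, 18)`.}
#'   \item{luminance_floor}{Minimum mean frame luminance, 8-bit DN (20).}
#'   \item{min_mask_pixels}{Minimum valid pixels per plot observation (40).}
#'   \item{daily_aggregator}{`"median"` (default) or `"p90"`.}
#'   \item{sg_poly_order, sg_window}{Savitzky-Golay settings (3, 7).}
#'   \item{max_gap_interp_days}{Largest interpolated day gap (3).}
#'   \item{sog_slope}{Green-up slope threshold, scaled units (0.015).}
#'   \item{eos_slope}{End-of-senescence slope threshold (-0.01).}
#'   \item{min_prominence}{Minimum scaled peak prominence (0.02).}
#'   \item{min_peak_height}{Minimum scaled peak height (0.35).}
#'   \item{greenup_level}{Scaled level defining green-up onset (0.2).}
#'   \item{eos_drop_guard}{Required drop below the senescence peak before
#'     the end-of-senescence scan (0.05).}
#'   \item{eos_method}{`"slope"` (default) or `"minimum"`.}
#'   \item{knots_r, knots_c}{P-spline segments per dimension (`NULL` =
#'     automatic).}
#'   \item{reml_tol, reml_max_iter}{REML convergence controls (1e-6, 5000).}
#'   \item{senescence_split}{Rating splitting the two gcc regimes (65).}
#'   \item{lai_min, lai_sat_frac}{LAI analysis bounds (1, 0.1).}
#'   \item{seed}{Integer seed for any stochastic stage (1).}
#' }
#' @export
pf_config <- function(...) {
  defaults <- list(
    sowing_date = "2015-04-10", timestamp_pattern = "%Y%m%d_%H%M%S",
    tz = "UTC", day_window = c(8, 18), luminance_floor = 20,
    min_mask_pixels = 40L, daily_aggregator = "median",
    sg_poly_order = 3L, sg_window = 7L, max_gap_interp_days = 3L,
    sog_slope = 0.015, eos_slope = -0.01, min_prominence = 0.02,
    min_peak_height = 0.35, greenup_level = 0.2, eos_drop_guard = 0.05,
    eos_method = "slope", knots_r = NULL, knots_c = NULL,
    reml_tol = 1e-6, reml_max_iter = 5000L,
    senescence_split = 65, lai_min = 1, lai_sat_frac = 0.1, seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = c("pf_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Flat or per-stage-sectioned YAML; section nesting is flattened before
#' validation, so unknown keys are still rejected.
#'
#' @param path YAML file path.
#' @return A [pf_config()] object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (k in names(raw)) {
    v <- raw[[k]]
    if (is.list(v) && !is.null(names(v))) flat[names(v)] <- v
    else flat[[k]] <- v
  }
  do.call(pf_config, flat)
}

#' Run manifest for a pipeline stage
#'
#' Records the configuration snapshot, package version, per-stage record
#' counts and warnings; rerunning with identical config and inputs yields
#' identical outputs (and an identical manifest apart from nothing --
#' no wall-clock fields enter any computation).
#'
#' @param config The [pf_config()] used.
#' @param counts Named integer vector of record counts per stage.
#' @param warnings Character vector of warnings raised.
#' @param path If non-`NULL`, the manifest is written there as JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, counts = integer(), warnings = character(),
                         path = NULL) {
  man <- list(
    package = "phenofield",
    version = as.character(utils::packageVersion("phenofield")),
    config = unclass(config),
    counts = as.list(counts),
    warnings = warnings)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(man))
  }
  man
}
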