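#' Simulate a synthetic campaign to disk
#'
#' Wraps [make_campaign()] (and [render_frames()] when enabled) behind the
#' pipeline's file interfaces.
#'
#' @param out_dir Output directory.
#' @param cfg A [campaign_config()].
#' @return Invisibly, the written paths.
#' @export
cmd_simulate <- function(out_dir, cfg = campaign_config()) {
  camp <- make_campaign(cfg)
  paths <- write_campaign(camp, out_dir)
  if (isTRUE(cfg$render_images)) {
    r <- render_frames(camp, file.path(out_dir, "frames"))
    paths <- c(paths, masks = r$masks_path)
  }
  invisible(paths)
}

#' Extract plot observations from frames on disk
#'
#' @param image_dir Directory of PNG frames.
#' @param masks_path JSON mask file (plot polygons).
#' @param out_csv Output observations CSV.
#' @param config A [pf_config()].
#' @return Invisibly, the observations data frame.
#' @export
cmd_extract <- function(image_dir, masks_path, out_csv, config = pf_config()) {
  if (!file.exists(masks_path)) stop("mask file not found: ", masks_path)
  probe <- list.files(image_dir, pattern = "\\.png$", full.names = TRUE)
  if (length(probe) == 0L) {
    warning("no frames in ", image_dir, "; writing empty observations CSV")
    obs <- data.frame(plot_id = character(), timestamp = character(),
                      das = integer(), gcc = numeric(),
                      n_pixels_used = integer())
    utils::write.csv(obs, out_csv, row.names = FALSE)
    return(invisible(obs))
  }
  dim1 <- dim(png::readPNG(probe[1]))
  masks <- read_masks(masks_path, width = dim1[2], height = dim1[1],
                      min_pixels = config$min_mask_pixels)
  obs <- extract_observations(
    image_dir, masks, config$sowing_date, config$timestamp_pattern,
    config$tz, config$day_window, config$luminance_floor,
    config$min_mask_pixels)
  out <- obs
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(obs)
}

#' Daily aggregation and smoothing stage
#'
#' @param observations_csv Observations CSV (from [cmd_extract()] or
#'   [cmd_simulate()]).
#' @param out_csv Output daily-signal CSV.
#' @param config A [pf_config()].
#' @return Invisibly, the daily-signal data frame.
#' @export
cmd_daily <- function(observations_csv, out_csv, config = pf_config()) {
  obs <- utils::read.csv(observations_csv)
  daily <- aggregate_daily(obs, config$daily_aggregator)
  sig <- daily_signal(daily, config$sg_poly_order, config$sg_window,
                      config$max_gap_interp_days)
  utils::write.csv(sig, out_csv, row.names = FALSE)
  invisible(sig)
}

#' Phenological time point and phase stage
#'
#' @param daily_csv Daily-signal CSV.
#' @param out_points_csv,out_phases_csv Output CSVs.
#' @param config A [pf_config()].
#' @return Invisibly, list of the points and (plot-level) phases tables.
#' @export
cmd_points <- function(daily_csv, out_points_csv, out_phases_csv,
                       config = pf_config()) {
  sig <- utils::read.csv(daily_csv)
  pts <- phenopoints_all(sig, config)
  phases <- compute_phases(pts)
  utils::write.csv(pts, out_points_csv, row.names = FALSE)
  utils::write.csv(phases, out_phases_csv, row.names = FALSE)
  invisible(list(points = pts, phases = phases))
}

#' Spatial correction stage
#'
#' Corrects the four time points (then derives genotype-level phases from
#' the corrected BLUEs) and any additional response columns.
#'
#' @param points_csv Time-point CSV from [cmd_points()].
#' @param layout_csv Field layout CSV.
#' @param out_dir Directory for `blues.csv`, `h2.csv`, `phases_genotypic.csv`.
#' @param config A [pf_config()].
#' @return Invisibly, the [correct_phenopoints()] result.
#' @export
cmd_correct <- function(points_csv, layout_csv, out_dir,
                        config = pf_config()) {
  pts <- utils::read.csv(points_csv)
  layout <- utils::read.csv(layout_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- correct_phenopoints(pts, layout, knots_r = config$knots_r,
                             knots_c = config$knots_c, tol = config$reml_tol,
                             max_iter = config$reml_max_iter)
  utils::write.csv(res$points$blues, file.path(out_dir, "blues.csv"),
                   row.names = FALSE)
  utils::write.csv(res$points$h2, file.path(out_dir, "h2.csv"),
                   row.names = FALSE)
  if (!is.null(res$phases))
    utils::write.csv(res$phases, file.path(out_dir, "phases_genotypic.csv"),
                     row.names = FALSE)
  invisible(res)
}

#' Full pipeline over a simulated or real campaign directory
#'
#' Orchestrates daily aggregation, smoothing, time-point extraction,
#' spatial correction and the run manifest over a campaign directory laid
#' out as written by [cmd_simulate()] (or by [cmd_extract()] for real
#' imagery). Every intermediate is persisted; a failed stage aborts with
#' the partial outputs left labelled by stage.
#'
#' @param campaign_dir Directory containing `observations.csv` and
#'   `layout.csv`.
#' @param out_dir Output directory (default `campaign_dir/results`).
#' @param config A [pf_config()].
#' @return Invisibly, list of stage outputs.
#' @export
run_pipeline <- function(campaign_dir, out_dir = file.path(campaign_dir, "results"),
                         config = pf_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warns <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  obs_csv <- file.path(campaign_dir, "observations.csv")
  lay_csv <- file.path(campaign_dir, "layout.csv")
  if (!file.exists(obs_csv) || !file.exists(lay_csv))
    stop("campaign directory must contain observations.csv and layout.csv")
  sig <- wh(cmd_daily(obs_csv, file.path(out_dir, "daily_signal.csv"), config))
  pts <- wh(cmd_points(file.path(out_dir, "daily_signal.csv"),
                       file.path(out_dir, "phenopoints.csv"),
                       file.path(out_dir, "phases_plot.csv"), config))
  corr <- wh(cmd_correct(file.path(out_dir, "phenopoints.csv"), lay_csv,
                         out_dir, config))
  counts <- c(observations = nrow(utils::read.csv(obs_csv)),
              daily = nrow(sig), plots = length(unique(sig$plot_id)),
              points_detected = sum(!is.na(pts$points$SOG)))
  run_manifest(config, counts, warns, file.path(out_dir, "manifest.json"))
  invisible(list(signal = sig, points = pts, correction = corr,
                 warnings = warns, out_dir = out_dir))
}

#' Correlate corrected phenology with trait tables
#'
#' Genotype-level correlations of trait BLUEs against time-point and phase
#' BLUEs, reported as signed coefficients of determination.
#'
#' @param blues_csv Genotypic time-point BLUEs (`response`, `genotype`,
#'   `blue`) from [cmd_correct()].
#' @param phases_csv Genotypic phases CSV from [cmd_correct()].
#' @param trait_values Named list of genotype-keyed numeric vectors (one
#'   per trait).
#' @param out_csv Output CSV of correlation rows.
#' @return Invisibly, the correlation data frame.
#' @export
cmd_correlate <- function(blues_csv, phases_csv, trait_values, out_csv) {
  blues <- utils::read.csv(blues_csv)
  wide <- stats::reshape(blues[, c("response", "genotype", "blue")],
                         direction = "wide", idvar = "genotype",
                         timevar = "response")
  names(wide) <- sub("^blue\\.", "", names(wide))
  if (file.exists(phases_csv)) {
    ph <- utils::read.csv(phases_csv)
    wide <- merge(wide, ph, by = "genotype")
  }
  phen_cols <- setdiff(names(wide), "genotype")
  rows <- list()
  for (tn in names(trait_values)) {
    tv <- trait_values[[tn]]
    for (pc in phen_cols) {
      r <- tryCatch(
        correlate(stats::setNames(wide[[pc]], wide$genotype), tv,
                  level = "genotypic", pair = c(pc, tn)),
        error = function(e) NULL)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}
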