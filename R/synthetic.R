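#' Ground-truth greenness curve parameters
#'
#' Parameter set for one plot's seasonal gcc trajectory: a flat baseline, a
#' steep green-up to the green peak, a shallow shoulder dip, a second
#' (senescence) peak, a steep senescence decline flattening at the end of
#' senescence, and a gently drifting tail. Defaults reproduce the canonical
#' soybean season narrative (green-up from DAS 48, green peak near DAS 76,
#' senescence peak near DAS 125, end of senescence near DAS 144).
#'
#' @param baseline Absolute gcc before green-up (default 0.345).
#' @param t_sog,t_gp,t_dip,t_sp,t_eos Integer anchor days (defaults 48, 76,
#'   95, 125, 144); must be strictly increasing. `t_dip` defaults to the
#'   rounded midpoint of `t_gp` and `t_sp` when `NULL`.
#' @param gp_amplitude Rise of the green peak above baseline (default 0.095).
#' @param dip_depth Drop of the shoulder dip below the green peak
#'   (default 0.045).
#' @param sp_amplitude Rise of the senescence peak above baseline
#'   (default 0.090); `0` gives a unimodal (degenerate) curve.
#' @param eos_drop Drop of the end-of-senescence level below baseline
#'   (default 0.015).
#' @param tail_slope Absolute gcc change per day after `t_eos`
#'   (default -3e-4; gentle, above the end-of-senescence slope threshold).
#' @param steepness Multiplier on all transition slopes (default 1).
#' @return Object of class `curve_params` (a validated list).
#' @export
curve_params <- function(baseline = 0.345, t_sog = 48L, t_gp = 76L,
                         t_dip = NULL, t_sp = 125L, t_eos = 144L,
                         gp_amplitude = 0.095, dip_depth = 0.045,
                         sp_amplitude = 0.090, eos_drop = 0.015,
                         tail_slope = -3e-4, steepness = 1) {
  if (is.null(t_dip)) t_dip <- as.integer(round((t_gp + t_sp) / 2))
  p <- list(baseline = baseline, t_sog = as.integer(t_sog),
            t_gp = as.integer(t_gp), t_dip = as.integer(t_dip),
            t_sp = as.integer(t_sp), t_eos = as.integer(t_eos),
            gp_amplitude = gp_amplitude, dip_depth = dip_depth,
            sp_amplitude = sp_amplitude, eos_drop = eos_drop,
            tail_slope = tail_slope, steepness = steepness)
  with(p, {
    if (!(t_sog < t_gp && t_gp < t_dip && t_dip < t_sp && t_sp < t_eos))
      stop("infeasible anchors: need t_sog < t_gp < t_dip < t_sp < t_eos")
    if (gp_amplitude < 0 || sp_amplitude < 0 || dip_depth < 0)
      stop("amplitudes must be non-negative")
    if (sp_amplitude > 0 && gp_amplitude - dip_depth < 0)
      stop("dip_depth exceeds gp_amplitude")
    if (t_gp - t_sog < 5L || t_sp - t_dip < 5L || t_eos - t_sp < 8L)
      stop("segments too short for a well-shaped trajectory")
  })
  structure(p, class = "curve_params")
}

# One segment of daily increments: a linear slope ramp with endpoint ratio
# shape = c(s0, s1), rescaled so the increments sum exactly to `rise`.
seg_ramp <- function(L, rise, shape) {
  w <- seq(shape[1], shape[2], length.out = L)
  w * (rise / sum(w))
}

#' Daily true greenness trajectory from curve parameters
#'
#' Builds the trajectory from an explicit per-day slope schedule through the
#' anchor days: segment slopes are linear ramps rescaled to hit each anchor
#' value exactly, so anchors are exact local extrema on the daily grid, the
#' scaled slope immediately after `t_sog` exceeds the green-up threshold
#' (0.015/day), the pre-peak slopes stay below it, and the senescence
#' decline eases through the end-of-senescence slope threshold (-0.01/day)
#' at `t_eos`. If `sp_amplitude = 0` the curve is unimodal: it declines
#' from the green peak to the end level without a second peak.
#'
#' @param params A [curve_params()] object.
#' @param days Integer day grid (default `0:150`); must start at or before
#'   `t_sog` and extend past `t_eos`.
#' @return Numeric vector of absolute gcc values on `days`, clamped to
#'   `[0, 1]`.
#' @export
make_trajectory <- function(params, days = 0:150) {
  stopifnot(inherits(params, "curve_params"))
  p <- params
  T0 <- days[1]; T1 <- days[length(days)]
  if (T0 > p$t_sog || T1 < p$t_eos + 2L)
    stop("day grid must cover the season: [", p$t_sog, ", ", p$t_eos + 2, "]")
  full <- T0:T1
  inc <- numeric(length(full) - 1L)   # inc[i] = value change from day i-1 to i
  at <- function(d) d - T0            # day -> increment index (change into day d)
  gp_val <- p$baseline + p$gp_amplitude
  eos_val <- p$baseline - p$eos_drop
  st <- p$steepness
  # green-up: front-loaded ramp, first scaled slope well above 0.015,
  # final approach slope below it
  inc[(at(p$t_sog) + 1L):at(p$t_gp)] <-
    seg_ramp(p$t_gp - p$t_sog, p$gp_amplitude, c(5, 1) * st)
  if (p$sp_amplitude > 0) {
    dip_val <- gp_val - p$dip_depth
    sp_val <- p$baseline + p$sp_amplitude
    inc[(at(p$t_gp) + 1L):at(p$t_dip)] <-
      seg_ramp(p$t_dip - p$t_gp, dip_val - gp_val, c(1.2, 1.55))
    inc[(at(p$t_dip) + 1L):at(p$t_sp)] <-
      seg_ramp(p$t_sp - p$t_dip, sp_val - dip_val, c(1, 3.2))
    peak_val <- sp_val
  } else {
    # unimodal: gentle decline from the green peak toward the senescence drop
    inc[(at(p$t_gp) + 1L):at(p$t_sp)] <-
      seg_ramp(p$t_sp - p$t_gp, -p$dip_depth, c(1, 1))
    peak_val <- gp_val - p$dip_depth
  }
  # senescence decline: steep ramp easing through the slope threshold at EOS
  L <- p$t_eos - p$t_sp
  range_nom <- p$gp_amplitude + p$eos_drop
  tail3 <- c(-0.018, -0.015, -0.012) * range_nom * st
  drop_main <- (eos_val - peak_val) - sum(tail3)
  inc[(at(p$t_sp) + 1L):(at(p$t_eos) - 3L)] <-
    seg_ramp(L - 3L, drop_main, c(0.45, 1.9) * st)
  inc[(at(p$t_eos) - 2L):at(p$t_eos)] <- tail3
  # post-season tail
  if (at(p$t_eos) < length(inc))
    inc[(at(p$t_eos) + 1L):length(inc)] <- p$tail_slope
  v <- p$baseline + c(0, cumsum(inc))
  v <- pmin(1, pmax(0, v))
  v[match(days, full)]
}

#' Campaign configuration for the synthetic generator
#'
#' Defaults emulate the reference campaign: 10 genotypes in 8 complete
#' blocks (80 experimental plots on a 10-row by 8-column grid), a 150-day
#' season, 4-60 images per hour inside the daylight window, a smooth field
#' trend plus a zenith-viewing-angle gradient whose sign flips between early
#' and mid season, globally shared illumination noise with AR(1) day-to-day
#' weather carry-over, and a small fraction of outlier observations.
#'
#' @param n_genotypes,replicates,n_rows Design dimensions (defaults 10, 8,
#'   10); plots = genotypes x replicates must fit the `n_rows` x
#'   `replicates` grid.
#' @param season_days Season length in days after sowing (default 156,
#'   covering sowing to harvest plus the senescence tail of the latest
#'   genotypes).
#' @param sowing_date Sowing date (default `"2015-04-10"`).
#' @param images_per_hour Integer range of capture frequency (default
#'   `c(4, 60)`).
#' @param day_window Daylight window in local hours (default `c(8, 18)`).
#' @param sog_spread,gp_spread,sp_spread Full between-genotype ranges, in
#'   days, of the start-of-green-up, green-peak and senescence-peak timing
#'   shifts (defaults 2, 6 and 14; the senescence spread matches the
#'   maturity range of the emulated cultivar set).
#' @param plot_jitter_sd SD in days of per-plot timing jitter (default 0.8).
#' @param spatial_amp Amplitude of the smooth field trend in absolute gcc
#'   (default 0.006).
#' @param zenith_amp Mid-season amplitude of the zenith-angle gradient in
#'   absolute gcc (default 0.006); early-season sign is positive, mid-season
#'   negative.
#' @param illum_sd SD of the shared per-timestamp illumination term
#'   (default 0.010).
#' @param day_ar_sd,day_ar_rho Innovation SD and autocorrelation of the
#'   shared AR(1) day effect (defaults 8e-4 and 0.6, giving day-to-day
#'   wander of the daily median of a few thousandths of a gcc unit, the
#'   scatter a fixed camera shows under changing weather).
#' @param obs_sd SD of independent per-observation noise (default 0.004).
#' @param outlier_frac Fraction of observations replaced by obstacle-level
#'   gcc values (default 0.01).
#' @param outlier_gcc gcc value of outlier observations (default 0.08).
#' @param render_images Render PNG frames (default `FALSE`).
#' @param frames_per_day,image_size,pixel_noise_sd Rendering controls
#'   (defaults 2 frames/day, 600 x 400 canvas, channel noise 0.01); the
#'   rendering density is an artifact control, separate from the
#'   observation-level capture frequency.
#' @param seed Integer seed; all campaign randomness flows from it.
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(n_genotypes = 10L, replicates = 8L, n_rows = 10L,
                            season_days = 156L, sowing_date = "2015-04-10",
                            images_per_hour = c(4L, 60L),
                            day_window = c(8, 18),
                            sog_spread = 2, gp_spread = 6, sp_spread = 14,
                            plot_jitter_sd = 0.8,
                            spatial_amp = 0.006, zenith_amp = 0.006,
                            illum_sd = 0.010, day_ar_sd = 8e-4,
                            day_ar_rho = 0.6, obs_sd = 0.004,
                            outlier_frac = 0.01, outlier_gcc = 0.08,
                            render_images = FALSE, frames_per_day = 2L,
                            image_size = c(600L, 400L), pixel_noise_sd = 0.01,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (n_rows * replicates < n_genotypes * replicates)
    stop("grid too small for the design")
  if (images_per_hour[1] < 1L)
    stop("images_per_hour must be at least 1")
  structure(cfg, class = "campaign_config")
}

#' Field layout with randomized complete blocks
#'
#' One block per grid column; within each block the genotypes are assigned
#' to rows in random order. The per-plot mean zenith viewing angle is a
#' smooth function of field position (strongest along columns), mirroring a
#' camera mounted beyond one field corner.
#'
#' @param cfg A [campaign_config()]; uses its design dimensions (the caller
#'   controls the RNG state).
#' @return Data frame `plot_id`, `row`, `range_col`, `genotype`, `block`,
#'   `zenith_angle`.
#' @export
make_layout <- function(cfg) {
  genos <- sprintf("g%02d", seq_len(cfg$n_genotypes))
  rows_used <- seq_len(cfg$n_genotypes)
  out <- list()
  for (b in seq_len(cfg$replicates)) {
    ord <- sample(genos)
    out[[b]] <- data.frame(
      plot_id = sprintf("p%03d", (b - 1L) * cfg$n_genotypes + rows_used),
      row = rows_used, range_col = b, genotype = ord, block = sprintf("b%d", b))
  }
  lay <- do.call(rbind, out)
  lay$zenith_angle <- 25 + 40 * (lay$range_col - 1) / max(1, cfg$replicates - 1) +
    5 * (lay$row - 1) / max(1, cfg$n_rows - 1)
  lay
}

# Smooth field trend evaluated at plot positions, amplitude `amp` (abs gcc).
field_surface <- function(row, col, amp) {
  r <- (row - mean(range(row))) / max(1, diff(range(row)) / 2)
  c_ <- (col - mean(range(col))) / max(1, diff(range(col)) / 2)
  amp * (sin(pi * r / 2) * 0.6 + cos(pi * c_ / 2) * 0.4 + 0.3 * r * c_)
}

# Season-phase weight of the zenith-angle effect: positive early, negative
# mid-season, weakly positive at the end. Transitions are cosine-eased over
# 20 days so the gradient never injects slope steps into the daily signal.
zenith_phase <- function(das, t_gp = 76, t_eos = 144) {
  ease <- function(x) (1 - cos(pi * pmin(1, pmax(0, x)))) / 2   # 0 -> 1
  down <- ease((das - (t_gp - 25)) / 20)   # early +1 -> mid -1
  up <- ease((das - (t_eos - 20)) / 20)    # mid -1 -> late +0.3
  (1 - down) * 1 + down * (-1) + up * 1.3
}

#' Generate a full synthetic PhenoCam campaign
#'
#' Draws the layout, genotype timing shifts and per-plot curve jitter,
#' builds daily true trajectories, adds the spatial surface and the
#' phase-dependent zenith-angle gradient, then samples per-image
#' observations: shared illumination noise per timestamp, a shared AR(1)
#' day effect, independent observation noise, and obstacle outliers. All
#' randomness flows from `cfg$seed`; identical configurations reproduce
#' identical campaigns.
#'
#' @param cfg A [campaign_config()].
#' @return List with `observations` (`plot_id`, `timestamp`, `das`, `gcc`),
#'   `layout`, `daily_true` (plots x days matrix of noise-free daily gcc
#'   including spatial and zenith terms), and `truth` (the manifest: per-plot
#'   anchor days and curve parameters, genotype shifts, spatial and zenith
#'   components, noise parameters, seed).
#' @export
make_campaign <- function(cfg = campaign_config()) {
  stopifnot(inherits(cfg, "campaign_config"))
  set.seed(cfg$seed)
  layout <- make_layout(cfg)
  n_plot <- nrow(layout)
  days <- 0:cfg$season_days
  base <- curve_params()
  g <- cfg$n_genotypes
  even <- function(spread) round(seq(-spread / 2, spread / 2, length.out = g))
  shifts <- data.frame(genotype = sprintf("g%02d", seq_len(g)),
                       sog = even(cfg$sog_spread), gp = even(cfg$gp_spread),
                       sp = even(cfg$sp_spread))
  shifts$eos <- shifts$sp
  amp_mult <- 1 + stats::runif(g, -0.03, 0.03)
  params <- vector("list", n_plot)
  anchors <- data.frame(plot_id = layout$plot_id, t_sog = NA_integer_,
                        t_gp = NA_integer_, t_sp = NA_integer_,
                        t_eos = NA_integer_)
  traj <- matrix(NA_real_, n_plot, length(days),
                 dimnames = list(layout$plot_id, days))
  for (i in seq_len(n_plot)) {
    gi <- match(layout$genotype[i], shifts$genotype)
    jit <- round(stats::rnorm(3, 0, cfg$plot_jitter_sd))
    t_sog <- base$t_sog + shifts$sog[gi] + jit[1]
    t_gp <- max(base$t_gp + shifts$gp[gi] + jit[2], t_sog + 10L)
    t_sp <- max(base$t_sp + shifts$sp[gi] + jit[3], t_gp + 20L)
    t_eos <- t_sp + (base$t_eos - base$t_sp)
    p <- curve_params(t_sog = t_sog, t_gp = t_gp, t_sp = t_sp, t_eos = t_eos,
                      gp_amplitude = base$gp_amplitude * amp_mult[gi],
                      sp_amplitude = base$sp_amplitude * amp_mult[gi])
    params[[i]] <- p
    anchors[i, -1L] <- c(p$t_sog, p$t_gp, p$t_sp, p$t_eos)
    traj[i, ] <- make_trajectory(p, days)
  }
  spat <- field_surface(layout$row, layout$range_col, cfg$spatial_amp)
  zen <- (layout$zenith_angle - mean(layout$zenith_angle)) /
    stats::sd(layout$zenith_angle)
  phase <- zenith_phase(days, base$t_gp, base$t_eos)
  daily_true <- traj + outer(spat, rep(1, length(days))) +
    cfg$zenith_amp * outer(zen, phase)
  # shared AR(1) day effect (weather carry-over)
  e <- stats::rnorm(length(days), 0, cfg$day_ar_sd)
  day_eff <- as.numeric(stats::filter(e, cfg$day_ar_rho, method = "recursive"))
  obs <- sample_observations(cfg, daily_true, day_eff, days, layout$plot_id)
  truth <- list(
    seed = cfg$seed, config = unclass(cfg), anchors = anchors,
    genotype_shifts = shifts, amp_mult = amp_mult,
    spatial = data.frame(plot_id = layout$plot_id, surface = spat,
                         zenith_std = zen),
    zenith_amp = cfg$zenith_amp, day_effect = day_eff,
    curve_base = unclass(base))
  list(observations = obs, layout = layout, daily_true = daily_true,
       truth = truth)
}

# Per-image observations for all plots: shared timestamps, shared
# illumination term, independent noise, outlier replacement.
sample_observations <- function(cfg, daily_true, day_eff, days, plot_ids) {
  sow <- as.Date(cfg$sowing_date)
  n_plot <- length(plot_ids)
  out <- vector("list", length(days))
  hours <- floor(cfg$day_window[1]):(ceiling(cfg$day_window[2]) - 1L)
  for (di in seq_along(days)) {
    d <- days[di]
    rng <- cfg$images_per_hour
    n_img_h <- if (rng[1] == rng[2]) rng[1] else
      sample(seq.int(rng[1], rng[2]), 1L)
    tt <- sort(unlist(lapply(hours, function(h)
      h * 3600 + sort(sample(0:3599, n_img_h)))))
    ts <- as.POSIXct(paste(sow + d, "00:00:00"), tz = "UTC") + tt
    illum <- stats::rnorm(length(ts), 0, cfg$illum_sd)
    v <- daily_true[, di] + day_eff[di]
    gcc <- rep(v, each = length(ts)) + rep(illum, times = n_plot) +
      stats::rnorm(length(ts) * n_plot, 0, cfg$obs_sd)
    if (cfg$outlier_frac > 0) {
      n_out <- stats::rbinom(1L, length(gcc), cfg$outlier_frac)
      if (n_out > 0L) {
        idx <- sample(length(gcc), n_out)
        gcc[idx] <- cfg$outlier_gcc + stats::rnorm(n_out, 0, 0.02)
      }
    }
    out[[di]] <- data.frame(
      plot_id = rep(plot_ids, each = length(ts)),
      timestamp = rep(ts, times = n_plot), das = d,
      gcc = pmin(1, pmax(0, gcc)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate plot-level values on a layout
#'
#' Lightweight generator for a single plot-level response: genotype effects
#' plus a smooth field surface, a linear column-wise gradient (the
#' viewing-geometry stand-in), and independent noise. Used for validating
#' the spatial model in isolation.
#'
#' @param layout A [make_layout()] data frame.
#' @param genotype_effects Named numeric vector of true genotype values
#'   (names = genotype labels), or a single number for no genotype signal.
#' @param gradient_coef Total value change across the column span
#'   (default 0).
#' @param surface_amp Amplitude of the smooth surface (default 0).
#' @param noise_sd Residual SD (default 0.01).
#' @return List `y` (values aligned with `layout`), `truth` (per-plot
#'   genotype effect, gradient and surface components).
#' @export
simulate_plot_values <- function(layout, genotype_effects, gradient_coef = 0,
                                 surface_amp = 0, noise_sd = 0.01) {
  if (length(genotype_effects) == 1L && is.null(names(genotype_effects)))
    genotype_effects <- stats::setNames(
      rep(genotype_effects, length(unique(layout$genotype))),
      unique(layout$genotype))
  ge <- genotype_effects[as.character(layout$genotype)]
  if (anyNA(ge)) stop("genotype_effects missing some layout genotypes")
  span <- diff(range(layout$range_col))
  grad <- gradient_coef * (layout$range_col - min(layout$range_col)) /
    max(1, span)
  surf <- field_surface(layout$row, layout$range_col, surface_amp)
  y <- as.numeric(ge) + grad + surf + stats::rnorm(nrow(layout), 0, noise_sd)
  list(y = y, truth = data.frame(plot_id = layout$plot_id,
                                 genotype_effect = as.numeric(ge),
                                 gradient = grad, surface = surf))
}

#' Simulated in-season and harvest trait tables
#'
#' Derives plot-level traits from a campaign's ground truth: early vigor at
#' DAS 40 anticorrelated with the genotype's green-peak timing; LAI
#' following a logistic rise saturating near `lai_max`; senescence ratings
#' at six dates per plot rising through 65% at the plot's senescence peak
#' and reaching 100% at its end of senescence; harvest traits with linear
#' dependencies on phase durations.
#'
#' @param campaign A [make_campaign()] result.
#' @param lai_max Saturation LAI (default 6).
#' @param vigor_noise_sd,senescence_noise_sd,yield_noise_sd Observation
#'   noise (defaults 0.35 rating units, 3 percent, 0.15 t/ha).
#' @param dependency_scale Multiplier on all trait-phenology dependency
#'   coefficients (default 1; `0` gives null traits for calibration).
#' @param seed Integer seed.
#' @return List of data frames: `vigor` (`plot_id`, `das`, `vigor`), `lai`
#'   (`plot_id`, `das`, `lai`), `senescence` (`plot_id`, `das`,
#'   `senescence_pct`), `harvest` (`plot_id`, `yield`, `tkw`,
#'   `oil_content`).
#' @export
make_traits <- function(campaign, lai_max = 6, vigor_noise_sd = 0.35,
                        senescence_noise_sd = 3, yield_noise_sd = 0.15,
                        dependency_scale = 1, seed = 2L) {
  set.seed(seed)
  an <- campaign$truth$anchors
  lay <- campaign$layout
  ds <- dependency_scale
  # vigor: earlier genotype green peak -> higher vigor
  gp_g <- tapply(an$t_gp, lay$genotype, mean)
  vig_g <- 4.5 - ds * 5 * (gp_g - mean(gp_g)) / max(1e-9, diff(range(gp_g)))
  vigor <- data.frame(
    plot_id = an$plot_id, das = 40L,
    vigor = pmin(8, pmax(1, vig_g[as.character(lay$genotype)] +
                           stats::rnorm(nrow(an), 0, vigor_noise_sd))))
  # LAI: logistic in time, midpoint tied to the plot's green-up
  lai_das <- c(30L, 40L, 50L, 61L, 70L)
  lai <- do.call(rbind, lapply(lai_das, function(d) {
    mid <- an$t_sog + 14
    data.frame(plot_id = an$plot_id, das = d,
               lai = pmax(0, lai_max / (1 + exp(-(d - mid) / 6)) +
                            stats::rnorm(nrow(an), 0, 0.15)))
  }))
  # senescence: 65% at SP, 100% at EOS
  sen_das <- c(109L, 117L, 124L, 132L, 137L, 150L)
  senescence <- do.call(rbind, lapply(sen_das, function(d) {
    up <- 65 * (d - an$t_gp) / pmax(1, an$t_sp - an$t_gp)
    down <- 65 + 35 * (d - an$t_sp) / pmax(1, an$t_eos - an$t_sp)
    s <- ifelse(d <= an$t_sp, pmax(0, up), pmin(100, down))
    data.frame(plot_id = an$plot_id, das = d,
               senescence_pct = pmin(100, pmax(0, s +
                 stats::rnorm(nrow(an), 0, senescence_noise_sd))))
  }))
  sp_gp <- an$t_sp - an$t_gp
  eos_sp <- an$t_eos - an$t_sp
  harvest <- data.frame(
    plot_id = an$plot_id,
    yield = 3 + ds * (0.06 * (eos_sp - mean(eos_sp)) -
                        0.04 * (sp_gp - mean(sp_gp))) +
      stats::rnorm(nrow(an), 0, yield_noise_sd),
    tkw = 180 - ds * 1.5 * (an$t_gp - mean(an$t_gp)) +
      stats::rnorm(nrow(an), 0, 4),
    oil_content = 18 + ds * 0.12 * (sp_gp - mean(sp_gp)) +
      stats::rnorm(nrow(an), 0, 0.5))
  list(vigor = vigor, lai = lai, senescence = senescence, harvest = harvest)
}

#' Simulated gcc-LAI calibration pairs
#'
#' Stand-alone generator for the saturating gcc-LAI relationship: linear
#' rise up to the plateau onset, flat beyond it, inflated noise below
#' `lai_unreliable` where the optical LAI reference is unreliable.
#'
#' @param n Number of pairs.
#' @param saturation True plateau-onset LAI (default 4.5).
#' @param slope Linear-regime gcc change per LAI unit (default 0.02).
#' @param base gcc at LAI 0 (default 0.35).
#' @param noise_sd gcc noise (default 0.004).
#' @param lai_unreliable LAI below which reference noise is inflated
#'   (default 1; noise x4).
#' @param lai_range Sampled LAI range (default `c(0.2, 6.5)`).
#' @return Data frame `lai`, `gcc`.
#' @export
sim_lai_gcc <- function(n, saturation = 4.5, slope = 0.02, base = 0.35,
                        noise_sd = 0.004, lai_unreliable = 1,
                        lai_range = c(0.2, 6.5)) {
  lai <- stats::runif(n, lai_range[1], lai_range[2])
  sd_i <- ifelse(lai < lai_unreliable, 4 * noise_sd, noise_sd)
  gcc <- base + slope * pmin(lai, saturation) + stats::rnorm(n, 0, sd_i)
  data.frame(lai = lai, gcc = gcc)
}

#' Write a campaign to disk in the pipeline's interface formats
#'
#' @param campaign A [make_campaign()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths (observations CSV,
#'   layout CSV, truth manifest JSON).
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- campaign$observations
  obs$timestamp <- format(obs$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  paths <- c(observations = file.path(dir, "observations.csv"),
             layout = file.path(dir, "layout.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(obs, paths["observations"], row.names = FALSE)
  utils::write.csv(campaign$layout, paths["layout"], row.names = FALSE)
  jsonlite::write_json(campaign$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
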