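test_that("curve parameters are validated", {
  expect_error(curve_params(t_sog = 80, t_gp = 76), "infeasible")
  expect_error(curve_params(gp_amplitude = -0.1), "non-negative")
  expect_error(curve_params(dip_depth = 0.2), "dip_depth")
  expect_error(make_trajectory(curve_params(), 0:100), "cover the season")
})

test_that("trajectories are bounded with exact anchor extrema", {
  p <- curve_params()
  y <- make_trajectory(p, 0:156)
  expect_true(all(y >= 0 & y <= 1))
  # first mode peaks exactly at the green-peak anchor
  expect_equal(which.max(y[1:100]) - 1L, p$t_gp)
  # second mode peaks at the senescence-peak anchor
  late <- y[101:157]
  expect_equal(which.max(late) + 99L, p$t_sp)
  # slope immediately after green-up onset exceeds the detection threshold
  s <- (y - min(y)) / diff(range(y))
  expect_gt(s[p$t_sog + 2] - s[p$t_sog + 1], 0.015)
  # zero senescence amplitude gives a unimodal curve
  y0 <- make_trajectory(curve_params(sp_amplitude = 0), 0:156)
  peaks <- which(diff(sign(diff(y0))) == -2)
  expect_length(peaks, 1L)
})

test_that("campaigns are reproducible from the seed", {
  cfg <- campaign_config(images_per_hour = c(4L, 4L), seed = 77L,
                         season_days = 156L)
  c1 <- make_campaign(cfg)
  c2 <- make_campaign(cfg)
  d1 <- file.path(tempdir(), "camp_a"); d2 <- file.path(tempdir(), "camp_b")
  write_campaign(c1, d1); write_campaign(c2, d2)
  for (f in c("observations.csv", "layout.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a noiseless campaign round-trips exactly through aggregation", {
  cfg <- campaign_config(images_per_hour = c(4L, 4L), seed = 5L,
                         illum_sd = 0, day_ar_sd = 0, obs_sd = 0,
                         outlier_frac = 0)
  camp <- make_campaign(cfg)
  daily <- aggregate_daily(camp$observations)
  for (pid in c("p001", "p040", "p080")) {
    d <- daily[daily$plot_id == pid, ]
    expect_equal(d$gcc_raw, unname(camp$daily_true[pid, as.character(d$das)]),
                 tolerance = 1e-12)
  }
})

test_that("the layout is a randomized complete block design with zenith metadata", {
  camp <- test_campaign()
  lay <- camp$layout
  expect_equal(nrow(lay), 80L)
  expect_equal(length(unique(lay$genotype)), 10L)
  # every block contains every genotype exactly once
  tab <- table(lay$block, lay$genotype)
  expect_true(all(tab == 1))
  expect_false(any(duplicated(lay[, c("row", "range_col")])))
  # zenith angle varies smoothly, dominated by the column direction
  expect_gt(cor(lay$zenith_angle, lay$range_col), 0.9)
})

test_that("recovered senescence-phase spread covers the genotype range", {
  camp <- test_campaign()
  sig <- daily_signal(aggregate_daily(camp$observations))
  pts <- phenopoints_all(sig)
  res <- correct_phenopoints(pts, camp$layout)
  an <- camp$truth$anchors
  true_range <- diff(range(tapply(an$t_sp - an$t_sog, camp$layout$genotype,
                                  mean)))
  expect_gte(diff(range(res$phases$SP_SOG)), true_range * 0.8)
  # the generated genotype spread itself mirrors a realistic maturity range
  expect_gte(true_range, 10)
})

test_that("rendered masks hold plot-scale pixel counts and encode gcc", {
  cfg <- campaign_config(images_per_hour = c(4L, 4L), seed = 21L,
                         render_images = TRUE, pixel_noise_sd = 0,
                         illum_sd = 0, day_ar_sd = 0, obs_sd = 0,
                         outlier_frac = 0, frames_per_day = 1L,
                         season_days = 156L)
  camp <- make_campaign(cfg)
  dir <- tempfile()
  # render only three days' worth by truncating the day grid
  camp$daily_true <- camp$daily_true[, as.character(60:62)]
  r <- render_frames(camp, dir)
  masks <- read_masks(r$masks_path, 600, 400)
  npix <- vapply(masks, nrow, 0L)
  expect_true(all(npix >= 1000 & npix <= 9400))
  img <- png::readPNG(r$frames[1])
  for (pid in c("p001", "p042")) {
    g <- extract_plot_gcc(img, masks[[pid]])$gcc
    # 8-bit quantization bounds the attainable accuracy
    expect_lt(abs(g - camp$daily_true[pid, "60"]), 2.5e-3)
  }
  unlink(dir, recursive = TRUE)
})

test_that("trait tables carry the configured structure", {
  camp <- test_campaign()
  tr <- make_traits(camp)
  expect_true(all(tr$vigor$vigor >= 1 & tr$vigor$vigor <= 8))
  expect_true(all(tr$senescence$senescence_pct >= 0 &
                    tr$senescence$senescence_pct <= 100))
  expect_true(all(tr$lai$lai >= 0))
  # six rating dates per plot
  expect_true(all(table(tr$senescence$plot_id) == 6L))
  # null dependencies give near-zero plot-level phenology correlation
  tr0 <- make_traits(camp, dependency_scale = 0, seed = 8L)
  an <- camp$truth$anchors
  r <- correlate(setNames(tr0$harvest$yield, tr0$harvest$plot_id),
                 setNames(an$t_gp, an$plot_id), "phenotypic",
                 pair = c("yield", "GP"))
  expect_lt(r$r2, 0.05)
})
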