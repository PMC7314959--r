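test_that("unit rescaling maps extremes to 0 and 1 and rejects constants", {
  expect_equal(rescale_unit(c(0.35, 0.45)), c(0, 1))
  set.seed(1)
  y <- runif(50)
  s <- rescale_unit(y)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  # affine transforms leave the scaled signal unchanged
  expect_equal(rescale_unit(3 * y + 0.2), s, tolerance = 1e-12)
  expect_error(rescale_unit(rep(0.4, 10)), "degenerate")
})

test_that("start of green-up is the first sustained slope-threshold crossing", {
  # 0.005/day through day 40, then 0.05/day: first crossing at day 41
  s <- cumsum(c(0, rep(0.005, 40), rep(0.05, 12)))
  s <- s / max(s)
  das <- 0:52
  # slopes scale with the normalization; use the raw construction directly
  s_raw <- cumsum(c(0, rep(0.005, 40), rep(0.05, 12)))
  r <- detect_sog(s_raw, das, gp = 52L)
  expect_equal(r$das, 41L)
  # pure ramp below threshold never qualifies
  ramp <- cumsum(c(0, rep(0.01, 60)))
  r2 <- detect_sog(ramp, 0:60, gp = 60L)
  expect_true(is.na(r2$das))
  expect_equal(r2$reason, "no_green_up")
})

test_that("raising the slope threshold never finds an earlier start", {
  set.seed(2)
  p <- curve_params()
  y <- smooth_signal(make_trajectory(p, 0:156) + rnorm(157, 0, 0.002))
  s <- rescale_unit(y)
  gp <- detect_gp(s, 0:156)$das
  prev <- -Inf
  for (thr in c(0.01, 0.015, 0.02, 0.03)) {
    d <- detect_sog(s, 0:156, gp, sog_slope = thr)$das
    if (is.na(d)) break
    expect_gte(d, prev)
    prev <- d
  }
})

test_that("green peak is the first qualifying maximum, with plateau tie-break", {
  tri <- c(seq(0, 1, length.out = 81), seq(1, 0.2, length.out = 40)[-1])
  expect_equal(detect_gp(tri, 0:119)$das, 80L)
  plateau <- c(seq(0, 1, length.out = 80), 1, 1, seq(0.99, 0.2, length.out = 38))
  expect_equal(detect_gp(plateau, 0:119)$das, 79L)
  flat <- rep(0.5, 60)
  expect_equal(detect_gp(flat, 0:59)$reason, "no_peak")
})

test_that("bimodal trajectories give first and last peaks as GP and SP", {
  p <- curve_params()
  s <- rescale_unit(smooth_signal(make_trajectory(p, 0:156)))
  gp <- detect_gp(s, 0:156)
  sp <- detect_sp(s, 0:156, gp$das)
  expect_equal(gp$das, p$t_gp)
  expect_equal(sp$das, p$t_sp)
  expect_true(is.na(sp$reason))
})

test_that("a unimodal signal flags SP = GP as degenerate", {
  tri <- c(seq(0, 1, length.out = 81), seq(1, 0, length.out = 41)[-1])
  gp <- detect_gp(tri, 0:120)
  sp <- detect_sp(tri, 0:120, gp$das)
  expect_equal(sp$das, gp$das)
  expect_equal(sp$reason, "unimodal")
})

test_that("end of senescence is the first slow-decline day after the guard", {
  # decline 0.05/day for 15 days after the peak, then 0.005/day
  s <- c(seq(0, 1, length.out = 41),
         1 - cumsum(rep(0.05, 15)), 0.25 - cumsum(rep(0.005, 20)))
  das <- seq_along(s) - 1L
  sp <- 40L
  r <- detect_eos(s, das, sp)
  expect_equal(r$das, 56L)   # first day with backward difference -0.005
  # slope exactly at the threshold does not qualify (strict inequality);
  # use a binary-exact decline rate so the comparison is sharp
  rate <- 0.0078125
  s2 <- c(seq(0, 1, length.out = 41), 1 - cumsum(rep(rate, 60)))
  r2 <- detect_eos(s2, seq_along(s2) - 1L, 40L, eos_slope = -rate)
  expect_true(is.na(r2$das))
  expect_equal(r2$reason, "season_truncated")
})

test_that("the drop guard keeps a flat peak top from triggering the scan", {
  s <- c(seq(0, 1, length.out = 41), rep(0.995, 5),
         0.995 - cumsum(rep(0.05, 15)), 0.245 - cumsum(rep(0.003, 10)))
  das <- seq_along(s) - 1L
  r <- detect_eos(s, das, 40L)
  expect_gt(r$das, 45L)
})

test_that("phase durations are differences with additivity and missingness", {
  pts <- data.frame(plot_id = "p1", SOG = 48, GP = 76, SP = 120, EOS = 140)
  ph <- compute_phases(pts)
  expect_equal(ph$SP_SOG, 72)
  expect_equal(ph$SP_SOG, ph$GP_SOG + ph$SP_GP)
  expect_equal(ph$GP_SOG, 28)
  pts2 <- data.frame(plot_id = "p1", SOG = NA, GP = 76, SP = 76, EOS = 140)
  ph2 <- compute_phases(pts2)
  expect_true(is.na(ph2$SP_SOG))
  expect_equal(ph2$SP_GP, 0)
})

test_that("detection is invariant to affine transforms of the raw signal", {
  p <- curve_params()
  y <- smooth_signal(make_trajectory(p, 0:156))
  a <- extract_phenopoints(0:156, y)
  b <- extract_phenopoints(0:156, 5 * y + 2)
  expect_identical(a[, c("SOG", "GP", "SP", "EOS")],
                   b[, c("SOG", "GP", "SP", "EOS")])
})

test_that("time points stay ordered on every synthetic realization", {
  set.seed(3)
  for (i in 1:40) {
    ts <- 48L + sample(-1:1, 1); tg <- 76L + sample(-3:3, 1)
    tp <- 125L + sample(-7:7, 1)
    p <- curve_params(t_sog = ts, t_gp = tg, t_sp = tp, t_eos = tp + 19L)
    y <- make_trajectory(p, 0:156) + rnorm(157, 0, 0.001)
    r <- extract_phenopoints(0:156, smooth_signal(y))
    pts <- c(r$SOG, r$GP, r$SP, r$EOS)
    if (!anyNA(pts)) expect_true(all(diff(pts) >= 0))
  }
})
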