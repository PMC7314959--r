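test_that("the surface basis spans plane surfaces and penalizes curvature only", {
  lay <- tiny_layout()
  b <- build_surface_basis(lay)
  # the unpenalized polynomial part has full column rank on the grid and the
  # penalized system is positive definite (identifiable through the ridge)
  expect_equal(qr(b$X)$rank, ncol(b$X))
  W <- cbind(b$X, do.call(cbind, b$Z))
  C <- crossprod(W) + diag(c(rep(0, ncol(b$X)),
                             rep(1, ncol(W) - ncol(b$X))))
  expect_no_error(chol(C))
  # a plane is reproduced exactly by the unpenalized polynomial part
  z <- 2 * lay$row + 3 * lay$range_col
  fit <- lm(z ~ b$X - 1)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  # second differences annihilate linear B-spline coefficient vectors
  p <- ncol(b$row$B)
  D <- diff(diag(p), differences = 2)
  expect_equal(max(abs(D %*% (2 + 3 * seq_len(p)))), 0)
})

test_that("requesting too many knots reduces them with a warning", {
  lay <- tiny_layout()
  expect_warning(build_surface_basis(lay, knots_r = 50), "reducing")
  expect_error(build_surface_basis(data.frame(row = c(1, 1, 2, 2),
                                              range_col = c(1, 2, 1, 2))),
               "at least 4")
})

test_that("coefficients with fixed penalties match a direct GLS solve", {
  lay <- tiny_layout(seed = 4L)
  set.seed(4)
  y <- rnorm(20, 10, 1)
  lamfix <- c(f_row = 2, f_col = 3, col_by_frow = 4, row_by_fcol = 5,
              f_rowcol = 6, row_fac = 1.5)
  f <- fit_spatial_model(y, lay, "fixed", lambda = lamfix)
  # oracle: generalized least squares on V = I + sum Z_k Z_k' / lambda_k,
  # random coefficients via the equivalent ridge back-solve
  b <- build_surface_basis(lay)
  G <- model.matrix(~ factor(lay$genotype) - 1)
  X <- cbind(b$X, G[, -1])
  Zl <- c(b$Z, list(row_fac = model.matrix(~ factor(lay$row) - 1)))
  V <- diag(length(y))
  for (k in names(Zl)) V <- V + tcrossprod(Zl[[k]]) / lamfix[k]
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid_gls <- y - X %*% beta
  expect_lt(max(abs(f$coefficients$fixed - beta)), 1e-8)
  for (k in names(Zl)) {
    u_k <- crossprod(Zl[[k]], Vi %*% resid_gls) / lamfix[k]
    expect_lt(max(abs(f$coefficients[[k]] - u_k)), 1e-8)
  }
})

test_that("effective dimensions partition the trace of the hat matrix", {
  lay <- tiny_layout(seed = 5L)
  set.seed(5)
  y <- rnorm(20, 10, 1) + 0.3 * lay$row
  f <- fit_spatial_model(y, lay, "random")
  H <- f$W %*% f$Cinv %*% t(f$W)
  expect_lt(abs(sum(diag(H)) - f$ed_total), 1e-6)
  expect_true(all(f$ed >= 0))
  expect_true(all(f$ed <= vapply(f$blocks, length, 0L) + 1e-8))
})

test_that("with noise orthogonal to the design, BLUEs equal genotype means", {
  lay <- test_campaign()$layout
  set.seed(11)
  gm <- setNames(rnorm(10, 20, 2), sort(unique(lay$genotype)))
  y <- as.numeric(gm[lay$genotype]) + orthogonal_noise(lay)
  f <- fit_spatial_model(y, lay, "fixed")
  bl <- genotype_blues(f)
  raw <- tapply(y, lay$genotype, mean)
  expect_lt(max(abs(bl$blue - raw[bl$genotype])), 1e-6)
  # adding a constant shifts every BLUE by that constant
  f2 <- fit_spatial_model(y + 5, lay, "fixed")
  bl2 <- genotype_blues(f2)
  expect_equal(bl2$blue, bl$blue + 5, tolerance = 1e-6)
})

test_that("as penalties grow the fit becomes the polynomial-plus-genotype OLS", {
  lay <- tiny_layout(seed = 6L)
  set.seed(6)
  y <- rnorm(20, 5, 1)
  lamInf <- setNames(rep(1e8, 6),
                     c("f_row", "f_col", "col_by_frow", "row_by_fcol",
                       "f_rowcol", "row_fac"))
  f <- fit_spatial_model(y, lay, "fixed", lambda = lamInf)
  b <- build_surface_basis(lay)
  G <- model.matrix(~ factor(lay$genotype) - 1)
  X <- cbind(b$X, G[, -1])
  expect_lt(max(abs(f$coefficients$fixed - coef(lm(y ~ X - 1)))), 1e-5)
  # and as penalties shrink, the fit interpolates better than any fixed one
  lam0 <- lamInf; lam0[] <- 1e-6
  f0 <- fit_spatial_model(y, lay, "fixed", lambda = lam0)
  expect_lt(sum(f0$residuals^2), sum(f$residuals^2) + 1e-10)
})

test_that("BLUEs remove a column-aligned gradient that biases raw means", {
  # unbalanced layout (two plots of one genotype dropped from the low-gradient
  # side) with a strong column gradient: raw means are biased, BLUEs are not
  set.seed(12)
  lay <- test_campaign()$layout
  drop <- which(lay$genotype == "g05" & lay$range_col <= 3)[1:2]
  lay2 <- lay[-drop, ]
  ge <- setNames(rep(0.40, 10), sort(unique(lay$genotype)))
  sv <- simulate_plot_values(lay2, ge, gradient_coef = 0.04, noise_sd = 0.002)
  f <- fit_spatial_model(sv$y, lay2, "fixed")
  bl <- genotype_blues(f)
  se_diff <- sqrt(max(bl$se)^2 + median(bl$se)^2)
  blue_bias <- abs((bl$blue[bl$genotype == "g05"] - mean(bl$blue[bl$genotype != "g05"])))
  raw <- tapply(sv$y, lay2$genotype, mean)
  raw_bias <- abs(raw["g05"] - mean(raw[names(raw) != "g05"]))
  expect_gt(raw_bias, 2 * se_diff)   # phenotypic means carry the confound
  expect_lt(blue_bias, 2 * se_diff)  # genotypic values do not
})

test_that("heritability follows the effective-dimension formula and its bounds", {
  fake <- structure(list(genotype_mode = "random", m_g = 10L,
                         ed = c(genotype = 6.3)), class = "spatial_fit")
  h <- heritability(fake)
  expect_equal(h$H2, 0.7)
  expect_error(heritability(structure(list(genotype_mode = "fixed"),
                                      class = "spatial_fit")), "random")
  lay <- tiny_layout(seed = 7L)
  set.seed(7)
  y <- rnorm(20)
  f <- fit_spatial_model(y, lay, "random")
  h2 <- heritability(f)
  expect_gte(h2$H2, 0)
  expect_lte(h2$H2, 1)
  expect_lte(h2$ED_g, h2$m_g - 1)
})

test_that("correct_all processes responses independently and logs failures", {
  lay <- test_campaign()$layout
  set.seed(13)
  vals <- data.frame(plot_id = lay$plot_id,
                     good = rnorm(80, 10) + (lay$genotype == "g01"),
                     constant = 7)
  res <- correct_all(vals, lay)
  expect_true("good" %in% res$blues$response)
  expect_true("constant" %in% names(res$errors))
  expect_false("constant" %in% res$blues$response)
  expect_true(all(res$h2$H2 >= 0 & res$h2$H2 <= 1))
  # single response delegates exactly to the two underlying fits
  fb <- fit_spatial_model(vals$good, lay, "fixed")
  expect_equal(res$blues$blue[res$blues$response == "good"],
               genotype_blues(fb)$blue, tolerance = 1e-10)
})

test_that("phase durations derive from corrected time-point BLUEs", {
  camp <- test_campaign()
  pts <- phenopoints_all(daily_signal(aggregate_daily(camp$observations)))
  res <- correct_phenopoints(pts, camp$layout)
  expect_true(all(c("SOG", "GP", "SP", "EOS") %in% res$points$h2$response))
  expect_true(all(res$points$h2$H2 >= 0 & res$points$h2$H2 <= 1))
  wide <- reshape(res$points$blues[, c("response", "genotype", "blue")],
                  direction = "wide", idvar = "genotype", timevar = "response")
  names(wide) <- sub("^blue\\.", "", names(wide))
  m <- merge(res$phases, wide, by = "genotype")
  expect_equal(m$SP_SOG, m$SP - m$SOG, tolerance = 1e-10)
  expect_true(all(m$SP_SOG >= 0))
})
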