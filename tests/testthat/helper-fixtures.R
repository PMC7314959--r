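# Shared fixtures, generated once per test run.

# Small observation-level campaign (low capture rate keeps it light).
test_campaign <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- make_campaign(campaign_config(images_per_hour = c(4L, 6L),
                                             seed = 101L))
    }
    memo
  }
})

# 4 x 5 grid with 5 genotypes in 4 complete column blocks.
tiny_layout <- function(seed = 1L) {
  set.seed(seed)
  lay <- expand.grid(row = 1:4, range_col = 1:5)
  lay$plot_id <- sprintf("t%02d", seq_len(nrow(lay)))
  lay$genotype <- unlist(lapply(1:5, function(b) sample(sprintf("g%d", 1:4))))
  lay$block <- sprintf("b%d", lay$range_col)
  lay
}

# Noise orthogonal to the full fixed-genotype model design: the penalized
# fit then reproduces the genotype means exactly, for any penalty.
orthogonal_noise <- function(layout, sd = 0.5) {
  b <- build_surface_basis(layout)
  G <- stats::model.matrix(~ factor(layout$genotype) - 1)
  W <- cbind(b$X, G[, -1], do.call(cbind, b$Z),
             stats::model.matrix(~ factor(layout$row) - 1))
  e <- stats::rnorm(nrow(layout), 0, sd)
  as.numeric(e - qr.fitted(qr(W), e))
}

# Brute-force Savitzky-Golay oracle: windowed least-squares polynomial fit
# evaluated at the window centre (interior points only).
sg_oracle_interior <- function(y, p = 3L, n = 7L) {
  h <- (n - 1L) %/% 2L
  out <- rep(NA_real_, length(y))
  for (i in (h + 1L):(length(y) - h)) {
    w <- (i - h):(i + h)
    X <- outer(w, 0:p, "^")
    b <- qr.solve(X, y[w])
    out[i] <- sum(outer(i, 0:p, "^") * b)
  }
  out
}
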