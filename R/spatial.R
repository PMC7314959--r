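#' Two-dimensional P-spline surface basis for a field layout
#'
#' Builds the PS-ANOVA decomposition of a tensor-product cubic B-spline
#' surface over row and range (column) positions: an unpenalized polynomial
#' part (intercept, linear row, linear column, their product) and five
#' penalized smooth parts (row-smooth, column-smooth, the two
#' linear-by-smooth interactions, and the smooth-by-smooth interaction),
#' each reparameterized through the eigendecomposition of its second-order
#' difference penalty so that every smooth block carries an identity
#' covariance in the mixed model.
#'
#' @param layout Data frame with integer columns `row` and `range_col`.
#' @param knots_r,knots_c Number of B-spline segments per dimension;
#'   `NULL` (default) uses `min(ceiling(d / 2), 10)` where `d` is the number
#'   of distinct positions. Too-large requests are reduced with a warning.
#' @return List with the fixed design `X` (polynomial part), the list `Z` of
#'   smooth random designs, and bookkeeping needed for prediction.
#' @export
build_surface_basis <- function(layout, knots_r = NULL, knots_c = NULL) {
  r <- layout$row; c_ <- layout$range_col
  ur <- sort(unique(r)); uc <- sort(unique(c_))
  if (length(ur) < 4L || length(uc) < 4L)
    stop("need at least 4 distinct rows and 4 distinct columns")
  default_k <- function(d) min(ceiling(d / 2), 10L)
  cap_k <- function(k, d, what) {
    if (is.null(k)) return(default_k(d))
    if (k > d) {
      warning("reducing ", what, " segments from ", k, " to ", d)
      k <- d
    }
    max(2L, k)
  }
  kr <- cap_k(knots_r, length(ur), "row")
  kc <- cap_k(knots_c, length(uc), "column")
  mr <- marginal_basis(r, kr)
  mc <- marginal_basis(c_, kc)
  xr <- mr$x; xc <- mc$x
  X <- cbind(`(Intercept)` = 1, row_lin = xr, col_lin = xc, rowcol_lin = xr * xc)
  Z <- list(
    f_row = mr$Z,
    f_col = mc$Z,
    col_by_frow = mr$Z * xc,
    row_by_fcol = mc$Z * xr,
    f_rowcol = rowwise_kron(mr$Z, mc$Z))
  list(X = X, Z = Z, row = mr, col = mc)
}

# Marginal P-spline pieces for one coordinate: cubic B-spline basis with
# `nseg` equal segments, second-order difference penalty, mixed-model
# reparameterization Z = B U_+ diag(1/sqrt(ev_+)). The null space of the
# penalty (constant + linear) is represented by the centred/scaled
# coordinate itself.
marginal_basis <- function(v, nseg) {
  rng <- range(v)
  h <- diff(rng) / nseg
  knots <- seq(rng[1] - 3 * h, rng[2] + 3 * h, by = h)
  B <- splines::splineDesign(knots, v, ord = 4)
  p <- ncol(B)
  D <- diff(diag(p), differences = 2)
  e <- eigen(crossprod(D), symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  U <- e$vectors[, pos, drop = FALSE]
  Z <- B %*% U %*% diag(1 / sqrt(e$values[pos]), sum(pos))
  x <- (v - mean(rng)) / (diff(rng) / 2)   # centred, scaled to [-1, 1]
  list(x = x, Z = Z, B = B, knots = knots, U = U, ev = e$values[pos], nseg = nseg)
}

# Row-wise Khatri-Rao product: tensor interaction evaluated at observations.
rowwise_kron <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(A) * ncol(B))
  for (j in seq_len(ncol(A))) {
    out[, (j - 1L) * ncol(B) + seq_len(ncol(B))] <- A[, j] * B
  }
  out
}

#' Fit the spatial mixed model to plot values
#'
#' Fits `Y = f(r, c) + Z_g c_g + Z_r c_r + eps`, where `f(r, c)` is the
#' PS-ANOVA P-spline surface of [build_surface_basis()], `c_g` the genotype
#' effects (fixed for BLUE extraction, random for heritability) and `c_r` a
#' random row effect. Variance components are estimated by deterministic
#' Schall-type REML iteration on the mixed-model equations; the effective
#' dimension of each random component is its partition of the trace of the
#' influence (hat) matrix.
#'
#' @param y Numeric plot values, aligned with `layout` rows; `NA`s dropped.
#' @param layout Data frame with `plot_id`, `row`, `range_col`, `genotype`.
#' @param genotype_mode `"fixed"` (genotype BLUEs) or `"random"`
#'   (effective-dimension heritability).
#' @param knots_r,knots_c Passed to [build_surface_basis()].
#' @param lambda Optional named numeric vector of fixed penalty ratios
#'   (residual variance over component variance) for any of
#'   `f_row`, `f_col`, `col_by_frow`, `row_by_fcol`, `f_rowcol`, `row_fac`,
#'   `genotype`; fixed components are excluded from the REML update.
#' @param tol Relative convergence tolerance on effective dimensions and
#'   variances (default 1e-6).
#' @param max_iter Maximum REML iterations (default 5000).
#' @return Object of class `spatial_fit` with coefficients, fitted values,
#'   residuals, variance components, per-component effective dimensions and
#'   everything needed by [genotype_blues()] and [heritability()].
#' @export
fit_spatial_model <- function(y, layout, genotype_mode = c("fixed", "random"),
                              knots_r = NULL, knots_c = NULL, lambda = NULL,
                              tol = 1e-6, max_iter = 5000L) {
  genotype_mode <- match.arg(genotype_mode)
  keep <- is.finite(y)
  y0 <- y[keep]
  lay <- layout[keep, , drop = FALSE]
  geno <- factor(as.character(lay$genotype))
  m_g <- nlevels(geno)
  if (m_g < 2L) stop("need at least 2 genotypes")
  if (any(table(geno) < 2L) && genotype_mode == "fixed")
    warning("some genotypes have a single plot; their BLUEs equal that plot")
  basis <- build_surface_basis(lay, knots_r, knots_c)
  G <- stats::model.matrix(~ geno - 1)
  colnames(G) <- levels(geno)
  rowfac <- factor(lay$row)
  Zrow <- stats::model.matrix(~ rowfac - 1)
  X <- basis$X
  Z <- basis$Z
  Z$row_fac <- Zrow
  if (genotype_mode == "fixed") {
    X <- cbind(X, G[, -1L, drop = FALSE])
  } else {
    Z$genotype <- G
  }
  fit <- schall_fit(y0, X, Z, lambda = lambda, tol = tol, max_iter = max_iter)
  structure(c(fit, list(
    response = deparse(substitute(y)), basis = basis, genotype = geno,
    genotype_levels = levels(geno), genotype_mode = genotype_mode,
    layout = lay, m_g = m_g, keep = keep)), class = "spatial_fit")
}

# Schall-type REML for y = X b + sum_k Z_k u_k + e, u_k ~ N(0, s2_k I).
# lambda_k = s2_e / s2_k; ED_k = q_k - lambda_k * tr(Cinv_kk).
schall_fit <- function(y, X, Z, lambda = NULL, tol = 1e-6, max_iter = 5000L) {
  n <- length(y)
  p <- ncol(X)
  q <- vapply(Z, ncol, 0L)
  K <- length(Z)
  W <- cbind(X, do.call(cbind, Z))
  blocks <- vector("list", K)
  off <- p
  for (k in seq_len(K)) {
    blocks[[k]] <- off + seq_len(q[k])
    off <- off + q[k]
  }
  names(blocks) <- names(Z)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  lam <- stats::setNames(rep(1, K), names(Z))
  fixed_lam <- rep(FALSE, K)
  if (!is.null(lambda)) {
    idx <- match(names(lambda), names(Z))
    if (anyNA(idx)) stop("unknown component in lambda: ",
                         paste(names(lambda)[is.na(idx)], collapse = ", "))
    lam[idx] <- lambda
    fixed_lam[idx] <- TRUE
  }
  LAM_MAX <- 1e8   # a variance ratio below 1e-8 is numerically zero: pin it
  ed <- rep(NA_real_, K)
  s2e <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- WtW
    for (k in seq_len(K)) {
      d <- blocks[[k]]
      C[cbind(d, d)] <- C[cbind(d, d)] + lam[k]
    }
    R <- tryCatch(chol(C), error = function(e)
      stop("mixed-model equations not positive definite; iteration ", it))
    theta <- backsolve(R, forwardsolve(t(R), Wty))
    Cinv <- chol2inv(R)
    resid <- y - as.numeric(W %*% theta)
    rss <- sum(resid^2)
    ed_new <- vapply(seq_len(K), function(k) {
      d <- blocks[[k]]
      q[k] - lam[k] * sum(diag(Cinv)[d])
    }, 0)
    ed_new <- pmax(ed_new, 0)
    ed_tot <- p + sum(ed_new)
    if (n - ed_tot <= 0) stop("model saturates the data; reduce knots")
    s2e_new <- rss / (n - ed_tot)
    if (s2e_new <= 1e-14 * max(1, stats::var(y)))
      stop("degenerate fit: zero residual variance")
    lam_new <- lam
    for (k in seq_len(K)) {
      if (fixed_lam[k]) next
      u2 <- sum(theta[blocks[[k]]]^2)
      s2k <- if (ed_new[k] > 1e-10) u2 / ed_new[k] else 0
      lam_new[k] <- if (s2k <= s2e_new / LAM_MAX) LAM_MAX else s2e_new / s2k
      if (lam_new[k] >= LAM_MAX) {
        lam_new[k] <- LAM_MAX
        fixed_lam[k] <- TRUE   # component effectively eliminated; freeze it
      }
    }
    delta <- max(abs(ed_new - ifelse(is.na(ed), 0, ed)) / (1 + ed_new),
                 abs(s2e_new - ifelse(is.na(s2e), 0, s2e)) / (1 + s2e_new))
    ed <- ed_new; s2e <- s2e_new
    if (all(fixed_lam)) { lam <- lam_new; converged <- TRUE; break }
    lam <- lam_new
    if (delta < tol && it > 1L) { converged <- TRUE; break }
  }
  if (!converged)
    stop("REML did not converge in ", max_iter,
         " iterations (last max relative change ", signif(delta, 3), ")")
  names(ed) <- names(Z)
  coef_split <- c(list(fixed = theta[seq_len(p)]),
                  stats::setNames(lapply(blocks, function(d) theta[d]), names(Z)))
  fitted <- as.numeric(W %*% theta)
  list(coefficients = coef_split, theta = as.numeric(theta), W = W, X = X,
       blocks = blocks, fitted = fitted, residuals = y - fitted, y = y,
       sigma2 = s2e, lambda = lam, var_comp = s2e / lam, ed = ed,
       ed_total = p + sum(ed), p_fixed = p, n = n, n_iter = it, Cinv = Cinv)
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat("Spatial P-spline mixed model (", x$genotype_mode, " genotype effects)\n",
      sep = "")
  cat("  n =", x$n, " genotypes =", x$m_g, " iterations =", x$n_iter, "\n")
  cat("  residual variance:", signif(x$sigma2, 4), "\n")
  cat("  effective dimensions:\n")
  print(round(x$ed, 3))
  invisible(x)
}

#' Genotype BLUEs from a spatial fit
#'
#' Best linear unbiased estimators of the genotype values (genotype fixed).
#' Each BLUE is reported on the response scale as the model prediction for
#' that genotype averaged over all observed field positions, so BLUEs are
#' directly comparable to phenotypic means and shift by `k` when `k` is
#' added to every observation.
#'
#' @param fit A `spatial_fit` with `genotype_mode = "fixed"`.
#' @return Data frame `genotype`, `blue`, `se`.
#' @export
genotype_blues <- function(fit) {
  if (fit$genotype_mode != "fixed")
    stop("BLUEs require genotype_mode = 'fixed'")
  levs <- fit$genotype_levels
  m <- length(levs)
  a_base <- colMeans(fit$W)
  gcols <- fit$p_fixed - (m - 1L) + seq_len(m - 1L)   # genotype dummy columns
  out <- data.frame(genotype = levs, blue = NA_real_, se = NA_real_)
  for (i in seq_len(m)) {
    a <- a_base
    a[gcols] <- 0
    if (i > 1L) a[gcols[i - 1L]] <- 1
    out$blue[i] <- sum(a * fit$theta)
    out$se[i] <- sqrt(fit$sigma2 * drop(t(a) %*% fit$Cinv %*% a))
  }
  out
}

#' Heritability from effective dimensions
#'
#' Generalized heritability of a spatially corrected trait:
#' `H2 = ED_g / (m_g - 1)`, where `ED_g` is the effective dimension of the
#' random genotype effect and `m_g` the number of genotypes; `m_g - 1` is
#' the upper bound `ED_g` attains when genotypic variance dominates.
#'
#' @param fit A `spatial_fit` with `genotype_mode = "random"`.
#' @return List `H2`, `ED_g`, `m_g`.
#' @export
heritability <- function(fit) {
  if (fit$genotype_mode != "random")
    stop("heritability requires genotype_mode = 'random'")
  if (fit$m_g < 2L) stop("need at least 2 genotypes")
  ed_g <- unname(fit$ed["genotype"])
  h2 <- min(1, max(0, ed_g / (fit$m_g - 1)))
  list(H2 = h2, ED_g = ed_g, m_g = fit$m_g)
}

#' Spatially correct a table of plot-level responses
#'
#' For each response column the model is fitted twice: genotype fixed for
#' BLUEs, genotype random for heritability — the order used throughout:
#' time points are corrected first and phase durations derived from the
#' corrected time-point BLUEs.
#'
#' @param values Data frame keyed by `plot_id` with one column per response.
#' @param layout Field layout (`plot_id`, `row`, `range_col`, `genotype`).
#' @param responses Character vector of columns of `values` to process
#'   (default: all non-key numeric columns).
#' @param ... Passed to [fit_spatial_model()].
#' @return List with `blues` (long data frame `response`, `genotype`,
#'   `blue`, `se`), `h2` (`response`, `H2`, `ED_g`, `m_g`), and `errors`
#'   (named character vector of per-response failures).
#' @export
correct_all <- function(values, layout, responses = NULL, ...) {
  stopifnot("plot_id" %in% names(values))
  idx <- match(layout$plot_id, values$plot_id)
  if (is.null(responses))
    responses <- setdiff(names(values)[vapply(values, is.numeric, TRUE)],
                         c("row", "range_col", "das"))
  blues <- list(); h2 <- list(); errors <- character()
  for (resp in responses) {
    yv <- values[[resp]][idx]
    res <- tryCatch({
      fb <- fit_spatial_model(yv, layout, genotype_mode = "fixed", ...)
      fr <- fit_spatial_model(yv, layout, genotype_mode = "random", ...)
      b <- genotype_blues(fb)
      h <- heritability(fr)
      list(b = b, h = h)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[resp] <- conditionMessage(res)
      next
    }
    blues[[resp]] <- cbind(response = resp, res$b)
    h2[[resp]] <- data.frame(response = resp, H2 = res$h$H2,
                             ED_g = res$h$ED_g, m_g = res$h$m_g)
  }
  list(blues = do.call(rbind, c(blues, list(make.row.names = FALSE))),
       h2 = do.call(rbind, c(h2, list(make.row.names = FALSE))),
       errors = errors)
}

#' Corrected phase durations from corrected time points
#'
#' Applies [correct_all()] to the four time-point columns and derives the
#' phase durations from the genotype BLUEs of the corrected time points.
#'
#' @param points Output of [phenopoints_all()].
#' @param layout Field layout.
#' @param ... Passed to [fit_spatial_model()].
#' @return List `points` (the [correct_all()] result for SOG/GP/SP/EOS) and
#'   `phases` (genotype-level durations from the BLUEs).
#' @export
correct_phenopoints <- function(points, layout, ...) {
  res <- correct_all(points, layout,
                     responses = intersect(c("SOG", "GP", "SP", "EOS"),
                                           names(points)), ...)
  phases <- NULL
  if (!is.null(res$blues)) {
    wide <- stats::reshape(res$blues[, c("response", "genotype", "blue")],
                           direction = "wide", idvar = "genotype",
                           timevar = "response")
    names(wide) <- sub("^blue\\.", "", names(wide))
    have <- intersect(c("SOG", "GP", "SP", "EOS"), names(wide))
    if (length(have) >= 2L) {
      pairs <- c("GP_SOG", "SP_SOG", "SP_GP", "EOS_SP", "EOS_GP")
      pairs <- pairs[vapply(strsplit(pairs, "_"), function(ab)
        all(ab %in% have), TRUE)]
      phases <- compute_phases(wide, pairs)
    }
  }
  list(points = res, phases = phases)
}
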