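#' Signed coefficient of determination between two variables
#'
#' Simple linear regression of `y` on `x`, reported the way correlation
#' panels in phenology studies present it: the coefficient of determination
#' `R2` with the slope sign carried separately. The analysis level
#' (`phenotypic` = plot values, `genotypic` = genotype BLUEs) is an explicit
#' part of the result so that levels are never silently mixed.
#'
#' @param x,y Named numeric vectors keyed by plot id or genotype; only keys
#'   present in both enter the regression.
#' @param level `"phenotypic"` or `"genotypic"`.
#' @param pair Optional label `c(x_name, y_name)` for the output.
#' @return One-row data frame `x`, `y`, `level`, `r2`, `sign`, `slope`,
#'   `p_value`, `n`.
#' @export
correlate <- function(x, y, level = c("phenotypic", "genotypic"),
                      pair = c(deparse(substitute(x)), deparse(substitute(y)))) {
  level <- match.arg(level)
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by plot id or genotype")
  keys <- intersect(names(x), names(y))
  xv <- as.numeric(x[keys]); yv <- as.numeric(y[keys])
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop("need at least 3 paired complete observations")
  if (stats::var(xv) == 0 || stats::var(yv) == 0)
    stop("undefined correlation: zero variance")
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  data.frame(x = pair[1], y = pair[2], level = level,
             r2 = sm$r.squared, sign = if (slope >= 0) "+" else "-",
             slope = slope, p_value = sm$coefficients[2, 4], n = n,
             stringsAsFactors = FALSE)
}

#' Two-regime regression of gcc on senescence rating
#'
#' Canopy greenness first rises with the visual senescence rating (leaves
#' yellow but stay attached) and then falls sharply once leaf drop sets in;
#' the regime change sits near a rating of 65%. Fits independent
#' regressions below and above the split (boundary included in both).
#'
#' @param gcc,rating Named numeric vectors keyed alike (plot or genotype).
#' @param split Rating (percent) separating the regimes (default 65).
#' @param level Analysis level, see [correlate()].
#' @return Data frame of one or two [correlate()] rows with a `regime`
#'   column (`"below"`, `"above"`); one-sided data returns a single row.
#' @export
senescence_split_regression <- function(gcc, rating, split = 65,
                                        level = c("phenotypic", "genotypic")) {
  level <- match.arg(level)
  keys <- intersect(names(gcc), names(rating))
  g <- gcc[keys]; r <- rating[keys]
  out <- list()
  lo <- names(r)[is.finite(r) & r <= split]
  hi <- names(r)[is.finite(r) & r >= split]
  if (length(lo) >= 3L && stats::var(r[lo]) > 0)
    out$below <- cbind(regime = "below",
                       correlate(r[lo], g[lo], level, c("senescence_pct", "gcc")))
  if (length(hi) >= 3L && stats::var(r[hi]) > 0)
    out$above <- cbind(regime = "above",
                       correlate(r[hi], g[hi], level, c("senescence_pct", "gcc")))
  if (length(out) == 0L) stop("no regime with enough data on either side of ", split)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Linear range and saturation of the gcc-LAI relationship
#'
#' Greenness tracks leaf area index roughly linearly between LAI 1 and a
#' saturation level beyond which additional leaf layers no longer change
#' canopy colour. Points below `lai_min` are excluded (the optical LAI
#' reference is unreliable there); the linear regime is fitted by least
#' squares, and the saturation LAI is estimated as the midpoint of the
#' first LAI bin where the local slope falls below `sat_frac` of the
#' linear-regime slope and stays below it thereafter.
#'
#' @param lai,gcc Paired numeric vectors (plot-level values, any keying).
#' @param lai_min Lower LAI bound of the linear regime (default 1).
#' @param linear_max Upper LAI bound used to fit the linear-regime slope
#'   (default 2.5, safely below any plausible saturation).
#' @param sat_frac Fraction of the linear slope defining saturation
#'   (default 0.1).
#' @param bin_width LAI bin width for local slopes (default 0.5).
#' @return List `slope` (linear-regime slope), `intercept`, `r2_linear`,
#'   `saturation_lai` (estimate or `NA`), `saturated` (logical),
#'   `n_linear`, `n_excluded_low`.
#' @export
lai_gcc_curve <- function(lai, gcc, lai_min = 1, linear_max = 2.5,
                          sat_frac = 0.1, bin_width = 0.5) {
  ok <- is.finite(lai) & is.finite(gcc)
  lai <- lai[ok]; gcc <- gcc[ok]
  n_low <- sum(lai < lai_min)
  lin <- lai >= lai_min & lai <= linear_max
  if (sum(lin) < 3L) stop("insufficient data in the linear LAI regime")
  fit <- stats::lm(gcc[lin] ~ lai[lin])
  slope <- unname(stats::coef(fit)[2])
  res <- list(slope = slope, intercept = unname(stats::coef(fit)[1]),
              r2_linear = summary(fit)$r.squared,
              saturation_lai = NA_real_, saturated = FALSE,
              n_linear = sum(lin), n_excluded_low = n_low)
  breaks <- seq(lai_min, max(lai) + bin_width, by = bin_width)
  if (length(breaks) < 4L) return(res)   # span too short to see saturation
  mids <- breaks[-length(breaks)] + bin_width / 2
  bin <- cut(lai, breaks, include.lowest = TRUE, labels = FALSE)
  bm <- tapply(gcc, factor(bin, levels = seq_along(mids)), mean)
  ok_bin <- !is.na(bm)
  if (sum(ok_bin) < 4L) return(res)
  local_slope <- diff(bm[ok_bin]) / diff(mids[ok_bin])
  slow <- local_slope < sat_frac * slope
  # first bin boundary from which all later local slopes stay slow
  persist <- rev(cumprod(rev(slow))) == 1
  if (any(persist)) {
    i <- which(persist)[1]
    res$saturation_lai <- mids[ok_bin][i]
    res$saturated <- TRUE
  }
  res
}

#' Correlate phenology with traits across a table
#'
#' Convenience wrapper producing the figure-style summary: every requested
#' x/y pair run through [correlate()] at the given level, errors per pair
#' collected rather than aborting the rest.
#'
#' @param data Data frame containing a key column and the variables.
#' @param key Name of the key column (`"plot_id"` or `"genotype"`).
#' @param pairs Two-column character matrix (or data frame) of x/y variable
#'   names.
#' @param level Analysis level, see [correlate()].
#' @return Data frame of [correlate()] rows; failed pairs are dropped with
#'   a warning naming them.
#' @export
correlate_table <- function(data, key, pairs,
                            level = c("phenotypic", "genotypic")) {
  level <- match.arg(level)
  pairs <- as.matrix(pairs)
  rows <- list(); failed <- character()
  for (i in seq_len(nrow(pairs))) {
    xn <- pairs[i, 1]; yn <- pairs[i, 2]
    r <- tryCatch(
      correlate(stats::setNames(data[[xn]], data[[key]]),
                stats::setNames(data[[yn]], data[[key]]),
                level, c(xn, yn)),
      error = function(e) e)
    if (inherits(r, "error")) failed <- c(failed, paste0(xn, "~", yn)) else
      rows[[length(rows) + 1L]] <- r
  }
  if (length(failed)) warning("pairs skipped: ", paste(failed, collapse = ", "))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
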