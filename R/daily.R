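#' Collapse intra-day observations to one value per day
#'
#' The representative daily value is the median of all retained observations
#' of a plot on a day (robust to illumination changes); the 90th percentile
#' used elsewhere in the PhenoCam literature is available for comparison.
#'
#' @param observations Data frame with columns `plot_id`, `das`, `gcc`
#'   (as produced by [extract_observations()]); `NA` gcc values are dropped.
#' @param aggregator `"median"` (default) or `"p90"`.
#' @return Data frame `plot_id`, `das`, `gcc_raw`, `n_obs`, sorted by plot
#'   and day. Days with no valid observation are absent (gaps are flagged,
#'   never silently interpolated here).
#' @export
aggregate_daily <- function(observations, aggregator = c("median", "p90")) {
  aggregator <- match.arg(aggregator)
  obs <- observations[is.finite(observations$gcc), , drop = FALSE]
  if (nrow(obs) == 0L) {
    warning("no valid observations to aggregate")
    return(data.frame(plot_id = character(), das = integer(),
                      gcc_raw = numeric(), n_obs = integer()))
  }
  f <- if (aggregator == "median") stats::median else
    function(x) stats::quantile(x, 0.9, names = FALSE, type = 7)
  key <- interaction(obs$plot_id, obs$das, drop = TRUE)
  agg <- data.frame(
    plot_id = tapply(as.character(obs$plot_id), key, `[`, 1L),
    das = as.integer(tapply(obs$das, key, `[`, 1L)),
    gcc_raw = as.numeric(tapply(obs$gcc, key, f)),
    n_obs = as.integer(tapply(obs$gcc, key, length)),
    row.names = NULL)
  agg[order(agg$plot_id, agg$das), , drop = FALSE]
}

# Linear interpolation of interior gaps up to max_gap days; longer gaps keep
# NA and split the series into independently smoothed segments.
fill_small_gaps <- function(das, gcc, max_gap = 3L) {
  full <- seq.int(min(das), max(das))
  y <- rep(NA_real_, length(full))
  y[match(das, full)] <- gcc
  interpolated <- rep(FALSE, length(full))
  isna <- is.na(y)
  if (any(isna)) {
    r <- rle(isna)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (r$lengths[k] <= max_gap && starts[k] > 1L && ends[k] < length(y)) {
        i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
        idx <- starts[k]:ends[k]
        y[idx] <- y[i0] + (y[i1] - y[i0]) * (idx - i0) / (i1 - i0)
        interpolated[idx] <- TRUE
      }
    }
  }
  data.frame(das = full, gcc = y, is_interpolated = interpolated)
}

#' Savitzky-Golay smoothing of a daily series
#'
#' Local least-squares polynomial smoothing (default 3rd order, 7-day
#' window), the standard filter for damping day-to-day illumination noise in
#' PhenoCam greenness series. Boundaries are handled by evaluating the
#' boundary-window polynomial at the edge days (polynomial extension), which
#' avoids artificial extrema where season start and end points are detected.
#'
#' @param x Numeric vector on a regular daily grid, no `NA`.
#' @param poly_order Polynomial order (default 3).
#' @param window Odd window length > `poly_order` (default 7).
#' @return Smoothed vector of the same length. Series shorter than `window`
#'   are returned unsmoothed with a warning.
#' @export
smooth_signal <- function(x, poly_order = 3L, window = 7L) {
  stopifnot(window %% 2L == 1L, window > poly_order)
  if (length(x) < window) {
    warning("series shorter than smoothing window; returned unsmoothed")
    return(x)
  }
  as.numeric(signal::sgolayfilt(x, p = poly_order, n = window))
}

#' Build smoothed daily signals for every plot
#'
#' Fills interior gaps of at most `max_gap_interp_days` by linear
#' interpolation (the filter needs a regular grid); longer gaps split a
#' plot's series into segments smoothed independently.
#'
#' @param daily Output of [aggregate_daily()].
#' @param poly_order,window Savitzky-Golay settings (defaults 3 and 7).
#' @param max_gap_interp_days Largest gap bridged by interpolation
#'   (default 3).
#' @return Data frame `plot_id`, `das`, `gcc_raw`, `gcc_smooth`,
#'   `is_interpolated`; `gcc_raw` is `NA` on interpolated days.
#' @export
daily_signal <- function(daily, poly_order = 3L, window = 7L,
                         max_gap_interp_days = 3L) {
  out <- lapply(split(daily, daily$plot_id), function(d) {
    d <- d[order(d$das), , drop = FALSE]
    filled <- fill_small_gaps(d$das, d$gcc_raw, max_gap_interp_days)
    # segment id: runs of non-NA days
    obsrun <- !is.na(filled$gcc)
    segid <- cumsum(c(TRUE, diff(obsrun) != 0))
    filled$gcc_smooth <- NA_real_
    for (s in unique(segid[obsrun])) {
      idx <- which(segid == s & obsrun)
      filled$gcc_smooth[idx] <- smooth_signal(filled$gcc[idx], poly_order, window)
    }
    keep <- obsrun
    data.frame(plot_id = d$plot_id[1], das = filled$das[keep],
               gcc_raw = ifelse(filled$is_interpolated[keep], NA_real_,
                                filled$gcc[keep]),
               gcc_smooth = filled$gcc_smooth[keep],
               is_interpolated = filled$is_interpolated[keep],
               row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
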