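#' Scale a smoothed signal to the unit interval
#'
#' Transition points are defined on the per-plot signal scaled so that its
#' minimum is 0 and maximum is 1; the slope thresholds (0.015 per day for
#' green-up, -0.01 per day for end of senescence) are expressed in these
#' scaled units. Scaling makes detection invariant to affine transformations
#' of the raw greenness signal.
#'
#' @param x Numeric vector (smoothed daily gcc).
#' @return Vector with `min = 0`, `max = 1`.
#' @export
rescale_unit <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] <= 0)
    stop("degenerate signal: no variation to scale")
  (x - r[1]) / (r[2] - r[1])
}

# Local maxima of s with plateau tie-break to the earliest day, restricted to
# a height floor, with topographic prominence >= min_prominence.
# Returns integer indices into s.
find_peaks <- function(s, min_prominence = 0.02, min_height = 0.35) {
  n <- length(s)
  if (n < 3L) return(integer())
  cand <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[j]) j <- j + 1L  # plateau
      if (j < n && s[j + 1L] < s[j]) cand <- c(cand, i)  # earliest plateau day
      i <- j + 1L
    } else i <- i + 1L
  }
  cand <- cand[s[cand] >= min_height]
  if (length(cand) == 0L) return(integer())
  # topographic prominence: for each candidate, lowest point on the path to
  # the nearest higher ground on each side (series edge counts as a key col).
  prom <- vapply(cand, function(p) {
    h <- s[p]
    left <- if (p > 1L) s[seq_len(p - 1L)] else numeric()
    right <- if (p < n) s[(p + 1L):n] else numeric()
    base_side <- function(v) {
      higher <- which(v > h)
      if (length(higher) == 0L) min(v, h) else {
        # v ordered moving away from the peak for the left side handled below
        min(v[seq_len(min(higher))])
      }
    }
    lb <- base_side(rev(left))
    rb <- base_side(right)
    h - max(lb, rb)
  }, 0)
  cand[prom >= min_prominence]
}

#' Detect the green peak
#'
#' First local maximum of the scaled signal after green-up onset (the first
#' day the scaled signal exceeds `greenup_level`). Peaks must reach the
#' height floor and minimum prominence to exclude noise ripple.
#'
#' @param s Scaled signal (see [rescale_unit()]).
#' @param das Integer day axis aligned with `s`.
#' @param min_prominence Minimum scaled prominence of a peak (default 0.02).
#' @param min_height Minimum scaled height of a candidate peak (default 0.35,
#'   well above the dormant-baseline level of a scaled greenness series).
#' @param greenup_level Scaled level defining green-up onset (default 0.2).
#' @return List `das` (day of the peak or `NA`) and `reason` (`NA` or
#'   `"no_peak"`).
#' @export
detect_gp <- function(s, das, min_prominence = 0.02, min_height = 0.35,
                      greenup_level = 0.2) {
  onset <- which(s > greenup_level)[1]
  pk <- find_peaks(s, min_prominence, min_height)
  pk <- pk[!is.na(onset) & pk >= onset]
  if (length(pk) == 0L) return(list(das = NA_integer_, reason = "no_peak"))
  list(das = das[pk[1]], reason = NA_character_)
}

#' Detect the senescence peak
#'
#' Last qualifying local maximum of the scaled signal. For a unimodal signal
#' the single peak is both green peak and senescence peak; this degenerate
#' case is flagged.
#'
#' @inheritParams detect_gp
#' @param gp Day of the green peak (`NA` allowed).
#' @return List `das`, `reason` (`NA`, `"no_senescence_peak"`, or
#'   `"unimodal"` when SP coincides with GP).
#' @export
detect_sp <- function(s, das, gp = NA, min_prominence = 0.02, min_height = 0.35) {
  pk <- find_peaks(s, min_prominence, min_height)
  if (length(pk) == 0L)
    return(list(das = NA_integer_, reason = "no_senescence_peak"))
  d <- das[pk[length(pk)]]
  if (!is.na(gp) && d == gp) return(list(das = d, reason = "unimodal"))
  list(das = d, reason = NA_character_)
}

#' Detect the start of green-up
#'
#' First day before the green peak whose backward difference of the scaled
#' signal exceeds the slope threshold (default 0.015 per day) and which
#' lies on the rising envelope into the peak: the signal must not drop back
#' below the pre-crossing level before the green peak. The envelope
#' condition separates the start of the sustained green-up from transient
#' weather-driven rises of the dormant baseline, which can clear the slope
#' threshold but recede again.
#'
#' @inheritParams detect_gp
#' @param gp Day of the green peak (required).
#' @param sog_slope Scaled slope threshold (default 0.015, strict `>`).
#' @param edge_exclude Number of leading days skipped by the scan
#'   (default 3, half the smoothing window): at the series edge the
#'   smoother extrapolates its boundary polynomial, which inflates the
#'   slope variance and can trip the strict threshold spuriously.
#' @return List `das`, `reason` (`NA` or `"no_green_up"`).
#' @export
detect_sog <- function(s, das, gp, sog_slope = 0.015, edge_exclude = 3L) {
  if (is.na(gp)) return(list(das = NA_integer_, reason = "no_green_up"))
  i_gp <- match(gp, das)
  d1 <- c(NA, diff(s))
  hit <- which(d1 > sog_slope & das < gp & seq_along(s) > edge_exclude + 1L)
  for (i in hit) {
    # sustained rise: the signal must stay a threshold-worth above the
    # pre-crossing level all the way to the peak
    if (min(s[i:i_gp]) >= s[i - 1L] + sog_slope)
      return(list(das = das[i], reason = NA_character_))
  }
  list(das = NA_integer_, reason = "no_green_up")
}

#' Detect the end of senescence
#'
#' First day after the senescence peak, beyond the initial steep decline,
#' whose backward difference exceeds `eos_slope` (default -0.01, strict
#' `>`). The scan starts only once the signal has dropped `drop_guard`
#' (default 0.05 scaled) below the peak, so the flat top of the peak itself
#' cannot trigger. An alternative definition, the first local minimum after
#' the peak, is available via `method = "minimum"`.
#'
#' @inheritParams detect_gp
#' @param sp Day of the senescence peak (required).
#' @param eos_slope Scaled slope threshold (default -0.01).
#' @param drop_guard Required scaled drop below the peak before scanning
#'   (default 0.05).
#' @param method `"slope"` (default, the operative rule) or `"minimum"`.
#' @return List `das`, `reason` (`NA` or `"season_truncated"`).
#' @export
detect_eos <- function(s, das, sp, eos_slope = -0.01, drop_guard = 0.05,
                       method = c("slope", "minimum")) {
  method <- match.arg(method)
  if (is.na(sp)) return(list(das = NA_integer_, reason = "season_truncated"))
  i_sp <- match(sp, das)
  if (is.na(i_sp) || i_sp >= length(s))
    return(list(das = NA_integer_, reason = "season_truncated"))
  after <- (i_sp + 1L):length(s)
  dropped <- after[s[after] <= s[i_sp] - drop_guard]
  if (length(dropped) == 0L)
    return(list(das = NA_integer_, reason = "season_truncated"))
  start <- dropped[1]
  if (method == "minimum") {
    for (i in start:(length(s) - 1L)) {
      if (s[i] <= s[i - 1L] && s[i] < s[i + 1L])
        return(list(das = das[i], reason = NA_character_))
    }
    return(list(das = NA_integer_, reason = "season_truncated"))
  }
  d1 <- c(NA, diff(s))
  hit <- which(d1 > eos_slope & seq_along(s) >= start)
  if (length(hit) == 0L)
    return(list(das = NA_integer_, reason = "season_truncated"))
  list(das = das[hit[1]], reason = NA_character_)
}

#' Extract all four phenological time points for one plot
#'
#' Scales the smoothed signal to `[0, 1]` and applies the four detectors:
#' start of green-up (SOG), green peak (GP), senescence peak (SP) and end of
#' senescence (EOS). Points are extracted from the spatially uncorrected
#' per-plot signal; spatial correction of the resulting DAS values happens
#' downstream.
#'
#' @param das Integer day axis.
#' @param gcc_smooth Smoothed daily gcc for one plot.
#' @param config Named list of detector settings; see [pf_config()] keys
#'   `sog_slope`, `eos_slope`, `min_prominence`, `min_peak_height`,
#'   `greenup_level`, `eos_drop_guard`, `eos_method`.
#' @return One-row data frame `SOG`, `GP`, `SP`, `EOS` plus `reason_*`
#'   columns for missing points.
#' @export
extract_phenopoints <- function(das, gcc_smooth, config = pf_config()) {
  ok <- is.finite(gcc_smooth)
  das <- das[ok]; g <- gcc_smooth[ok]
  s <- rescale_unit(g)
  gp <- detect_gp(s, das, config$min_prominence, config$min_peak_height,
                  config$greenup_level)
  sp <- detect_sp(s, das, gp$das, config$min_prominence, config$min_peak_height)
  sog <- detect_sog(s, das, gp$das, config$sog_slope,
                    edge_exclude = (config$sg_window - 1L) %/% 2L)
  eos <- detect_eos(s, das, sp$das, config$eos_slope, config$eos_drop_guard,
                    config$eos_method)
  data.frame(SOG = sog$das, GP = gp$das, SP = sp$das, EOS = eos$das,
             reason_SOG = sog$reason, reason_GP = gp$reason,
             reason_SP = sp$reason, reason_EOS = eos$reason,
             stringsAsFactors = FALSE)
}

#' Extract phenological time points for every plot of a daily-signal table
#'
#' @param signals Output of [daily_signal()].
#' @param config See [extract_phenopoints()].
#' @return Data frame with `plot_id`, `SOG`, `GP`, `SP`, `EOS` and reason
#'   codes.
#' @export
phenopoints_all <- function(signals, config = pf_config()) {
  out <- lapply(split(signals, signals$plot_id), function(d) {
    d <- d[order(d$das), , drop = FALSE]
    cbind(plot_id = d$plot_id[1],
          extract_phenopoints(d$das, d$gcc_smooth, config))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Durations of phenological phases
#'
#' A phase duration is the difference in DAS between two time points
#' (later minus earlier); a missing endpoint gives a missing duration.
#'
#' @param points Data frame with columns `SOG`, `GP`, `SP`, `EOS` (and
#'   optionally `plot_id` or `genotype`, carried through).
#' @param pairs Character vector of `"LATER_EARLIER"` phase names (default
#'   the five phases used throughout: `GP_SOG`, `SP_SOG`, `SP_GP`, `EOS_SP`,
#'   `EOS_GP`).
#' @return Data frame of durations in days, one column per phase.
#' @export
compute_phases <- function(points,
                           pairs = c("GP_SOG", "SP_SOG", "SP_GP",
                                     "EOS_SP", "EOS_GP")) {
  keycols <- intersect(c("plot_id", "genotype"), names(points))
  out <- points[, keycols, drop = FALSE]
  for (p in pairs) {
    ab <- strsplit(p, "_", fixed = TRUE)[[1]]
    out[[p]] <- points[[ab[1]]] - points[[ab[2]]]
  }
  out
}
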