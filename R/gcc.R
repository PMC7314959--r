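#' Green chromatic coordinate of RGB pixels
#'
#' The green chromatic coordinate, `gcc = green / (green + red + blue)`, is
#' the standard PhenoCam greenness index: because it is a ratio of digital
#' numbers it is insensitive to a common rescaling of all three channels and
#' therefore robust to changing scene illumination and to uncalibrated
#' cameras.
#'
#' @param red,green,blue Numeric vectors of channel digital numbers (any
#'   common scale: 0–255, 0–65535 or 0–1). Recycled to a common length.
#' @return Numeric vector of gcc values in `[0, 1]`. Pixels whose channel sum
#'   is zero (or with any non-finite channel) are invalid and yield `NA`;
#'   they are excluded from plot statistics rather than raising an error.
#' @examples
#' compute_gcc(60, 120, 60)   # 0.5
#' compute_gcc(0, 255, 0)     # 1
#' @seealso [extract_plot_gcc()]
#' @export
compute_gcc <- function(red, green, blue) {
  s <- red + green + blue
  out <- green / s
  bad <- !is.finite(red) | !is.finite(green) | !is.finite(blue) | s <= 0
  out[bad] <- NA_real_
  out
}

#' Red and blue chromatic coordinates
#'
#' Companions of [compute_gcc()]; for any valid pixel the three chromatic
#' coordinates sum to one.
#' @inheritParams compute_gcc
#' @return Numeric vector in `[0, 1]`, `NA` for invalid pixels.
#' @export
compute_rcc <- function(red, green, blue) compute_gcc(green, red, blue)

#' @rdname compute_rcc
#' @export
compute_bcc <- function(red, green, blue) compute_gcc(red, blue, green)

#' Interquartile mean of pixel gcc values
#'
#' Averages the gcc values lying within the 25th to 75th percentile of the
#' distribution (bounds included; linear-interpolation percentiles). The
#' trim suppresses obstacle pixels such as platform cables or exposed soil.
#'
#' @param gcc Numeric vector of per-pixel gcc values; `NA`s are dropped.
#' @return Scalar interquartile mean, or `NA` if no valid pixel remains.
#' @keywords internal
iqr_mean <- function(gcc) {
  gcc <- gcc[is.finite(gcc)]
  if (length(gcc) == 0L) return(NA_real_)
  q <- stats::quantile(gcc, c(0.25, 0.75), names = FALSE, type = 7)
  keep <- gcc >= q[1] & gcc <= q[2]
  mean(gcc[keep])
}

#' Extract a robust plot-level gcc observation from one frame
#'
#' Computes per-pixel gcc inside a plot mask and returns the mean of the
#' values within the 25th–75th percentile of the mask's gcc distribution.
#'
#' @param image Numeric array `height x width x 3` (R, G, B), any DN scale.
#' @param mask Either an integer matrix with columns `x`, `y` of 0-based
#'   pixel coordinates, or a two-column data frame of the same; typically
#'   produced by [rasterize_mask()].
#' @param min_pixels Minimum number of valid pixels required (default 40,
#'   enough for the percentile trim to be meaningful); below it the
#'   observation is marked missing (`gcc = NA`).
#' @return A list with `gcc` (interquartile-mean gcc or `NA`) and
#'   `n_pixels_used` (count of valid pixels entering the statistic).
#' @export
extract_plot_gcc <- function(image, mask, min_pixels = 40L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  mask <- as.matrix(mask)
  h <- dim(image)[1]; w <- dim(image)[2]
  x <- mask[, 1] + 1L; y <- mask[, 2] + 1L   # 0-based -> R indices
  if (any(x < 1L | x > w | y < 1L | y > h))
    stop("mask extends outside image bounds")
  idx <- cbind(y, x)
  g <- compute_gcc(image[cbind(idx, 1L)], image[cbind(idx, 2L)], image[cbind(idx, 3L)])
  g <- g[is.finite(g)]
  if (length(g) < min_pixels)
    return(list(gcc = NA_real_, n_pixels_used = length(g)))
  list(gcc = iqr_mean(g), n_pixels_used = length(g))
}

#' Rasterize a plot polygon to pixel coordinates
#'
#' Even-odd-rule scan over the polygon bounding box. Coordinates follow the
#' image convention: `x` right, `y` down, 0-based; a pixel belongs to the
#' mask if its centre lies inside the polygon.
#'
#' @param polygon Two-column matrix/data frame of vertex `(x, y)` pixel
#'   coordinates (0-based, not closed).
#' @param width,height Image dimensions in pixels.
#' @return Integer matrix with columns `x`, `y` (0-based) of mask pixels.
#' @export
rasterize_mask <- function(polygon, width, height) {
  p <- as.matrix(polygon)
  stopifnot(ncol(p) == 2L, nrow(p) >= 3L)
  xr <- range(p[, 1]); yr <- range(p[, 2])
  xs <- max(0L, floor(xr[1])):min(width - 1L, ceiling(xr[2]))
  ys <- max(0L, floor(yr[1])):min(height - 1L, ceiling(yr[2]))
  if (length(xs) == 0L || length(ys) == 0L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- point_in_polygon(gx, gy, p)
  out <- cbind(x = gx[inside], y = gy[inside])
  storage.mode(out) <- "integer"
  out
}

# Vectorized even-odd (crossing number) point-in-polygon test.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read plot masks from a JSON file
#'
#' The JSON maps `plot_id` to a list of `[x, y]` polygon vertices in 0-based
#' pixel coordinates. Masks are static for the whole season (one
#' conservative mask per plot).
#'
#' @param path Path to the JSON mask file.
#' @param width,height Frame dimensions used to rasterize the polygons.
#' @param min_pixels Masks with fewer rasterized pixels raise an error
#'   (default 40).
#' @return Named list of 0-based `(x, y)` integer pixel matrices.
#' @export
read_masks <- function(path, width, height, min_pixels = 40L) {
  polys <- jsonlite::read_json(path, simplifyVector = TRUE)
  masks <- lapply(polys, function(p) rasterize_mask(as.matrix(p), width, height))
  small <- vapply(masks, nrow, 0L) < min_pixels
  if (any(small))
    stop("masks with fewer than ", min_pixels, " pixels: ",
         paste(names(masks)[small], collapse = ", "))
  masks
}

#' Parse frame timestamps from file names
#'
#' @param filenames Character vector of frame file names.
#' @param pattern `strftime`-style pattern locating the timestamp in the
#'   base name (default `"%Y%m%d_%H%M%S"`; leading/trailing non-digit text
#'   is stripped first).
#' @param tz Time zone of the camera clock (default `"UTC"`).
#' @return `POSIXct` vector; unparseable names give `NA` with a warning.
#' @export
parse_frame_time <- function(filenames, pattern = "%Y%m%d_%H%M%S", tz = "UTC") {
  base <- sub("\\.[A-Za-z]+$", "", basename(filenames))
  core <- gsub("^[^0-9]+|[^0-9]+$", "", base)
  ts <- as.POSIXct(strptime(core, pattern, tz = tz))
  if (anyNA(ts))
    warning("skipping frames with unparseable timestamps: ",
            paste(utils::head(filenames[is.na(ts)], 5L), collapse = ", "))
  ts
}

#' Days after sowing for a timestamp
#'
#' Integer day count: the calendar day of sowing is DAS 0.
#' @param timestamp `POSIXct` or `Date` vector.
#' @param sowing_date `Date` (or string) of sowing.
#' @return Integer vector of days after sowing.
#' @export
days_after_sowing <- function(timestamp, sowing_date) {
  as.integer(as.Date(timestamp, tz = attr(timestamp, "tzone") %||% "UTC") -
               as.Date(sowing_date))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter frames to usable day images
#'
#' Keeps frames whose local capture time falls inside a daylight window and
#' whose mean luminance exceeds a floor (lens faults and night exposures
#' yield near-black frames).
#'
#' @param timestamps `POSIXct` vector, one per frame; `NA` entries (failed
#'   parses) are dropped with a warning.
#' @param luminance Optional numeric vector of mean frame luminance on the
#'   8-bit DN scale (mean of the three channel means times 255 for unit-range
#'   images); `NULL` skips the luminance check.
#' @param window Length-2 numeric, daylight window in local hours
#'   (default `c(8, 18)`, inclusive).
#' @param luminance_floor Minimum mean luminance in 8-bit DN (default 20).
#' @return Logical vector: `TRUE` for retained frames.
#' @export
filter_day_images <- function(timestamps, luminance = NULL,
                              window = c(8, 18), luminance_floor = 20) {
  keep <- !is.na(timestamps)
  if (!all(keep)) warning(sum(!keep), " frame(s) skipped: unparseable timestamp")
  lt <- as.POSIXlt(timestamps)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  keep <- keep & hour >= window[1] & hour <= window[2]
  if (!is.null(luminance)) keep <- keep & !is.na(luminance) & luminance > luminance_floor
  keep
}

#' Mean luminance of a frame on the 8-bit scale
#' @param image Numeric array `h x w x 3` in `[0, 1]` (as read by
#'   [png::readPNG()]) or raw DN.
#' @return Scalar mean of the three channels, scaled to 0–255 when the input
#'   is unit-range.
#' @export
frame_luminance <- function(image) {
  m <- mean(image[, , 1:3])
  if (max(image[, , 1:3]) <= 1) m * 255 else m
}

#' Extract plot observations from a directory of frames
#'
#' Applies [filter_day_images()] and [extract_plot_gcc()] over all frames and
#' masks, yielding one row per retained frame and plot.
#'
#' @param image_dir Directory of PNG frames whose names carry timestamps.
#' @param masks Named list of pixel masks (see [read_masks()]).
#' @param sowing_date Sowing date (`Date` or string).
#' @param pattern,tz Passed to [parse_frame_time()].
#' @param window,luminance_floor Passed to [filter_day_images()].
#' @param min_pixels Passed to [extract_plot_gcc()].
#' @return Data frame with columns `plot_id`, `timestamp`, `das`, `gcc`,
#'   `n_pixels_used`.
#' @export
extract_observations <- function(image_dir, masks, sowing_date,
                                 pattern = "%Y%m%d_%H%M%S", tz = "UTC",
                                 window = c(8, 18), luminance_floor = 20,
                                 min_pixels = 40L) {
  files <- list.files(image_dir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0L) {
    warning("no frames found in ", image_dir)
    return(data.frame(plot_id = character(), timestamp = as.POSIXct(character()),
                      das = integer(), gcc = numeric(), n_pixels_used = integer()))
  }
  ts <- parse_frame_time(files, pattern, tz)
  ok <- !is.na(ts)
  files <- files[ok]; ts <- ts[ok]
  ord <- order(ts); files <- files[ord]; ts <- ts[ord]
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 2L) next   # greyscale frame: unusable
    keep <- filter_day_images(ts[i], frame_luminance(img), window, luminance_floor)
    if (!keep) next
    obs <- lapply(masks, function(m) extract_plot_gcc(img, m, min_pixels))
    rows[[i]] <- data.frame(
      plot_id = names(masks),
      timestamp = ts[i],
      das = days_after_sowing(ts[i], sowing_date),
      gcc = vapply(obs, `[[`, 0, "gcc"),
      n_pixels_used = vapply(obs, function(o) as.integer(o$n_pixels_used), 0L),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(plot_id = character(), timestamp = as.POSIXct(character()),
                      das = integer(), gcc = numeric(), n_pixels_used = integer())
  out
}
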