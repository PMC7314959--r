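#' Plot polygons for a rendered campaign canvas
#'
#' Lays the field grid out on the canvas: one rectangle per plot, inset a
#' few pixels from its grid cell so neighbouring masks never touch. With
#' the default 600 x 400 canvas and the 10 x 8 reference design each mask
#' holds roughly 2,500 pixels, within the 1,000-9,400 pixel range of a real
#' camera's plot masks.
#'
#' @param layout Field layout data frame (`plot_id`, `row`, `range_col`).
#' @param image_size `c(width, height)` in pixels.
#' @param inset Pixels trimmed from each cell edge (default 3).
#' @return Named list of 4 x 2 polygon vertex matrices (0-based `x`, `y`).
#' @export
plot_polygons <- function(layout, image_size = c(600L, 400L), inset = 3L) {
  w <- image_size[1]; h <- image_size[2]
  nc <- max(layout$range_col); nr <- max(layout$row)
  cw <- w / nc; ch <- h / nr
  if (cw - 2 * inset < 4 || ch - 2 * inset < 4)
    stop("canvas too small for the layout")
  polys <- lapply(seq_len(nrow(layout)), function(i) {
    x0 <- round((layout$range_col[i] - 1) * cw) + inset
    x1 <- round(layout$range_col[i] * cw) - inset - 1L
    y0 <- round((layout$row[i] - 1) * ch) + inset
    y1 <- round(layout$row[i] * ch) - inset - 1L
    if (x1 >= w || y1 >= h) stop("polygon outside canvas")
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  })
  stats::setNames(polys, layout$plot_id)
}

# Solve the green channel so the rendered colour has the requested gcc,
# holding red and blue fixed: green = gcc * (red + blue) / (1 - gcc).
gcc_to_rgb <- function(gcc, red = 0.30, blue = 0.20) {
  gcc <- pmin(0.9, pmax(0.05, gcc))
  green <- gcc * (red + blue) / (1 - gcc)
  cbind(red = red, green = pmin(1, green), blue = blue)
}

#' Render a campaign as PNG frames plus a mask file
#'
#' Draws every plot as a rectangle whose mean colour encodes its true daily
#' gcc (green channel solved from the gcc given fixed red and blue), over a
#' soil-coloured background, with per-pixel Gaussian channel noise, a shared
#' per-frame illumination offset, and optionally two dark cable stripes
#' crossing the field. Frame filenames carry the capture timestamp
#' (`frame_%Y%m%d_%H%M%S.png`); plot polygons are written as a JSON mask
#' file in the extractor's input format.
#'
#' @param campaign A [make_campaign()] result whose config has
#'   `render_images = TRUE` (or pass `force = TRUE`).
#' @param dir Output directory for frames and `masks.json`.
#' @param force Render even if the config disabled it.
#' @return Invisibly, a list with `frames` (paths), `masks_path`, and
#'   `polygons`.
#' @export
render_frames <- function(campaign, dir, force = FALSE) {
  cfg <- campaign$truth$config
  if (!isTRUE(cfg$render_images) && !force) {
    message("render_images is FALSE; nothing rendered")
    return(invisible(NULL))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1L)
  w <- cfg$image_size[1]; h <- cfg$image_size[2]
  lay <- campaign$layout
  polys <- plot_polygons(lay, cfg$image_size)
  masks <- lapply(polys, rasterize_mask, width = w, height = h)
  jsonlite::write_json(lapply(polys, function(p) unname(apply(p, 1, c,
                                                              simplify = FALSE))),
                       file.path(dir, "masks.json"), auto_unbox = FALSE,
                       digits = NA)
  # linear pixel indices per plot for each channel plane
  idx <- lapply(masks, function(m) (m[, 1]) * h + m[, 2] + 1L)
  soil <- c(0.33, 0.28, 0.20)
  cable_rows <- unique(pmin(h, pmax(1, round(c(0.22, 0.55) * h) + 0:1)))
  days <- as.integer(colnames(campaign$daily_true))
  sow <- as.Date(cfg$sowing_date)
  hours <- seq(cfg$day_window[1] + 1, cfg$day_window[2] - 1,
               length.out = cfg$frames_per_day)
  frames <- character(0)
  for (di in seq_along(days)) {
    d <- days[di]
    gccs <- campaign$daily_true[, di]
    for (fk in seq_len(cfg$frames_per_day)) {
      illum <- stats::rnorm(1, 0, cfg$illum_sd)
      img <- array(0, dim = c(h, w, 3))
      for (ch in 1:3) img[, , ch] <- soil[ch]
      cols <- gcc_to_rgb(gccs + illum)
      for (i in seq_along(idx)) {
        for (ch in 1:3) {
          plane <- (ch - 1L) * h * w
          img[plane + idx[[i]]] <- cols[i, ch]
        }
      }
      img[cable_rows, , 1] <- 0.06
      img[cable_rows, , 2] <- 0.01
      img[cable_rows, , 3] <- 0.05
      img <- img + stats::rnorm(length(img), 0, cfg$pixel_noise_sd)
      img <- pmin(pmax(img, 0), 1)   # order keeps the array dims
      hh <- floor(hours[fk]); mm <- round((hours[fk] - hh) * 60)
      ts <- sprintf("%s_%02d%02d00", format(sow + d, "%Y%m%d"), hh, mm)
      path <- file.path(dir, sprintf("frame_%s.png", ts))
      png::writePNG(img, path)
      frames <- c(frames, path)
    }
  }
  invisible(list(frames = frames, masks_path = file.path(dir, "masks.json"),
                 polygons = polys))
}
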