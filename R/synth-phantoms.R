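#' Configuration for a synthetic section image
#'
#' Describes a two-structure phantom for morphometry: a tectorial-membrane
#' ROI above the organ of Corti, separated from the organ surface
#' (reticular lamina) by a configurable gap. ROI corners are placed on
#' half-integer pixel boundaries so that the pixel-centre count of each
#' rectangle is exact.
#'
#' @param image_shape c(rows, cols) in pixels
#' @param pixel_size um per pixel
#' @param gap_true um (>= 0); 0 produces touching structures
#' @param tm_area_true um^2 (> 0)
#' @param ooc_area_true um^2 (> 0)
#' @param ooc_width_true um (> 0)
#' @param noise_sd intensity units of additive Gaussian image noise
#' @param seed integer RNG seed
#' @return object of class `section_phantom_config`
#' @export
section_phantom_config <- function(image_shape = c(256, 256),
                                   pixel_size = 0.5, gap_true = 6,
                                   tm_area_true = 2000,
                                   ooc_area_true = 3000,
                                   ooc_width_true = 90,
                                   noise_sd = 50, seed = 1L) {
  stopifnot(gap_true >= 0, tm_area_true > 0, ooc_area_true > 0,
            ooc_width_true > 0, pixel_size > 0, noise_sd >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, gap_true = gap_true,
                 tm_area_true = tm_area_true,
                 ooc_area_true = ooc_area_true,
                 ooc_width_true = ooc_width_true,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "section_phantom_config")
}

#' Render a synthetic section image with ROIs
#'
#' Builds the phantom described by a [section_phantom_config()]: a 16-bit
#' image with two labelled structures, the TM and OoC ROI polygons, the
#' reticular-lamina polyline (the OoC upper boundary) and the organ-width
#' measurement segment, plus the ground truth every measurement should
#' recover.
#'
#' @param config a [section_phantom_config()]
#' @return list with `image` (integer matrix, rows x cols), `geometry`
#'   (a [section_geometry()]), and `truth` (gap/areas/width in um)
#' @export
#' @examples
#' ph <- render_section_phantom(section_phantom_config(seed = 7))
#' measure_section(ph$geometry)
render_section_phantom <- function(config) {
  stopifnot(inherits(config, "section_phantom_config"))
  set.seed(config$seed)
  ps <- config$pixel_size
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  gap_px <- config$gap_true / ps

  # OoC rectangle: integer pixel width, fractional height for exact area
  ooc_w <- round(config$ooc_width_true / ps)
  ooc_h <- config$ooc_area_true / ps^2 / ooc_w
  # TM rectangle: a wide slab, width 1.5x its height
  tm_area_px <- config$tm_area_true / ps^2
  tm_w <- round(sqrt(1.5 * tm_area_px))
  tm_h <- tm_area_px / tm_w

  x0_ooc <- round((nc - ooc_w) / 2) - 0.5
  x0_tm <- round((nc - tm_w) / 2) - 0.5
  y_lam <- round(nr * 0.55) - 0.5           # reticular lamina (OoC top)
  y_tm_bot <- y_lam - gap_px                # TM lower boundary
  y_tm_top <- y_tm_bot - tm_h
  if (y_tm_top < 1 || y_lam + ooc_h > nr - 2 ||
      x0_tm < 1 || x0_tm + tm_w > nc - 2 ||
      x0_ooc < 1 || x0_ooc + ooc_w > nc - 2)
    stop("structures do not fit inside the image")

  rect <- function(x0, y0, w, h)
    cbind(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
  tm_roi <- rect(x0_tm, y_tm_top, tm_w, tm_h)
  ooc_roi <- rect(x0_ooc, y_lam, ooc_w, ooc_h)
  lamina <- cbind(x = c(x0_ooc, x0_ooc + ooc_w), y = c(y_lam, y_lam))
  width_line <- cbind(x = c(x0_ooc, x0_ooc + ooc_w),
                      y = rep(y_lam + ooc_h / 2, 2))

  if (config$gap_true > 0 &&
      min_gap(tm_roi, lamina, ps) <= 0)
    stop("internal failure: structures overlap despite gap_true > 0")

  # render: pixel-centre masks + Gaussian noise, 16-bit
  cx <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  cy <- matrix(rep(0:(nr - 1), nc), nr, nc)
  img <- matrix(200, nr, nc)
  in_tm <- matrix(points_in_polygon(as.vector(cx), as.vector(cy), tm_roi),
                  nr, nc)
  in_ooc <- matrix(points_in_polygon(as.vector(cx), as.vector(cy), ooc_roi),
                   nr, nc)
  img[in_tm] <- 12000
  img[in_ooc] <- 20000
  img <- img + rnorm(nr * nc, sd = config$noise_sd)
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)), nr, nc)

  geom <- section_geometry(tm_roi, ooc_roi, reticular_lamina = lamina,
                           width_line = width_line, pixel_size = ps)
  list(image = img, geometry = geom,
       truth = list(gap = config$gap_true,
                    tm_area = tm_w * tm_h * ps^2,
                    ooc_area = ooc_w * ooc_h * ps^2,
                    ooc_width = ooc_w * ps,
                    seed = config$seed))
}
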