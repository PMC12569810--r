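#' Section geometry: ROIs and reference lines for one cochlear section
#'
#' Coordinates are continuous pixel coordinates (0-based, `x` = column,
#' `y` = row; pixel centres at integer coordinates). Polygons are closed
#' implicitly (last vertex joins the first) and must be simple.
#'
#' @param tm_roi tectorial-membrane polygon, matrix/data.frame with columns
#'   `x`, `y`
#' @param ooc_roi organ-of-Corti polygon
#' @param reticular_lamina open polyline tracing the surface of the hearing
#'   organ (optional; the upper boundary of `ooc_roi` is used when absent)
#' @param basilar_membrane optional open polyline
#' @param width_line optional 2x2 matrix (two endpoints) of the organ-width
#'   measurement segment
#' @param pixel_size um per pixel (> 0)
#' @return object of class `section_geometry`
#' @export
section_geometry <- function(tm_roi, ooc_roi, reticular_lamina = NULL,
                             basilar_membrane = NULL, width_line = NULL,
                             pixel_size = 1) {
  as_xy <- function(p, nm) {
    if (is.null(p)) return(NULL)
    p <- as.matrix(as.data.frame(p)[, 1:2])
    colnames(p) <- c("x", "y")
    if (nrow(p) < 2) stop(nm, " needs at least 2 vertices")
    p
  }
  tm_roi <- as_xy(tm_roi, "tm_roi"); ooc_roi <- as_xy(ooc_roi, "ooc_roi")
  if (nrow(tm_roi) < 3 || nrow(ooc_roi) < 3)
    stop("ROI polygons need at least 3 vertices")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  for (nm in c("tm_roi", "ooc_roi")) {
    p <- get(nm)
    if (polygon_self_intersects(p)) stop(nm, " is self-intersecting")
  }
  structure(list(tm_roi = tm_roi, ooc_roi = ooc_roi,
                 reticular_lamina = as_xy(reticular_lamina,
                                          "reticular_lamina"),
                 basilar_membrane = as_xy(basilar_membrane,
                                          "basilar_membrane"),
                 width_line = as_xy(width_line, "width_line"),
                 pixel_size = pixel_size),
            class = "section_geometry")
}

# closed-polygon edge list as segment endpoint matrices (p1 -> p2)
polygon_edges <- function(poly) {
  n <- nrow(poly)
  list(p1 = poly, p2 = poly[c(2:n, 1), , drop = FALSE])
}

polyline_edges <- function(line) {
  n <- nrow(line)
  list(p1 = line[-n, , drop = FALSE], p2 = line[-1, , drop = FALSE])
}

# do segments (p1,p2) and (q1,q2) properly or improperly intersect?
segments_intersect <- function(p1, p2, q1, q2, eps = 1e-12) {
  d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  on_seg <- function(a, b, c)
    min(a[1], b[1]) - eps <= c[1] && c[1] <= max(a[1], b[1]) + eps &&
    min(a[2], b[2]) - eps <= c[2] && c[2] <= max(a[2], b[2]) + eps
  (abs(d1) <= eps && on_seg(q1, q2, p1)) ||
    (abs(d2) <= eps && on_seg(q1, q2, p2)) ||
    (abs(d3) <= eps && on_seg(p1, p2, q1)) ||
    (abs(d4) <= eps && on_seg(p1, p2, q2))
}

polygon_self_intersects <- function(poly) {
  e <- polygon_edges(poly)
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next   # closing edge shares a vertex with edge 1
      if (segments_intersect(e$p1[i, ], e$p2[i, ], e$p1[j, ], e$p2[j, ]))
        return(TRUE)
    }
  }
  FALSE
}

# even-odd (ray crossing) point-in-polygon test, vectorised over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' ROI area by pixel counting
#'
#' Area is the number of pixels whose centres fall inside the polygon,
#' times the squared pixel size — the same rule used when outlining
#' structures on section images. (The continuous shoelace area is the test
#' oracle, not the measurement.)
#'
#' @param roi simple polygon (columns `x`, `y`, pixel coordinates)
#' @param pixel_size um per pixel
#' @return area in um^2
#' @export
#' @examples
#' rect <- cbind(x = c(0, 100, 100, 0) - 0.5, y = c(0, 0, 50, 50) - 0.5)
#' roi_area(rect, pixel_size = 0.5)  # 100 x 50 px at 0.5 um/px -> 1250 um^2
roi_area <- function(roi, pixel_size) {
  roi <- as.matrix(as.data.frame(roi)[, 1:2])
  if (nrow(roi) < 3) stop("polygon needs at least 3 vertices")
  if (polygon_self_intersects(roi)) stop("self-intersecting polygon")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  xr <- range(roi[, 1]); yr <- range(roi[, 2])
  gx <- seq(floor(xr[1]), ceiling(xr[2]))
  gy <- seq(floor(yr[1]), ceiling(yr[2]))
  gr <- expand.grid(x = gx, y = gy)
  sum(points_in_polygon(gr$x, gr$y, roi)) * pixel_size^2
}

# minimum distance between two segments (a1,a2) and (b1,b2)
segment_segment_distance <- function(a1, a2, b1, b2) {
  if (segments_intersect(a1, a2, b1, b2)) return(0)
  pt_seg <- function(p, s1, s2) {
    v <- s2 - s1; L2 <- sum(v^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - s1) * v) / L2))
    sqrt(sum((s1 + t * v - p)^2))
  }
  min(pt_seg(a1, b1, b2), pt_seg(a2, b1, b2),
      pt_seg(b1, a1, a2), pt_seg(b2, a1, a2))
}

# min distance between two edge sets (lists with p1, p2 matrices)
edge_set_distance <- function(ea, eb) {
  best <- Inf
  for (i in seq_len(nrow(ea$p1))) {
    a1 <- ea$p1[i, ]; a2 <- ea$p2[i, ]
    for (j in seq_len(nrow(eb$p1))) {
      d <- segment_segment_distance(a1, a2, eb$p1[j, ], eb$p2[j, ])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

#' Minimal gap between the tectorial membrane and the organ surface
#'
#' Shortest Euclidean distance between the boundary of the
#' tectorial-membrane ROI (all edges, not just vertices) and the surface
#' polyline of the hearing organ (reticular lamina). Returns 0 when the
#' structures touch or intersect; penetration is not reported as negative.
#'
#' @param tm_roi TM polygon (columns `x`, `y`)
#' @param surface open polyline (columns `x`, `y`)
#' @param pixel_size um per pixel
#' @return gap in um (>= 0)
#' @export
#' @examples
#' tm <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 5, 5))
#' lam <- cbind(x = c(-5, 15), y = c(11, 11))
#' min_gap(tm, lam, pixel_size = 0.5)   # 6 px -> 3 um
min_gap <- function(tm_roi, surface, pixel_size) {
  tm_roi <- as.matrix(as.data.frame(tm_roi)[, 1:2])
  surface <- as.matrix(as.data.frame(surface)[, 1:2])
  if (nrow(tm_roi) < 3) stop("tm_roi degenerate: need a polygon")
  if (nrow(surface) < 2) stop("surface degenerate: need a polyline")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  # TM interior covering the surface also counts as contact
  if (any(points_in_polygon(surface[, 1], surface[, 2], tm_roi)))
    return(0)
  d <- edge_set_distance(polygon_edges(tm_roi), polyline_edges(surface))
  d * pixel_size
}

#' Width of the organ of Corti
#'
#' Length of the measurement segment drawn parallel to the basilar
#' membrane. When no explicit segment is given, the longest chord of the
#' OoC ROI parallel to a reference direction (the basilar membrane, or
#' horizontal) is used.
#'
#' @param width_line 2x2 matrix of segment endpoints (pixel coords), or
#'   `NULL`
#' @param ooc_roi fallback polygon used when `width_line` is missing
#' @param pixel_size um per pixel
#' @param direction reference direction in radians for the fallback chord
#'   (default 0 = horizontal)
#' @return width in um
#' @export
#' @examples
#' ooc_width(width_line = rbind(c(0, 0), c(100, 0)), pixel_size = 0.5)
ooc_width <- function(width_line = NULL, ooc_roi = NULL, pixel_size = 1,
                      direction = 0) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (!is.null(width_line)) {
    width_line <- as.matrix(as.data.frame(width_line)[, 1:2])
    stopifnot(nrow(width_line) == 2)
    return(sqrt(sum((width_line[2, ] - width_line[1, ])^2)) * pixel_size)
  }
  if (is.null(ooc_roi)) stop("provide width_line or ooc_roi")
  roi <- as.matrix(as.data.frame(ooc_roi)[, 1:2])
  # longest chord parallel to `direction`: rotate, scan rows of a fine grid
  R <- matrix(c(cos(direction), -sin(direction),
                sin(direction), cos(direction)), 2, 2)
  rot <- roi %*% R
  yr <- range(rot[, 2]); xr <- range(rot[, 1])
  ys <- seq(yr[1], yr[2], length.out = 200)
  xs <- seq(xr[1], xr[2], length.out = 400)
  gr <- expand.grid(x = xs, y = ys)
  inside <- points_in_polygon(gr$x, gr$y, rot)
  if (!any(inside)) return(0)
  widths <- tapply(gr$x[inside], gr$y[inside],
                   function(v) diff(range(v)))
  max(widths) * pixel_size
}

#' One section's morphometric measurements
#'
#' @param gap um; `tm_area`, `ooc_area` um^2; `ooc_width` um
#' @param tm_area,ooc_area,ooc_width see above
#' @param location_index apical location index within the cochlea
#' @param cochlea_id identifier of the cochlea the section comes from
#' @return object of class `section_measurement` (also a data.frame row)
#' @export
section_measurement <- function(gap, tm_area, ooc_area, ooc_width,
                                location_index = 1L, cochlea_id = "c1") {
  stopifnot(gap >= 0, tm_area >= 0, ooc_area >= 0, ooc_width >= 0)
  structure(data.frame(cochlea_id = cochlea_id,
                       location_index = as.integer(location_index),
                       gap = gap, tm_area = tm_area, ooc_area = ooc_area,
                       ooc_width = ooc_width, stringsAsFactors = FALSE),
            class = c("section_measurement", "data.frame"))
}

#' Measure a full section geometry
#'
#' Convenience wrapper running [min_gap()], [roi_area()] and [ooc_width()]
#' on one [section_geometry()].
#'
#' @param geom a [section_geometry()]
#' @param location_index,cochlea_id passed to [section_measurement()]
#' @return a [section_measurement()]
#' @export
measure_section <- function(geom, location_index = 1L, cochlea_id = "c1") {
  stopifnot(inherits(geom, "section_geometry"))
  surface <- geom$reticular_lamina
  if (is.null(surface)) {
    # human sections: use the upper boundary of the OoC ROI as the surface
    roi <- geom$ooc_roi
    surface <- roi[order(roi[, 1]), , drop = FALSE]
    keep <- !duplicated(surface[, 1])
    surface <- surface[keep, , drop = FALSE]
    ymin <- tapply(geom$ooc_roi[, 2], geom$ooc_roi[, 1], min)
    surface <- cbind(x = as.numeric(names(ymin)), y = as.numeric(ymin))
    surface <- surface[order(surface[, 1]), , drop = FALSE]
  }
  section_measurement(
    gap = min_gap(geom$tm_roi, surface, geom$pixel_size),
    tm_area = roi_area(geom$tm_roi, geom$pixel_size),
    ooc_area = roi_area(geom$ooc_roi, geom$pixel_size),
    ooc_width = ooc_width(geom$width_line, geom$ooc_roi, geom$pixel_size),
    location_index = location_index, cochlea_id = cochlea_id)
}

#' Average the measurements of one cochlea
#'
#' The apical locations measured in each cochlea are averaged
#' (arithmetic mean per quantity) and the averaged value is what enters
#' statistical analysis.
#'
#' @param measurements a data.frame of section measurements (rows from
#'   [section_measurement()]) for a single cochlea
#' @return a one-row data.frame with the per-cochlea means and `n_locations`
#' @export
per_cochlea_average <- function(measurements) {
  m <- as.data.frame(measurements)
  if (nrow(m) < 1) stop("need at least one measurement")
  if (length(unique(m$cochlea_id)) != 1)
    stop("mixed cochlea_ids; average one cochlea at a time")
  out <- data.frame(cochlea_id = m$cochlea_id[1],
                    gap = mean(m$gap), tm_area = mean(m$tm_area),
                    ooc_area = mean(m$ooc_area),
                    ooc_width = mean(m$ooc_width),
                    n_locations = nrow(m), stringsAsFactors = FALSE)
  out
}

#' Flag tectorial-membrane detachment
#'
#' A cochlea is flagged as detached when its measured gap exceeds the
#' threshold. The default threshold of 0 um flags any measurable gap,
#' matching the convention that control animals "had no measurable gap".
#'
#' @param measurement a row with a `gap` column (um), or a numeric gap
#' @param threshold um (default 0)
#' @return logical
#' @export
#' @examples
#' detachment_flag(0)     # FALSE
#' detachment_flag(6)     # TRUE
detachment_flag <- function(measurement, threshold = 0) {
  gap <- if (is.numeric(measurement)) measurement else measurement$gap
  if (any(is.na(gap))) stop("gap not measured")
  gap > threshold
}
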