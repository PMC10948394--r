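#' Measure geometric and intensity features of segmented ROIs
#'
#' Computes, for every labeled region, the seven features the NET caller
#' consumes: area, raw integrated density (sum of member-pixel intensities,
#' the proxy for total DNA content), aspect ratio and roundness from the
#' moment-fitted ellipse, solidity, and minimum/maximum brightness, plus the
#' centroid and a border flag.
#'
#' Ellipse axes come from the eigenvalues of the second central moment matrix
#' of the pixel coordinates with a `+1/12` per-pixel extent correction (the
#' variance of a unit square), so single pixels and straight lines remain
#' well-defined. With eigenvalues `l1 >= l2`, `major = 4*sqrt(l1)`,
#' `minor = 4*sqrt(l2)`, `aspect_ratio = major/minor`, and
#' `roundness = 4*area / (pi * major^2)` (the ImageJ definition). On tiny
#' discrete regions roundness may exceed 1 by up to ~0.05. Solidity is
#' `area / convex_hull_area` and never exceeds 1.
#'
#' @param field A [net_field].
#' @param labels Integer label matrix from [label_components()] or
#'   [segment_field()].
#' @return A tibble with one row per ROI: `slide_id`, `condition`,
#'   `field_index`, `roi_id`, `area_px`, `raw_integrated_density`,
#'   `aspect_ratio`, `roundness`, `solidity`, `min_brightness`,
#'   `max_brightness`, `touches_border`, `centroid_row`, `centroid_col`.
#'   Coordinates are 1-based matrix indices.
#' @export
measure_rois <- function(field, labels) {
  stopifnot(inherits(field, "net_field"))
  if (!identical(dim(field$pixels), dim(labels))) {
    stop("label map shape does not match image shape", call. = FALSE)
  }
  n <- max(labels)
  if (n == 0L) return(empty_measurements())
  fg <- which(labels > 0L)
  lab_fg <- as.integer(labels[fg])
  int_fg <- as.numeric(field$pixels[fg])
  nr <- nrow(labels)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  on_border <- rows == 1L | rows == nr | cols == 1L | cols == ncol(labels)

  area <- tabulate(lab_fg, nbins = n)
  rid <- as.numeric(rowsum(int_fg, lab_fg))
  minb <- unname(vapply(split(int_fg, lab_fg), min, numeric(1)))
  maxb <- unname(vapply(split(int_fg, lab_fg), max, numeric(1)))
  touches <- as.numeric(rowsum(as.numeric(on_border), lab_fg)) > 0
  crow <- as.numeric(rowsum(as.numeric(rows), lab_fg)) / area
  ccol <- as.numeric(rowsum(as.numeric(cols), lab_fg)) / area

  # second central moments with pixel-extent correction
  srr <- as.numeric(rowsum(as.numeric(rows)^2, lab_fg)) / area - crow^2 + 1 / 12
  scc <- as.numeric(rowsum(as.numeric(cols)^2, lab_fg)) / area - ccol^2 + 1 / 12
  src <- as.numeric(rowsum(as.numeric(rows) * cols, lab_fg)) / area - crow * ccol
  tr <- srr + scc
  det <- srr * scc - src^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 1e-12)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)

  pix_by_roi <- split(data.frame(row = rows, col = cols), lab_fg)
  hull_area <- unname(vapply(pix_by_roi, function(d) {
    convex_hull_area(cbind(d$row, d$col))
  }, numeric(1)))

  tibble::tibble(
    slide_id = field$slide_id,
    condition = field$condition,
    field_index = field$field_index,
    roi_id = seq_len(n),
    area_px = as.integer(area),
    raw_integrated_density = rid,
    aspect_ratio = major / minor,
    roundness = 4 * area / (pi * major^2),
    solidity = pmin(area / hull_area, 1),
    min_brightness = minb,
    max_brightness = maxb,
    touches_border = touches,
    centroid_row = crow,
    centroid_col = ccol
  )
}

empty_measurements <- function() {
  tibble::tibble(
    slide_id = character(0), condition = character(0),
    field_index = integer(0), roi_id = integer(0), area_px = integer(0),
    raw_integrated_density = numeric(0), aspect_ratio = numeric(0),
    roundness = numeric(0), solidity = numeric(0), min_brightness = numeric(0),
    max_brightness = numeric(0), touches_border = logical(0),
    centroid_row = numeric(0), centroid_col = numeric(0)
  )
}

#' Convex hull area of a pixel set
#'
#' Area of the convex hull of a set of pixels, measured as the number of
#' pixels whose centers lie inside or on the hull polygon of the member pixel
#' centers (the rasterized "convex image" convention). Under this convention
#' a filled convex region has hull area equal to its pixel count, so solidity
#' is exactly 1 there and never exceeds 1 elsewhere. Degenerate sets (fewer
#' than 3 non-collinear pixels) have hull area defined as the pixel count.
#'
#' @param pixels Two-column matrix of (row, col) pixel coordinates.
#' @return Hull area in pixels (a real number).
#' @export
convex_hull_area <- function(pixels) {
  pixels <- unique(as.matrix(pixels))
  n <- nrow(pixels)
  if (n < 3L) return(as.numeric(n))
  h <- grDevices::chull(pixels[, 2L], pixels[, 1L])  # x = col, y = row
  if (length(h) < 3L) return(as.numeric(n))  # collinear
  hull <- pixels[h, , drop = FALSE]
  rr <- seq(min(pixels[, 1L]), max(pixels[, 1L]))
  cc <- seq(min(pixels[, 2L]), max(pixels[, 2L]))
  grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  sum(points_in_convex_polygon(grid, hull))
}

# vectorized point-in-convex-polygon test (boundary inclusive)
points_in_convex_polygon <- function(pts, hull, tol = 1e-9) {
  nh <- nrow(hull)
  nxt <- c(seq_len(nh)[-1L], 1L)
  inside <- rep(TRUE, nrow(pts))
  # chull returns vertices clockwise in (x, y); with (row, col) ordering the
  # sign of the cross product is consistent per polygon, so orient first
  area2 <- 0
  for (i in seq_len(nh)) {
    j <- nxt[i]
    area2 <- area2 + hull[i, 2L] * hull[j, 1L] - hull[j, 2L] * hull[i, 1L]
  }
  s <- sign(area2)
  if (s == 0) s <- 1
  for (i in seq_len(nh)) {
    j <- nxt[i]
    # cross product in (x = col, y = row) space, matching the orientation sign
    cross <- (hull[j, 2L] - hull[i, 2L]) * (pts[, 1L] - hull[i, 1L]) -
             (hull[j, 1L] - hull[i, 1L]) * (pts[, 2L] - hull[i, 2L])
    inside <- inside & (s * cross >= -tol)
  }
  inside
}
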