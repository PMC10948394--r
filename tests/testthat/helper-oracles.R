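# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own implementations: per-pixel loops, explicit
# recursion-free flood fill, and all-pairs geometry.

# naive per-pixel Phansalkar threshold with replicated edge padding
oracle_phansalkar <- function(pixels, radius = 15L, k = 0.25, r = 0.5,
                              p = 2.0, q = 10.0, bit_depth = 8L) {
  x <- pixels / (2^bit_depth - 1)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax((i - radius):(i + radius), 1L), nr)
      rj <- pmin(pmax((j - radius):(j + radius), 1L), nc)
      w <- x[ri, rj]
      m <- mean(w)
      s <- sqrt(mean((w - m)^2))
      t <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
      out[i, j] <- x[i, j] > t
    }
  }
  out
}

# exhaustive intermodes oracle: rebuilds the histogram, smooths step by step
# with a mode-count check at every iteration
oracle_intermodes <- function(pixels, n_bins = 256L, max_iters = 10000L) {
  v <- as.numeric(pixels)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant")
  width <- (hi - lo) / n_bins
  idx <- pmin(pmax(floor((v - lo) / width) + 1, 1L), n_bins)
  h <- as.numeric(tabulate(idx, nbins = n_bins))
  centers <- lo + (seq_len(n_bins) - 0.5) * width
  count_modes <- function(h) {
    n <- length(h)
    sum(h > c(0, h[-n]) & h > c(h[-1L], 0))
  }
  it <- 0L
  while (count_modes(h) != 2L) {
    if (count_modes(h) < 2L || it >= max_iters) stop("not bimodal")
    n <- length(h)
    h <- (c(0, h[-n]) + h + c(h[-1L], 0)) / 3
    it <- it + 1L
  }
  n <- length(h)
  modes <- which(h > c(0, h[-n]) & h > c(h[-1L], 0))
  mean(centers[modes])
}

# queue-based flood fill component count
oracle_component_pixel_sets <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  comps <- list()
  for (start in which(mask & !seen)) {
    i0 <- ((start - 1) %% nr) + 1; j0 <- ((start - 1) %/% nr) + 1
    if (seen[i0, j0]) next
    queue <- matrix(c(i0, j0), ncol = 2)
    seen[i0, j0] <- TRUE
    members <- integer(0)
    while (nrow(queue) > 0) {
      pt <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      members <- c(members, (pt[2] - 1) * nr + pt[1])
      for (o in seq_len(nrow(offs))) {
        ni <- pt[1] + offs[o, 1]; nj <- pt[2] + offs[o, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# brute-force convex hull area over pixel centers: counts lattice points
# inside the hull by testing every candidate against every supporting
# half-plane derived from all point pairs
oracle_hull_area <- function(pixels) {
  pixels <- unique(as.matrix(pixels))
  n <- nrow(pixels)
  if (n < 3L) return(as.numeric(n))
  rr <- seq(min(pixels[, 1]), max(pixels[, 1]))
  cc <- seq(min(pixels[, 2]), max(pixels[, 2]))
  grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  in_hull <- rep(TRUE, nrow(grid))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d <- pixels[b, ] - pixels[a, ]
      if (all(d == 0)) next
      side <- (grid[, 1] - pixels[a, 1]) * d[2] - (grid[, 2] - pixels[a, 2]) * d[1]
      ref <- (pixels[, 1] - pixels[a, 1]) * d[2] - (pixels[, 2] - pixels[a, 2]) * d[1]
      # (a, b) is a hull edge if all points lie on one side
      if (all(ref >= -1e-9)) in_hull <- in_hull & (side >= -1e-9)
      if (all(ref <= 1e-9)) in_hull <- in_hull & (side <= 1e-9)
    }
  }
  sum(in_hull)
}

# rasterize a filled disk / ellipse as a logical matrix
raster_ellipse <- function(nr, nc, cy, cx, a_row, b_col, angle = 0) {
  co <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dy <- co$row - cy; dx <- co$col - cx
  u <- dy * cos(angle) + dx * sin(angle)
  v <- -dy * sin(angle) + dx * cos(angle)
  matrix((u / a_row)^2 + (v / b_col)^2 <= 1, nr, nc)
}

# small constructed field wrapper
make_field <- function(pixels, bit_depth = 8L, ...) {
  net_field(pixels, bit_depth = bit_depth, slide_id = "T", condition = "test",
            field_index = 1L, ...)
}

# measurements tibble for calling-logic tests that bypass segmentation
make_measurements <- function(area, rid = NULL, border = FALSE) {
  n <- length(area)
  tibble::tibble(
    slide_id = "T", condition = "test", field_index = 1L,
    roi_id = seq_len(n), area_px = as.integer(area),
    raw_integrated_density = if (is.null(rid)) area * 100 else rid,
    aspect_ratio = 1, roundness = 1, solidity = 1,
    min_brightness = 50, max_brightness = 150,
    touches_border = rep_len(border, n),
    centroid_row = 10, centroid_col = 10
  )
}
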