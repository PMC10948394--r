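#' Global intermodes histogram threshold
#'
#' Builds an equal-width intensity histogram over the observed range, smooths
#' it with a 3-bin running mean until exactly two local maxima survive, and
#' returns the midpoint of the two surviving mode bin centers. Foreground is
#' defined as pixels strictly greater than the threshold.
#'
#' Some histograms never become bimodal (a constant image is the extreme
#' case). By default this raises an error rather than silently guessing a
#' threshold, because an arbitrary threshold on an empty field would bias the
#' NET percentage; set `on_unimodal = "otsu_fallback"` to fall back to Otsu's
#' method on the same histogram.
#'
#' @param pixels Numeric matrix (or vector) of intensities, or a [net_field].
#' @param n_bins Number of histogram bins (default 256).
#' @param max_smooth_iters Iteration cap for the smoothing loop.
#' @param on_unimodal `"error"` (default) or `"otsu_fallback"`.
#' @return The threshold as a single real number.
#' @export
intermodes_threshold <- function(pixels, n_bins = 256L, max_smooth_iters = 10000L,
                                 on_unimodal = c("error", "otsu_fallback")) {
  on_unimodal <- match.arg(on_unimodal)
  if (inherits(pixels, "net_field")) pixels <- pixels$pixels
  v <- as.numeric(pixels)
  if (length(v) == 0L) stop("empty intensity matrix", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    return(unimodal_outcome(on_unimodal, v, lo, hi, iters = 0L,
                            reason = "constant image"))
  }
  width <- (hi - lo) / n_bins
  idx <- pmin(pmax(floor((v - lo) / width) + 1, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * width
  h <- as.numeric(counts)
  iters <- 0L
  repeat {
    modes <- local_maxima(h)
    if (length(modes) == 2L) {
      return((centers[modes[1L]] + centers[modes[2L]]) / 2)
    }
    if (length(modes) < 2L || iters >= max_smooth_iters) {
      return(unimodal_outcome(on_unimodal, v, lo, hi, iters = iters,
                              reason = if (length(modes) < 2L) "histogram is unimodal"
                                       else "smoothing iteration cap reached",
                              counts = counts, centers = centers))
    }
    h <- smooth3(h)
    iters <- iters + 1L
  }
}

# strict local maxima of a histogram, zero-padded at both ends
local_maxima <- function(h) {
  n <- length(h)
  left <- c(0, h[-n]); right <- c(h[-1L], 0)
  which(h > left & h > right)
}

smooth3 <- function(h) {
  n <- length(h)
  (c(0, h[-n]) + h + c(h[-1L], 0)) / 3
}

unimodal_outcome <- function(on_unimodal, v, lo, hi, iters, reason,
                             counts = NULL, centers = NULL) {
  if (on_unimodal == "error") {
    stop("intermodes threshold failed after ", iters,
         " smoothing iteration(s): ", reason, call. = FALSE)
  }
  if (hi <= lo) {
    stop("intermodes/otsu threshold undefined for a constant image", call. = FALSE)
  }
  otsu_threshold(counts, centers)
}

# Otsu's between-class-variance maximizer on a precomputed histogram
otsu_threshold <- function(counts, centers) {
  w <- counts / sum(counts)
  mu <- cumsum(w * centers)
  omega <- cumsum(w)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  # boundary between bin k and k+1
  centers[k] + (centers[2L] - centers[1L]) / 2
}

#' Phansalkar local adaptive threshold
#'
#' Computes the per-pixel threshold
#' \deqn{t = m \left(1 + p\, e^{-q m} + k \left(\frac{s}{r} - 1\right)\right)}
#' where `m` and `s` are the local mean and (population) standard deviation in
#' a square window of side `2*radius + 1` around each pixel, on intensities
#' normalized to `[0, 1]` by `2^bit_depth - 1`. Edges are handled by
#' replicated padding. A pixel is foreground when its normalized intensity is
#' strictly greater than its local threshold. Designed for low-contrast
#' stained images; defaults follow the algorithm's published parameters.
#'
#' @param pixels Numeric matrix of native-range intensities, or a [net_field].
#' @param radius Window radius in pixels (>= 1).
#' @param k,r,p,q Phansalkar parameters.
#' @param bit_depth Bit depth used for normalization. Taken from the
#'   `net_field` when one is supplied; for a bare matrix it defaults to 8 when
#'   no intensity exceeds 255 and 16 otherwise.
#' @return Logical foreground mask with the shape of `pixels`.
#' @export
phansalkar_threshold <- function(pixels, radius = 15L, k = 0.25, r = 0.5,
                                 p = 2.0, q = 10.0, bit_depth = NULL) {
  if (inherits(pixels, "net_field")) {
    if (is.null(bit_depth)) bit_depth <- pixels$bit_depth
    pixels <- pixels$pixels
  }
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (is.null(bit_depth)) bit_depth <- if (max(pixels) <= 255) 8L else 16L
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  if (radius > min(dim(pixels)) / 2) {
    stop("`radius` (", radius, ") exceeds half the smallest image dimension (",
         min(dim(pixels)), ")", call. = FALSE)
  }
  x <- pixels / (2^bit_depth - 1)
  side <- 2L * radius + 1L
  brush <- matrix(1 / side^2, side, side)
  m <- box_filter(x, brush)
  m2 <- box_filter(x^2, brush)
  s <- sqrt(pmax(m2 - m^2, 0))
  t <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
  x > t
}

# replicate-padded box filter via EBImage's FFT convolution
box_filter <- function(x, brush) {
  y <- EBImage::filter2(x, brush, boundary = "replicate")
  matrix(as.numeric(y), nrow(x), ncol(x))
}

#' Combine global and local segmentation masks
#'
#' The global (intermodes) mask is reliable about *where* bright nuclear
#' material is but truncates dim diffuse structures; the local (Phansalkar)
#' mask delineates full object extents but can pass background texture. Mode
#' `"local_seeded_by_global"` (default) keeps every 8-connected component of
#' the local mask that overlaps the global mask in at least one pixel, so
#' diffuse NET halos are retained whole while unseeded background texture is
#' dropped. Mode `"intersection"` is the pixelwise AND.
#'
#' @param global_fg,local_fg Logical masks of identical shape.
#' @param mode `"local_seeded_by_global"` or `"intersection"`.
#' @return Logical mask.
#' @export
combine_masks <- function(global_fg, local_fg,
                          mode = c("local_seeded_by_global", "intersection")) {
  mode <- match.arg(mode)
  if (!identical(dim(global_fg), dim(local_fg))) {
    stop("mask shapes differ: ", paste(dim(global_fg), collapse = "x"), " vs ",
         paste(dim(local_fg), collapse = "x"), call. = FALSE)
  }
  if (mode == "intersection") return(global_fg & local_fg)
  lab <- label_components(local_fg, connectivity = 8L, min_area_px = 0L)
  seeded <- sort(unique(lab[global_fg & lab > 0L]))
  local_fg & matrix(lab %in% seeded, nrow(lab), ncol(lab))
}

#' Label connected foreground components
#'
#' Labels connected components of a binary mask under 4- or 8-connectivity,
#' drops components smaller than `min_area_px` (a speckle floor below any
#' plausible nucleus), and renumbers the survivors contiguously from 1 in
#' raster-scan order of first appearance.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area_px Minimum component area in pixels; smaller components are
#'   removed before labeling (default 10). Components whose area equals
#'   `min_area_px` are kept.
#' @return Integer label matrix with attribute `n_labels`; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8L, min_area_px = 10L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    lab <- merge_diagonal_labels(lab)
  }
  n <- max(lab)
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(areas >= min_area_px)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  structure(lab, n_labels = max(lab))
}

# union 4-connected labels that touch diagonally (8-connectivity)
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.integer(lab[-nr, -nc]), as.integer(lab[-1L, -1L])),  # down-right
    cbind(as.integer(lab[-nr, -1L]), as.integer(lab[-1L, -nc]))   # down-left
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  pairs <- unique(pairs)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (row in seq_len(nrow(pairs))) {
    a <- find(pairs[row, 1L]); b <- find(pairs[row, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  # renumber roots contiguously, keeping first-appearance order
  remap <- integer(n)
  remap[sort(unique(root))] <- seq_along(unique(sort(root)))
  lab[lab > 0L] <- remap[root[lab[lab > 0L]]]
  lab
}

#' Segment one field into labeled nuclear ROIs
#'
#' Runs the two-threshold scheme end to end: intermodes global threshold,
#' Phansalkar local threshold, mask combination, and connected-component
#' labeling with the speckle floor.
#'
#' @param field A [net_field].
#' @param config A [net_config()]; the `segmentation` block supplies all
#'   parameters.
#' @return Integer label matrix (attribute `n_labels`), plus attributes
#'   `intermodes_threshold` (the global threshold used).
#' @export
segment_field <- function(field, config = net_config()) {
  stopifnot(inherits(field, "net_field"))
  seg <- config$segmentation
  thr <- intermodes_threshold(field$pixels, n_bins = seg$n_bins,
                              max_smooth_iters = seg$max_smooth_iters,
                              on_unimodal = seg$on_unimodal)
  global_fg <- field$pixels > thr
  local_fg <- phansalkar_threshold(field$pixels, radius = seg$radius,
                                   k = seg$k, r = seg$r, p = seg$p, q = seg$q,
                                   bit_depth = field$bit_depth)
  combined <- combine_masks(global_fg, local_fg, mode = seg$combine_mode)
  lab <- label_components(combined, connectivity = seg$connectivity,
                          min_area_px = seg$min_area_px)
  attr(lab, "intermodes_threshold") <- thr
  lab
}
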