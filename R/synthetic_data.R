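#' Specification of a synthetic NET-assay field
#'
#' Describes one simulated DAPI field: bright compact condensed nuclei, large
#' diffuse NET structures, dim-but-dense small fragments, and merged doublets
#' over a noisy background. Key biological premise encoded by the defaults:
#' an object's integrated intensity is its DNA content, so a NET carries
#' about one nucleus-equivalent of DNA spread over several times the nucleus
#' area, a doublet about two nucleus-equivalents, and a fragment about a
#' tenth. NETs are rendered as sparse webs of chromatin strands of uniform
#' amplitude with a few small bright condensed remnants ("beads"), matching
#' the web-like morphology of real NETs; a uniform dim disc conserving DNA
#' over >= 5x the nucleus area would sit below any local threshold tuned for
#' stained objects and is not how NETs look.
#'
#' One nucleus-equivalent is defined as `nucleus_area_mean *
#' nucleus_intensity * (2^bit_depth - 1)` summed intensity.
#'
#' @param shape Image shape `(rows, cols)`, default `c(512, 512)`.
#' @param bit_depth Bit depth (default 16).
#' @param background_level Flat background intensity in native units
#'   (default 500).
#' @param noise_sd Gaussian read-noise SD in native units (default 150).
#' @param n_nuclei,n_nets,n_fragments,n_doublets Object counts.
#' @param nucleus_area_mean,nucleus_area_sd Condensed-nucleus area
#'   distribution in px^2 (default 120 +/- 12).
#' @param nucleus_intensity Nucleus plateau intensity as a fraction of the
#'   dynamic range (default 0.75; exposure set so the stain dominates the
#'   background without saturating).
#' @param nucleus_intensity_sd_frac Relative SD of the plateau between nuclei
#'   (default 0.04; condensed NETosis-assay nuclei are fairly uniform).
#' @param net_area_multiplier Range of the NET web area as a multiple of
#'   `nucleus_area_mean` (default `c(10, 12)`; drawn uniformly --
#'   NET webs are unambiguously larger than any nucleus-scale object, as in
#'   real preparations).
#' @param net_dna_range NET total DNA in nucleus-equivalents (uniform,
#'   default `c(0.9, 1.1)`), of which `net_bead_dna_frac` sits in
#'   `net_n_beads` bright condensed remnants.
#' @param net_web_fill Fraction of the NET's bounding disc covered by
#'   chromatin strands (default 0.2; sets the web radius).
#' @param net_n_beads,net_bead_dna_frac,net_bead_sigma Condensed-remnant
#'   count, DNA share and Gaussian width.
#' @param doublet_offset_frac Center separation of the two doublet nuclei in
#'   units of the nucleus radius (default 1.4, giving a merged
#'   figure-of-eight blob carrying close to two nucleus-equivalents; the
#'   overlap lens saturates the detector as dense chromatin does).
#' @param fragment_area_frac Fragment area as a fraction of
#'   `nucleus_area_mean` (default 0.1).
#' @param fragment_dna_frac Fragment DNA in nucleus-equivalents (default
#'   0.1: a small shard at nuclear stain density).
#' @param min_spacing Minimum gap between object bounding circles in px.
#' @param placement_attempts Rejection-sampling budget per object.
#' @param rng_seed Integer seed; [generate_field()] is deterministic given
#'   the spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(512L, 512L), bit_depth = 16L,
                       background_level = 500, noise_sd = 150,
                       n_nuclei = 16L, n_nets = 4L, n_fragments = 3L,
                       n_doublets = 2L,
                       nucleus_area_mean = 120, nucleus_area_sd = 12,
                       nucleus_intensity = 0.75,
                       nucleus_intensity_sd_frac = 0.04,
                       net_area_multiplier = c(10, 12),
                       net_dna_range = c(0.9, 1.1),
                       net_web_fill = 0.2,
                       net_n_beads = 2L, net_bead_dna_frac = 0.05,
                       net_bead_sigma = 0.8,
                       doublet_offset_frac = 1.4,
                       fragment_area_frac = 0.1, fragment_dna_frac = 0.1,
                       min_spacing = 8, placement_attempts = 2000L,
                       rng_seed = 1L) {
  counts <- c(n_nuclei, n_nets, n_fragments, n_doublets)
  if (any(counts < 0L)) stop("object counts must be >= 0", call. = FALSE)
  spec <- list(shape = as.integer(shape), bit_depth = as.integer(bit_depth),
               background_level = background_level, noise_sd = noise_sd,
               n_nuclei = as.integer(n_nuclei), n_nets = as.integer(n_nets),
               n_fragments = as.integer(n_fragments),
               n_doublets = as.integer(n_doublets),
               nucleus_area_mean = nucleus_area_mean,
               nucleus_area_sd = nucleus_area_sd,
               nucleus_intensity = nucleus_intensity,
               nucleus_intensity_sd_frac = nucleus_intensity_sd_frac,
               net_area_multiplier = net_area_multiplier,
               net_dna_range = net_dna_range, net_web_fill = net_web_fill,
               net_n_beads = as.integer(net_n_beads),
               net_bead_dna_frac = net_bead_dna_frac,
               net_bead_sigma = net_bead_sigma,
               doublet_offset_frac = doublet_offset_frac,
               fragment_area_frac = fragment_area_frac,
               fragment_dna_frac = fragment_dna_frac,
               min_spacing = min_spacing,
               placement_attempts = as.integer(placement_attempts),
               rng_seed = as.integer(rng_seed))
  structure(spec, class = "scene_spec")
}

#' Adjust a scene to a target true NET fraction
#'
#' Keeps the total cell count (`n_nuclei + n_nets`) of `spec` and re-splits
#' it so that `n_nets / (n_nuclei + n_nets)` is as close as possible to
#' `fraction`.
#'
#' @param spec A [scene_spec()].
#' @param fraction Target true NET fraction in `[0, 1)`.
#' @return The adjusted `scene_spec`.
#' @export
scene_spec_for_fraction <- function(spec, fraction) {
  stopifnot(inherits(spec, "scene_spec"), fraction >= 0, fraction < 1)
  total <- spec$n_nuclei + spec$n_nets
  spec$n_nets <- as.integer(round(fraction * total))
  spec$n_nuclei <- total - spec$n_nets
  spec
}

#' Generate one synthetic field with per-object ground truth
#'
#' Deterministic for a given spec (including its `rng_seed`): objects are
#' placed by rejection sampling with non-overlapping bounding circles
#' (overlap occurs only *within* a doublet), rendered without noise, DNA
#' contents rescaled exactly to their targets, ground-truth labels taken as
#' the pre-noise support (contribution above four noise SDs), and
#' Gaussian read noise added last.
#'
#' @param spec A [scene_spec()].
#' @param slide_id,condition,field_index Identity stamped on the returned
#'   field.
#' @return List with `field` (a [net_field]) and `truth` (list with `labels`,
#'   an integer matrix, and `objects`, a tibble with `object_id`, `class`,
#'   `area_px`, `integrated_intensity` in native units, and
#'   `nucleus_equivalents`). The true NET fraction
#'   `n_nets / (n_nets + n_nuclei)` is attached as attribute `net_fraction`
#'   of the truth.
#' @export
generate_field <- function(spec, slide_id = "synthetic", condition = "spontaneous",
                           field_index = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$rng_seed)

  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  maxval <- 2^spec$bit_depth - 1
  neq_unit <- spec$nucleus_area_mean * spec$nucleus_intensity  # 1 neq, [0,1] scale
  mu_r <- sqrt(spec$nucleus_area_mean / pi)

  # --- plan objects (class, bounding radius) largest-first for placement
  classes <- c(rep("net", spec$n_nets), rep("doublet", spec$n_doublets),
               rep("nucleus", spec$n_nuclei), rep("fragment", spec$n_fragments))
  objects <- vector("list", length(classes))
  placed <- matrix(numeric(0), ncol = 3)  # cy, cx, radius

  signal <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)
  best <- matrix(0, nr, nc)  # strongest contribution so far, for ties
  support_eps <- 4 * spec$noise_sd / maxval

  for (i in seq_along(classes)) {
    cl <- classes[i]
    render <- switch(cl,
      net = render_net(spec, mu_r, neq_unit),
      doublet = render_doublet(spec, mu_r, neq_unit),
      nucleus = render_nucleus(spec, neq_unit),
      fragment = render_fragment(spec, neq_unit))
    rad <- render$radius
    pos <- place_object(nr, nc, rad, placed, spec$min_spacing,
                        spec$placement_attempts)
    if (is.null(pos)) {
      stop("overcrowded scene: could not place object of class '", cl,
           "' within ", spec$placement_attempts, " attempts", call. = FALSE)
    }
    placed <- rbind(placed, c(pos, rad))
    patch <- render$patch  # square canvas, object centered
    half <- (nrow(patch) - 1L) / 2L
    rows <- (pos[1L] - half):(pos[1L] + half)
    cols <- (pos[2L] - half):(pos[2L] + half)
    ok_r <- rows >= 1L & rows <= nr
    ok_c <- cols >= 1L & cols <= nc
    patch <- patch[ok_r, ok_c, drop = FALSE]
    rows <- rows[ok_r]; cols <- cols[ok_c]
    signal[rows, cols] <- signal[rows, cols] + patch
    sup <- patch > support_eps & patch > best[rows, cols]
    lab_patch <- labels[rows, cols]
    lab_patch[sup] <- i
    labels[rows, cols] <- lab_patch
    bb <- best[rows, cols]; bb[sup] <- patch[sup]
    best[rows, cols] <- bb
    objects[[i]] <- tibble::tibble(
      object_id = i, class = cl,
      area_px = sum(patch > support_eps),
      integrated_intensity = sum(patch) * maxval,
      nucleus_equivalents = sum(patch) / neq_unit
    )
  }
  objects <- dplyr::bind_rows(objects)
  if (nrow(objects) > 0L) {
    # areas after overlap resolution (doublet halves are one object; distinct
    # objects never overlap above the support threshold by construction)
    lab_areas <- tabulate(labels[labels > 0L], nbins = length(classes))
    objects$area_px <- lab_areas[objects$object_id]
  }

  img <- spec$background_level / maxval + signal
  clipped <- mean(img > 1)
  if (clipped > 0.001) {
    stop("rendered scene clips ", round(100 * clipped, 2),
         "% of pixels; lower intensities or counts", call. = FALSE)
  }
  img <- img + rnorm(nr * nc, 0, spec$noise_sd / maxval)
  pixels <- matrix(as.integer(round(pmin(pmax(img, 0), 1) * maxval)), nr, nc)

  truth <- structure(
    list(labels = labels, objects = objects),
    net_fraction = if (spec$n_nets + spec$n_nuclei > 0L) {
      spec$n_nets / (spec$n_nets + spec$n_nuclei)
    } else NA_real_)
  list(field = net_field(pixels, bit_depth = spec$bit_depth,
                         slide_id = slide_id, condition = condition,
                         field_index = field_index,
                         source_path = "<synthetic>"),
       truth = truth)
}

# rejection-sample a center so bounding circles keep min_spacing apart
place_object <- function(nr, nc, radius, placed, min_spacing, attempts) {
  margin <- radius + 3
  if (2 * margin >= min(nr, nc)) return(NULL)
  for (a in seq_len(attempts)) {
    cy <- runif(1, margin, nr - margin)
    cx <- runif(1, margin, nc - margin)
    if (nrow(placed) > 0L) {
      d <- sqrt((placed[, 1L] - cy)^2 + (placed[, 2L] - cx)^2)
      if (any(d < placed[, 3L] + radius + min_spacing)) next
    }
    return(c(round(cy), round(cx)))
  }
  NULL
}

# square odd-sized patch of zeros with the object centered
new_patch <- function(radius) {
  half <- ceiling(radius) + 4L
  matrix(0, 2L * half + 1L, 2L * half + 1L)
}

patch_coords <- function(patch) {
  half <- (nrow(patch) - 1L) / 2L
  d <- seq(-half, half)
  list(dy = matrix(d, nrow(patch), ncol(patch)),
       dx = matrix(d, nrow(patch), ncol(patch), byrow = TRUE))
}

render_nucleus <- function(spec, neq_unit) {
  area <- max(rnorm(1, spec$nucleus_area_mean, spec$nucleus_area_sd),
              0.4 * spec$nucleus_area_mean)
  intensity <- spec$nucleus_intensity *
    max(rnorm(1, 1, spec$nucleus_intensity_sd_frac), 0.5)
  r <- sqrt(area / pi)
  patch <- new_patch(r + 3)
  co <- patch_coords(patch)
  patch[co$dy^2 + co$dx^2 <= r^2] <- intensity
  patch <- gaussian_blur(patch, 1.0)
  list(patch = patch, radius = r + 3)
}

# two overlapping average-sized nuclei; the overlap lens saturates the
# detector, leaving the rendered DNA in [1.8, 2.2] nucleus-equivalents by
# construction
render_doublet <- function(spec, mu_r, neq_unit) {
  off <- spec$doublet_offset_frac * mu_r / 2
  theta <- runif(1, 0, pi)
  dy <- off * sin(theta); dx <- off * cos(theta)
  patch <- new_patch(mu_r + off + 3)
  co <- patch_coords(patch)
  for (s in c(-1, 1)) {
    inten <- spec$nucleus_intensity * runif(1, 0.97, 1.03)
    inside <- (co$dy - s * dy)^2 + (co$dx - s * dx)^2 <= mu_r^2
    patch[inside] <- patch[inside] + inten
  }
  patch <- pmin(patch, 1.0)
  patch <- gaussian_blur(patch, 1.0)
  list(patch = patch, radius = mu_r + off + 3)
}

# small dense shard of condensed chromatin at nuclear stain density
render_fragment <- function(spec, neq_unit) {
  area <- spec$fragment_area_frac * spec$nucleus_area_mean
  dna <- spec$fragment_dna_frac * runif(1, 0.9, 1.1) * neq_unit
  r <- sqrt(area / pi)
  patch <- new_patch(r + 3)
  co <- patch_coords(patch)
  patch[co$dy^2 + co$dx^2 <= r^2] <- 1
  patch <- gaussian_blur(patch, 0.5)
  patch <- patch * (dna / sum(patch))
  list(patch = patch, radius = r + 2)
}

# NET: sparse web of uniform-amplitude chromatin strands with a few bright
# condensed remnants on the strands; total DNA rescaled to the target.
# Strands are the minimum-spanning-tree edges of points scattered uniformly
# in the web's bounding disc: the web is connected by construction and its
# strand density is spatially uniform (strands piling up in one place would
# raise the local adaptive threshold there and punch holes in the object,
# which real chromatin webs do not show)
render_net <- function(spec, mu_r, neq_unit) {
  dna <- runif(1, spec$net_dna_range[1L], spec$net_dna_range[2L]) * neq_unit
  mult <- runif(1, spec$net_area_multiplier[1L], spec$net_area_multiplier[2L])
  target_area <- mult * spec$nucleus_area_mean
  radius <- sqrt(target_area / (pi * spec$net_web_fill))
  mask <- new_patch(radius)
  half <- (nrow(mask) - 1L) / 2L

  stamp <- function(mask, y, x) {
    iy <- round(y) + half + 1L; ix <- round(x) + half + 1L
    n <- nrow(mask)
    for (k in seq_along(iy)) {
      yy <- iy[k]; xx <- ix[k]
      if (yy < 2L || yy > n - 1L || xx < 2L || xx > n - 1L) next
      mask[yy, xx] <- 1
      mask[yy - 1L, xx] <- 1; mask[yy + 1L, xx] <- 1
      mask[yy, xx - 1L] <- 1; mask[yy, xx + 1L] <- 1
    }
    mask
  }
  # number of scatter points calibrated so the stamped strand area comes out
  # near 0.9 * target_area (MST length grows as sqrt(n * disc area))
  disc_area <- pi * radius^2
  n_pts <- max(8L, round((0.9 * target_area / (2.5 * 0.68))^2 / (1.2 * disc_area)))
  rr <- (radius - 2) * sqrt(runif(n_pts))
  th <- runif(n_pts, 0, 2 * pi)
  py <- rr * sin(th); px <- rr * cos(th)
  for (e in mst_edges(py, px)) {
    len <- sqrt((py[e[1L]] - py[e[2L]])^2 + (px[e[1L]] - px[e[2L]])^2)
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / 0.7)))
    mask <- stamp(mask,
                  py[e[1L]] + tt * (py[e[2L]] - py[e[1L]]) + rnorm(length(tt), 0, 0.3),
                  px[e[1L]] + tt * (px[e[2L]] - px[e[1L]]) + rnorm(length(tt), 0, 0.3))
  }

  web <- gaussian_blur(mask, 0.6)
  web <- web * ((1 - spec$net_bead_dna_frac) * dna / sum(web))

  # condensed remnants: bright compact beads on the strands
  on_web <- which(mask > 0.5, arr.ind = TRUE)
  inner <- on_web[sqrt((on_web[, 1L] - half - 1)^2 +
                       (on_web[, 2L] - half - 1)^2) < 0.6 * radius, ,
                  drop = FALSE]
  if (nrow(inner) == 0L) inner <- on_web
  picks <- inner[sample.int(nrow(inner), min(spec$net_n_beads, nrow(inner))), ,
                 drop = FALSE]
  co <- patch_coords(web)
  bead_dna <- spec$net_bead_dna_frac * dna / max(nrow(picks), 1L)
  s2 <- 2 * spec$net_bead_sigma^2
  for (b in seq_len(nrow(picks))) {
    by <- picks[b, 1L] - half - 1L; bx <- picks[b, 2L] - half - 1L
    g <- exp(-((co$dy - by)^2 + (co$dx - bx)^2) / s2)
    web <- web + g * (bead_dna / sum(g))
  }
  web <- web * (dna / sum(web))
  list(patch = web, radius = 0.88 * radius)
}

gaussian_blur <- function(x, sigma) {
  matrix(as.numeric(EBImage::gblur(x, sigma = sigma)), nrow(x), ncol(x))
}

#' Compare pipeline calls against synthetic ground truth
#'
#' Matches detected ROIs to ground-truth objects by pixel-overlap IoU
#' (intersection over union), greedily from the highest IoU downwards,
#' one-to-one, accepting matches with IoU at least `iou_min`. Builds a
#' confusion table of truth classes against pipeline calls and reports the
#' NET percentage error.
#'
#' @param calls Tibble from [classify_rois()].
#' @param labels Detected label matrix ([segment_field()]).
#' @param truth Ground truth from [generate_field()].
#' @param iou_min Minimum IoU for a match (default 0.5).
#' @return List with `matches` (tibble `object_id`, `roi_id`, `iou`, `class`,
#'   `call`), `confusion` (tibble of truth class x call counts, including
#'   `unmatched` on both sides), `net_percent_auto`, `net_percent_true`, and
#'   `net_percent_error` (absolute difference in percentage points).
#' @export
evaluate_against_truth <- function(calls, labels, truth, iou_min = 0.5) {
  if (!identical(dim(labels), dim(truth$labels))) {
    stop("detected and truth label maps have different shapes", call. = FALSE)
  }
  det_area <- tabulate(labels[labels > 0L], nbins = max(max(labels), 1L))
  tru_area <- tabulate(truth$labels[truth$labels > 0L],
                       nbins = max(max(truth$labels), 1L))
  both <- labels > 0L & truth$labels > 0L
  ov <- tibble::tibble(truth_id = as.integer(truth$labels[both]),
                       roi_id = as.integer(labels[both])) |>
    dplyr::count(.data$truth_id, .data$roi_id, name = "inter") |>
    dplyr::mutate(iou = .data$inter /
                    (det_area[.data$roi_id] + tru_area[.data$truth_id] -
                       .data$inter)) |>
    dplyr::filter(.data$iou >= iou_min) |>
    dplyr::arrange(dplyr::desc(.data$iou))
  used_t <- logical(length(tru_area)); used_d <- logical(length(det_area))
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    ti <- ov$truth_id[i]; di <- ov$roi_id[i]
    if (!used_t[ti] && !used_d[di]) {
      keep[i] <- TRUE; used_t[ti] <- TRUE; used_d[di] <- TRUE
    }
  }
  matches <- ov[keep, c("truth_id", "roi_id", "iou")]
  matches <- dplyr::left_join(
    matches,
    dplyr::select(truth$objects, truth_id = "object_id", "class"),
    by = "truth_id")
  matches <- dplyr::left_join(matches,
                              dplyr::select(calls, "roi_id", "call"),
                              by = "roi_id")

  truth_side <- dplyr::mutate(
    dplyr::left_join(dplyr::select(truth$objects, truth_id = "object_id",
                                   "class"),
                     dplyr::select(matches, "truth_id", "call"),
                     by = "truth_id"),
    call = dplyr::coalesce(.data$call, "unmatched"))
  extra_det <- dplyr::filter(calls, !.data$roi_id %in% matches$roi_id)
  confusion <- dplyr::bind_rows(
    dplyr::count(truth_side, .data$class, .data$call),
    dplyr::count(dplyr::mutate(extra_det, class = "unmatched"),
                 .data$class, .data$call)
  )

  retained <- calls$call %in% c("nucleus", "net")
  auto <- if (any(retained)) {
    100 * sum(calls$call == "net") / sum(retained)
  } else NA_real_
  true_pct <- 100 * attr(truth, "net_fraction")
  list(matches = matches, confusion = confusion,
       net_percent_auto = auto, net_percent_true = true_pct,
       net_percent_error = abs(auto - true_pct))
}

#' Simulate a study: slides, fields, images on disk, manifest and truth
#'
#' Writes one 16-bit TIFF per field under `out_dir/images/`, a manifest CSV
#' (`manifest.csv`) and a ground-truth table (`truth.csv`). Each field gets
#' its own RNG stream derived from `(seed, slide, field)`, so any slide or
#' field can be regenerated independently.
#'
#' @param out_dir Output directory.
#' @param slides Tibble with columns `slide_id`, `condition`, `group`,
#'   `net_fraction`; one row per slide. Defaults to two slides (patient and
#'   control) under the spontaneous condition.
#' @param n_fields Fields per slide (default 10).
#' @param spec Base [scene_spec()]; per-slide `net_fraction` is applied with
#'   [scene_spec_for_fraction()].
#' @param seed Master seed.
#' @return Invisibly, list with `manifest` (tibble) and `truth` (tibble);
#'   both are also written as CSV.
#' @export
simulate_study <- function(out_dir,
                           slides = tibble::tibble(
                             slide_id = c("S1", "S2"),
                             condition = "spontaneous",
                             group = c("patient", "control"),
                             net_fraction = c(0.2, 0.1)),
                           n_fields = 10L, spec = scene_spec(), seed = 1L) {
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(); truths <- list()
  for (s in seq_len(nrow(slides))) {
    sspec <- scene_spec_for_fraction(spec, slides$net_fraction[s])
    for (f in seq_len(n_fields)) {
      sspec$rng_seed <- field_seed(seed, s, f)
      gen <- generate_field(sspec, slide_id = slides$slide_id[s],
                            condition = slides$condition[s], field_index = f)
      fname <- sprintf("%s_%s_f%02d.tif", slides$slide_id[s],
                       slides$condition[s], f)
      path <- file.path(img_dir, fname)
      tiff::writeTIFF(gen$field$pixels / (2^spec$bit_depth - 1), path,
                      bits.per.sample = 16L)
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        slide_id = slides$slide_id[s], condition = slides$condition[s],
        group = slides$group[s], field_index = f, field_path = path)
      truths[[length(truths) + 1L]] <- dplyr::mutate(
        gen$truth$objects, slide_id = slides$slide_id[s],
        condition = slides$condition[s], field_index = f, .before = 1L)
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  truth <- dplyr::bind_rows(truths)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  readr::write_csv(truth, file.path(out_dir, "truth.csv"), progress = FALSE)
  invisible(list(manifest = manifest, truth = truth))
}

# deterministic per-field RNG stream; kept well inside 32-bit integer range
field_seed <- function(master, slide_idx, field_idx) {
  as.integer((as.numeric(master) %% 65011) * 33029 +
               slide_idx * 523 + field_idx) %% .Machine$integer.max
}

# Prim's algorithm over Euclidean distances; returns list of index pairs
mst_edges <- function(py, px) {
  n <- length(py)
  if (n < 2L) return(list())
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  d2 <- (outer(py, py, "-"))^2 + (outer(px, px, "-"))^2
  best_d <- d2[1L, ]; best_from <- rep(1L, n)
  edges <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_d[cand])]
    edges[[k]] <- c(best_from[j], j)
    in_tree[j] <- TRUE
    upd <- !in_tree & d2[j, ] < best_d
    best_d[upd] <- d2[j, upd]
    best_from[upd] <- j
  }
  edges
}

#' End-to-end recovery benchmark on synthetic fields
#'
#' For every combination of seed and true NET fraction, simulates `n_fields`
#' fields, runs the full pipeline (segment, measure, classify), pools the
#' counts and compares the pooled NET percentage against the ground truth.
#' Also reports how often synthetic doublets are eliminated as multiples and
#' synthetic fragments as fragments (matched by IoU).
#'
#' @param seeds Integer vector of master seeds.
#' @param fractions True NET fractions to simulate.
#' @param n_fields Fields pooled per (seed, fraction).
#' @param spec Base [scene_spec()].
#' @param config [net_config()] used for the pipeline.
#' @return Tibble with one row per (seed, fraction): pooled `net_percent`,
#'   `net_percent_true`, `abs_error`, and the doublet/fragment
#'   elimination counts and rates.
#' @export
evaluate_recovery <- function(seeds = 1:10, fractions = c(0, 0.2, 0.5),
                              n_fields = 10L, spec = scene_spec(),
                              config = net_config()) {
  grid <- expand.grid(seed = seeds, fraction = fractions)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sd <- grid$seed[i]; fr <- grid$fraction[i]
    sspec <- scene_spec_for_fraction(spec, fr)
    slide_idx <- as.integer(round(100 * fr)) + 1L
    nets <- 0L; retained <- 0L
    doub_ok <- 0L; doub_n <- 0L; frag_ok <- 0L; frag_n <- 0L
    for (f in seq_len(n_fields)) {
      sspec$rng_seed <- field_seed(sd, slide_idx, f)
      gen <- generate_field(sspec, field_index = f)
      labels <- segment_field(gen$field, config)
      calls <- classify_rois(measure_rois(gen$field, labels), config)
      nets <- nets + sum(calls$call == "net")
      retained <- retained + sum(calls$call %in% c("net", "nucleus"))
      ev <- evaluate_against_truth(calls, labels, gen$truth)
      cf <- ev$confusion
      doub_ok <- doub_ok + sum(cf$n[cf$class == "doublet" &
                                      cf$call == "eliminated_multiple"])
      doub_n <- doub_n + sum(cf$n[cf$class == "doublet"])
      frag_ok <- frag_ok + sum(cf$n[cf$class == "fragment" &
                                      cf$call == "eliminated_fragment"])
      frag_n <- frag_n + sum(cf$n[cf$class == "fragment"])
    }
    net_pct <- if (retained > 0L) 100 * nets / retained else 0
    tibble::tibble(seed = sd, fraction = fr, total_nets = nets,
                   total_retained = retained, net_percent = net_pct,
                   net_percent_true = 100 * fr,
                   abs_error = abs(net_pct - 100 * fr),
                   doublets_eliminated = doub_ok, doublets_total = doub_n,
                   fragments_eliminated = frag_ok, fragments_total = frag_n)
  })
  dplyr::bind_rows(rows)
}
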