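#' Pipeline configuration
#'
#' Bundles every cutoff and segmentation parameter of the pipeline. The two
#' cutoffs at the heart of the method are `net_area_cutoff = 4.30` (an ROI
#' whose area is at least 4.30 times the condensed-nucleus reference area is
#' called a NET) and `upper_elim_cutoff = 1.2` (a non-NET ROI whose relative
#' DNA content exceeds 1.2 is eliminated as a multiple, since a doublet
#' carries about twice one nucleus of DNA). `lower_elim_cutoff` eliminates
#' dim fragments carrying less than half a nucleus of DNA.
#'
#' @param net_area_cutoff Relative-area cutoff for the NET call (inclusive,
#'   default 4.30).
#' @param upper_elim_cutoff Relative-DNA cutoff above which a non-NET ROI is
#'   eliminated as a multiple (strict, default 1.2).
#' @param lower_elim_cutoff Relative-DNA cutoff below which an ROI is
#'   eliminated as a fragment (strict, default 0.5).
#' @param exclude_border Eliminate ROIs touching the image border (default
#'   `TRUE`; partially imaged cells have truncated areas).
#' @param min_rois_for_field_reference Fields with fewer border-surviving
#'   ROIs than this use reference statistics pooled over their slide and
#'   condition instead of the field alone (default 10).
#' @param segmentation Named list of segmentation parameters; see
#'   [segment_field()]. Partial lists are merged over the defaults.
#' @param channel Channel policy for RGB input images (see [load_field()]).
#' @return An object of class `net_config`.
#' @export
net_config <- function(net_area_cutoff = 4.30, upper_elim_cutoff = 1.2,
                       lower_elim_cutoff = 0.5, exclude_border = TRUE,
                       min_rois_for_field_reference = 10L,
                       segmentation = list(), channel = "blue") {
  if (!(net_area_cutoff > upper_elim_cutoff &&
        upper_elim_cutoff > lower_elim_cutoff && lower_elim_cutoff > 0)) {
    stop("cutoffs must satisfy net_area_cutoff > upper_elim_cutoff > ",
         "lower_elim_cutoff > 0", call. = FALSE)
  }
  seg_defaults <- list(
    n_bins = 256L, max_smooth_iters = 10000L, on_unimodal = "error",
    radius = 15L, k = 0.25, r = 0.5, p = 2.0, q = 10.0,
    combine_mode = "local_seeded_by_global", connectivity = 8L,
    min_area_px = 10L
  )
  unknown <- setdiff(names(segmentation), names(seg_defaults))
  if (length(unknown) > 0L) {
    stop("unknown segmentation parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seg <- utils::modifyList(seg_defaults, segmentation)
  structure(
    list(net_area_cutoff = net_area_cutoff,
         upper_elim_cutoff = upper_elim_cutoff,
         lower_elim_cutoff = lower_elim_cutoff,
         exclude_border = isTRUE(exclude_border),
         min_rois_for_field_reference = as.integer(min_rois_for_field_reference),
         segmentation = seg, channel = channel),
    class = "net_config"
  )
}

#' @export
print.net_config <- function(x, ...) {
  cat("<net_config>\n",
      "  NET call: relative_area >= ", x$net_area_cutoff, "\n",
      "  eliminate multiple: relative_dna > ", x$upper_elim_cutoff, "\n",
      "  eliminate fragment: relative_dna < ", x$lower_elim_cutoff, "\n",
      "  exclude border ROIs: ", x$exclude_border, "\n", sep = "")
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [net_config()]; the `segmentation`
#' block is merged key-by-key over the defaults. Missing keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A [net_config()].
#' @export
read_net_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- names(formals(net_config))
  unknown <- setdiff(names(y), c(known, "netquant_version"))
  if (length(unknown) > 0L) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  do.call(net_config, y[intersect(names(y), known)])
}

#' Write a configuration snapshot
#'
#' Serializes the exact configuration (plus the package version) next to a
#' result set so every output is reproducible from its snapshot.
#'
#' @param config A [net_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_config_snapshot <- function(config, path) {
  x <- unclass(config)
  x$netquant_version <- as.character(utils::packageVersion("netquant"))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Condensed-nucleus reference area
#'
#' Estimates the typical area of a condensed (non-NET) nucleus by a
#' fixed-point iteration: starting from an empty NET-candidate set, the
#' reference is the median area of non-candidates; every ROI whose area is at
#' least `net_area_cutoff` times the reference joins the candidate set; repeat
#' until stable. The candidate set grows monotonically, so the iteration
#' terminates in at most `n` rounds. The median (rather than the mean) keeps
#' the reference from being inflated by NETs and doublets.
#'
#' @param measurements Tibble with columns `roi_id` and `area_px`, or a bare
#'   numeric vector of areas (then `roi_id` is the position).
#' @param net_area_cutoff Relative-area cutoff (default 4.30).
#' @return List with `reference_area` (real) and `net_candidate_ids`
#'   (integer vector of `roi_id`s whose relative area meets the cutoff).
#' @export
reference_area <- function(measurements, net_area_cutoff = 4.30) {
  if (is.numeric(measurements) && is.null(dim(measurements))) {
    areas <- as.numeric(measurements)
    ids <- seq_along(areas)
  } else {
    areas <- as.numeric(measurements$area_px)
    ids <- measurements$roi_id
  }
  if (length(areas) == 0L) {
    stop("no ROIs available to estimate a reference area", call. = FALSE)
  }
  cand <- rep(FALSE, length(areas))
  repeat {
    if (all(cand)) {
      stop("degenerate reference: every ROI became a NET candidate; ",
           "field needs manual review", call. = FALSE)
    }
    ref <- stats::median(areas[!cand])
    new_cand <- cand | (areas / ref >= net_area_cutoff)
    if (identical(new_cand, cand)) break
    cand <- new_cand
  }
  list(reference_area = ref, net_candidate_ids = ids[cand])
}

# reference statistics (relative-DNA denominator + reference area) from a
# pool of border-filtered measurements
reference_stats <- function(measurements, config) {
  median_rid <- stats::median(measurements$raw_integrated_density)
  rel_dna <- measurements$raw_integrated_density / median_rid
  keep <- rel_dna >= config$lower_elim_cutoff
  if (!any(keep)) {
    return(list(median_rid = median_rid, reference_area = NA_real_))
  }
  ref <- reference_area(measurements[keep, , drop = FALSE],
                        net_area_cutoff = config$net_area_cutoff)
  list(median_rid = median_rid, reference_area = ref$reference_area)
}

#' Classify ROIs as nuclei, NETs, or eliminated objects
#'
#' Applies the deterministic decision sequence to measured ROIs:
#' \enumerate{
#'   \item ROIs touching the border are eliminated (`eliminated_border`) when
#'     `exclude_border` is set.
#'   \item Relative DNA is each ROI's raw integrated density divided by the
#'     median raw integrated density of the border-surviving ROIs; ROIs with
#'     relative DNA strictly below `lower_elim_cutoff` are eliminated as
#'     fragments.
#'   \item The condensed-nucleus [reference_area()] is estimated on the
#'     remainder; ROIs with relative area at or above `net_area_cutoff` are
#'     called NETs. The NET call precedes the multiple elimination: a NET
#'     carries about one nucleus of DNA spread thin, but a diffuse halo can
#'     push its relative DNA slightly over the upper cutoff, and eliminating
#'     it first would systematically under-call NETs.
#'   \item Remaining ROIs with relative DNA strictly above
#'     `upper_elim_cutoff` are eliminated as multiples.
#'   \item Everything else is a condensed nucleus.
#' }
#'
#' @param measurements Tibble from [measure_rois()].
#' @param config A [net_config()].
#' @param reference Optional list with `median_rid` and `reference_area`
#'   pooled from a wider stratum (used for sparse fields); when `NULL`
#'   (default) both are estimated from `measurements` itself.
#' @return The measurements tibble with added columns `relative_area`,
#'   `relative_dna` and `call`, plus attributes `reference_area` and
#'   `median_rid`. Calls are one of `nucleus`, `net`, `eliminated_fragment`,
#'   `eliminated_multiple`, `eliminated_border`.
#' @export
classify_rois <- function(measurements, config = net_config(), reference = NULL) {
  m <- measurements
  if (nrow(m) == 0L) {
    out <- dplyr::mutate(m, relative_area = numeric(0), relative_dna = numeric(0),
                         call = character(0))
    attr(out, "reference_area") <- NA_real_
    attr(out, "median_rid") <- NA_real_
    return(out)
  }
  call <- rep(NA_character_, nrow(m))
  if (config$exclude_border) call[m$touches_border] <- "eliminated_border"
  surviving <- is.na(call)

  median_rid <- if (!is.null(reference)) reference$median_rid else if (any(surviving)) {
    stats::median(m$raw_integrated_density[surviving])
  } else NA_real_
  rel_dna <- m$raw_integrated_density / median_rid

  frag <- surviving & rel_dna < config$lower_elim_cutoff
  call[frag] <- "eliminated_fragment"
  remainder <- surviving & !frag

  ref_area <- if (!is.null(reference)) {
    reference$reference_area
  } else if (any(remainder)) {
    reference_area(m[remainder, , drop = FALSE],
                   net_area_cutoff = config$net_area_cutoff)$reference_area
  } else NA_real_
  rel_area <- m$area_px / ref_area

  is_net <- remainder & !is.na(rel_area) & rel_area >= config$net_area_cutoff
  call[is_net] <- "net"
  multi <- remainder & !is_net & rel_dna > config$upper_elim_cutoff
  call[multi] <- "eliminated_multiple"
  call[is.na(call)] <- "nucleus"

  out <- dplyr::mutate(m, relative_area = rel_area, relative_dna = rel_dna,
                       call = call)
  attr(out, "reference_area") <- ref_area
  attr(out, "median_rid") <- median_rid
  out
}

#' Summarize the calls of one field
#'
#' Counts calls by category and computes the average cellular DNA of the
#' field: the mean raw integrated density over retained ROIs (nuclei plus
#' NETs). Fields with no retained ROI get `NA` for the average.
#'
#' @param calls Tibble from [classify_rois()].
#' @param measurements Optional measurements tibble; only needed when `calls`
#'   lacks a `raw_integrated_density` column.
#' @return One-row tibble: identity columns, `n_retained`, `n_nets`,
#'   `n_nuclei`, `n_fragment`, `n_multiple`, `n_border`, `reference_area`,
#'   `average_cellular_dna`.
#' @export
field_summary <- function(calls, measurements = NULL) {
  if (!"raw_integrated_density" %in% names(calls) && !is.null(measurements)) {
    calls <- dplyr::left_join(calls, measurements, by = "roi_id")
  }
  ref <- attr(calls, "reference_area")
  if (is.null(ref)) ref <- NA_real_
  counts <- table(factor(calls$call,
                         levels = c("nucleus", "net", "eliminated_fragment",
                                    "eliminated_multiple", "eliminated_border")))
  retained <- calls$call %in% c("nucleus", "net")
  tibble::tibble(
    slide_id = if (nrow(calls) > 0L) calls$slide_id[1L] else NA_character_,
    condition = if (nrow(calls) > 0L) calls$condition[1L] else NA_character_,
    field_index = if (nrow(calls) > 0L) calls$field_index[1L] else NA_integer_,
    n_retained = as.integer(counts[["nucleus"]] + counts[["net"]]),
    n_nets = as.integer(counts[["net"]]),
    n_nuclei = as.integer(counts[["nucleus"]]),
    n_fragment = as.integer(counts[["eliminated_fragment"]]),
    n_multiple = as.integer(counts[["eliminated_multiple"]]),
    n_border = as.integer(counts[["eliminated_border"]]),
    reference_area = ref,
    average_cellular_dna = if (any(retained)) {
      mean(calls$raw_integrated_density[retained])
    } else NA_real_
  )
}

#' Pool field results into a per-slide NET percentage
#'
#' The NET formation percentage of a slide is pooled across its fields:
#' `100 * sum(n_nets) / sum(n_retained)` — NET-like structures divided by the
#' total number of neutrophils, not a mean of per-field percentages. Slides
#' with zero retained ROIs get `NA` and must be reviewed manually.
#'
#' @param field_results Tibble of [field_summary()] rows sharing one
#'   `slide_id` and `condition` (a `group` column, if present, is carried
#'   through).
#' @return One-row tibble: `slide_id`, `condition`, `group`, `n_fields`,
#'   `total_retained`, `total_nets`, `net_percent`.
#' @export
slide_summary <- function(field_results) {
  stopifnot(nrow(field_results) > 0L)
  if (length(unique(field_results$slide_id)) != 1L ||
      length(unique(field_results$condition)) != 1L) {
    stop("field results must share one slide_id and condition", call. = FALSE)
  }
  total_retained <- sum(field_results$n_retained)
  total_nets <- sum(field_results$n_nets)
  tibble::tibble(
    slide_id = field_results$slide_id[1L],
    condition = field_results$condition[1L],
    group = if ("group" %in% names(field_results)) field_results$group[1L]
            else NA_character_,
    n_fields = nrow(field_results),
    total_retained = as.integer(total_retained),
    total_nets = as.integer(total_nets),
    net_percent = if (total_retained > 0L) 100 * total_nets / total_retained
                  else NA_real_
  )
}
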