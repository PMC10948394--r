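#' Construct a microscopy field object
#'
#' A `net_field` bundles one single-channel fluorescence image with its
#' identity within a study: slide, stimulation condition and field index.
#' Intensities are kept in their native integer range `[0, 2^bit_depth - 1]`;
#' nothing is rescaled at construction.
#'
#' @param pixels Numeric matrix of nonnegative intensities, at least 32 x 32.
#' @param bit_depth Integer, 8 or 16.
#' @param slide_id,condition Character identity labels.
#' @param field_index Integer field number within the slide (>= 1).
#' @param source_path Optional path the image was read from.
#' @return An object of class `net_field`.
#' @export
net_field <- function(pixels, bit_depth = 8L, slide_id = NA_character_,
                      condition = NA_character_, field_index = 1L,
                      source_path = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(dim(pixels) < 32L)) {
    stop("image must be at least 32 x 32; got ",
         paste(dim(pixels), collapse = " x "), call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  maxval <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > maxval) {
    stop("intensities must lie in [0, ", maxval, "]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         slide_id = as.character(slide_id), condition = as.character(condition),
         field_index = as.integer(field_index),
         source_path = as.character(source_path)),
    class = "net_field"
  )
}

#' @export
print.net_field <- function(x, ...) {
  cat("<net_field> ", nrow(x$pixels), "x", ncol(x$pixels), " ",
      x$bit_depth, "-bit  slide=", x$slide_id, " condition=", x$condition,
      " field=", x$field_index, "\n", sep = "")
  invisible(x)
}

#' Load one microscopy field from a TIFF or PNG file
#'
#' Reads a single-plane grayscale or RGB image and returns its intensities
#' unchanged in the native integer range. For RGB input one channel is
#' extracted; by DAPI convention this defaults to the blue channel (a
#' luminance conversion is never applied, so integrated densities keep their
#' meaning as summed stain signal).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param channel `"gray"` (require single-channel input), `"blue"` (default),
#'   `"red"`, `"green"`, or a 1-based channel index for RGB input.
#' @inheritParams net_field
#' @return A [net_field].
#' @export
load_field <- function(path, channel = "blue", slide_id = NA_character_,
                       condition = NA_character_, field_index = 1L) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path, " (",
                                             conditionMessage(e), ")", call. = FALSE))
    if (length(img) != 1L) {
      stop("unsupported format: multi-plane TIFF stack with ", length(img),
           " planes in ", path, call. = FALSE)
    }
    img <- img[[1L]]
    bits <- attr(img, "bits.per.sample")
    bit_depth <- if (!is.null(bits)) as.integer(bits) else 8L
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("unreadable PNG: ", path, " (",
                                             conditionMessage(e), ")", call. = FALSE))
    info <- attr(img, "info")
    bit_depth <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    # readPNG rescales to [0,1]; restore native integers
    img_attr <- attributes(img)
    img <- round(img * (2^bit_depth - 1))
    dim(img) <- img_attr$dim
  } else {
    stop("unsupported format: ", ext, " (expected TIFF or PNG)", call. = FALSE)
  }
  pixels <- extract_channel(img, channel, path)
  dim_p <- dim(pixels)
  attributes(pixels) <- NULL  # drop reader metadata, keep a bare matrix
  dim(pixels) <- dim_p
  net_field(pixels, bit_depth = bit_depth, slide_id = slide_id,
            condition = condition, field_index = as.integer(field_index),
            source_path = path)
}

extract_channel <- function(img, channel, path) {
  nd <- length(dim(img))
  if (nd == 2L || is.null(dim(img))) {
    if (is.null(dim(img))) dim(img) <- c(length(img), 1L)
    return(img)
  }
  if (nd != 3L || dim(img)[3L] > 4L) {
    stop("unsupported format: image of shape ",
         paste(dim(img), collapse = " x "), " in ", path, call. = FALSE)
  }
  nch <- dim(img)[3L]
  idx <- if (is.numeric(channel)) {
    as.integer(channel)
  } else {
    switch(match.arg(channel, c("blue", "red", "green", "gray")),
           gray = {
             if (nch > 1L) stop("unsupported format: expected single-channel image but ",
                                path, " has ", nch, " channels", call. = FALSE)
             1L
           },
           red = 1L, green = 2L, blue = 3L)
  }
  if (idx < 1L || idx > nch) {
    stop("channel index ", idx, " out of range for ", nch, "-channel image",
         call. = FALSE)
  }
  img[, , idx]
}

#' Load a slide manifest
#'
#' The manifest is the single source of study structure: which image file is
#' which field of which slide, condition and clinical/experimental group.
#' Required columns are `slide_id`, `condition`, `group`, `field_path`; an
#' optional `field_index` column is honoured, otherwise fields are numbered
#' in file order within each (slide, condition). Extra columns are ignored
#' with a warning.
#'
#' @param path CSV file with header `slide_id,condition,group,field_path`.
#' @param check_paths Verify every referenced image exists (default `TRUE`).
#' @return A tibble with columns `slide_id`, `condition`, `group`,
#'   `field_index`, `field_path`, ordered by slide, condition, field.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("slide_id", "condition", "group", "field_path")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    stop("manifest schema error: missing column(s) ",
         paste(missing, collapse = ", "), "; expected columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(m), c(required, "field_index"))
  if (length(extra) > 0L) {
    warning("ignoring unknown manifest column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  m <- dplyr::mutate(m, dplyr::across(dplyr::all_of(c("slide_id", "condition", "group")),
                                      as.character))
  if (!"field_index" %in% names(m)) {
    m <- m |>
      dplyr::group_by(.data$slide_id, .data$condition) |>
      dplyr::mutate(field_index = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  m <- m |>
    dplyr::mutate(field_index = as.integer(.data$field_index)) |>
    dplyr::select(dplyr::all_of(c("slide_id", "condition", "group",
                                  "field_index", "field_path"))) |>
    dplyr::arrange(.data$slide_id, .data$condition, .data$field_index)
  dup <- m |>
    dplyr::count(.data$slide_id, .data$condition, .data$field_index) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate manifest entries for (slide_id, condition, field_index): ",
         paste(sprintf("(%s, %s, %d)", dup$slide_id, dup$condition, dup$field_index),
               collapse = "; "), call. = FALSE)
  }
  if (check_paths) {
    base <- dirname(path)
    resolved <- ifelse(file.exists(m$field_path), m$field_path,
                       file.path(base, m$field_path))
    bad <- !file.exists(resolved)
    if (any(bad)) {
      stop("manifest references missing file(s): ",
           paste(utils::head(m$field_path[bad], 5L), collapse = ", "),
           call. = FALSE)
    }
    m$field_path <- resolved
  }
  m
}

#' Write the per-ROI, per-field and per-slide result tables
#'
#' Writes `rois.csv`, `fields.csv` and `slides.csv` with fixed column order.
#' Real-valued columns round-trip through the files to at least 6 decimal
#' places; integer columns round-trip exactly.
#'
#' @param results List with elements `rois`, `fields`, `slides` as produced by
#'   [quantify_study()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(is.list(results), all(c("rois", "fields", "slides") %in% names(results)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- c(rois = file.path(out_dir, "rois.csv"),
             fields = file.path(out_dir, "fields.csv"),
             slides = file.path(out_dir, "slides.csv"))
  schemas <- list(rois = roi_table_columns(), fields = field_table_columns(),
                  slides = slide_table_columns())
  for (nm in names(paths)) {
    tab <- as_result_table(results[[nm]], schemas[[nm]])
    readr::write_csv(tab, paths[[nm]], progress = FALSE)
  }
  invisible(paths)
}

roi_table_columns <- function() {
  c("slide_id", "condition", "field_index", "roi_id", "area_px",
    "raw_integrated_density", "aspect_ratio", "roundness", "solidity",
    "min_brightness", "max_brightness", "touches_border",
    "centroid_row", "centroid_col", "relative_area", "relative_dna", "call")
}

field_table_columns <- function() {
  c("slide_id", "condition", "field_index", "n_retained", "n_nets", "n_nuclei",
    "n_fragment", "n_multiple", "n_border", "reference_area",
    "average_cellular_dna", "status")
}

slide_table_columns <- function() {
  c("slide_id", "condition", "group", "n_fields", "total_retained",
    "total_nets", "net_percent", "manual_override", "final_net_percent")
}

as_result_table <- function(tab, columns) {
  if (is.null(tab) || nrow(tab) == 0L) {
    tab <- tibble::as_tibble(setNames(rep(list(logical(0)), length(columns)),
                                      columns))
    return(tab)
  }
  missing <- setdiff(columns, names(tab))
  for (nm in missing) tab[[nm]] <- NA
  dplyr::select(tab, dplyr::all_of(columns))
}
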