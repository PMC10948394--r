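#' Quantify NET formation for a whole study
#'
#' Runs segmentation, feature measurement, ROI classification and
#' per-field/per-slide aggregation for every entry of a slide manifest.
#' Failures on single fields (unreadable files, non-bimodal histograms under
#' the `error` policy) are recorded in the field table's `status` column and
#' skipped; they never abort the run.
#'
#' Fields with fewer border-surviving ROIs than
#' `config$min_rois_for_field_reference` do not estimate their own reference
#' statistics; they reuse the median raw integrated density and reference
#' area pooled over all ROIs of the same slide and condition, which keeps the
#' relative metrics stable on sparse fields.
#'
#' @param manifest A manifest tibble (see [load_manifest()]) or the path to a
#'   manifest CSV.
#' @param config A [net_config()].
#' @param quiet Suppress per-field progress messages (default `TRUE`).
#' @return A list of class `net_quantification` with tibbles `rois`, `fields`
#'   (including a `status` column, `"ok"` or the failure message) and
#'   `slides`.
#' @export
quantify_study <- function(manifest, config = net_config(), quiet = TRUE) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  required <- c("slide_id", "condition", "group", "field_index", "field_path")
  stopifnot(all(required %in% names(manifest)))
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)

  groups <- dplyr::group_split(dplyr::group_by(manifest, .data$slide_id,
                                               .data$condition))
  all_rois <- list(); all_fields <- list(); all_slides <- list()
  for (g in groups) {
    meas_list <- vector("list", nrow(g))
    status <- character(nrow(g))
    for (i in seq_len(nrow(g))) {
      res <- tryCatch({
        field <- load_field(g$field_path[i], channel = config$channel,
                            slide_id = g$slide_id[i],
                            condition = g$condition[i],
                            field_index = g$field_index[i])
        labels <- segment_field(field, config)
        measure_rois(field, labels)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        status[i] <- paste0("failed: ", conditionMessage(res))
        meas_list[i] <- list(NULL)
        if (!quiet) message(g$slide_id[i], "/", g$condition[i], " field ",
                            g$field_index[i], " ", status[i])
      } else {
        status[i] <- "ok"
        meas_list[[i]] <- res
        if (!quiet) message(g$slide_id[i], "/", g$condition[i], " field ",
                            g$field_index[i], ": ", nrow(res), " ROIs")
      }
    }
    ok <- which(status == "ok")
    pool <- dplyr::bind_rows(meas_list[ok])
    pooled_ref <- NULL
    if (nrow(pool) > 0L) {
      surv <- if (config$exclude_border) !pool$touches_border
              else rep(TRUE, nrow(pool))
      if (any(surv)) {
        pooled_ref <- tryCatch(reference_stats(pool[surv, , drop = FALSE], config),
                               error = function(e) NULL)
      }
    }
    field_rows <- vector("list", nrow(g))
    for (i in seq_len(nrow(g))) {
      if (status[i] != "ok") {
        field_rows[[i]] <- tibble::tibble(
          slide_id = g$slide_id[i], condition = g$condition[i],
          field_index = g$field_index[i], n_retained = NA_integer_,
          n_nets = NA_integer_, n_nuclei = NA_integer_,
          n_fragment = NA_integer_, n_multiple = NA_integer_,
          n_border = NA_integer_, reference_area = NA_real_,
          average_cellular_dna = NA_real_, status = status[i])
        next
      }
      m <- meas_list[[i]]
      surv_n <- if (config$exclude_border) sum(!m$touches_border) else nrow(m)
      use_pool <- surv_n < config$min_rois_for_field_reference &&
        !is.null(pooled_ref) && !is.na(pooled_ref$reference_area)
      calls <- classify_rois(m, config,
                             reference = if (use_pool) pooled_ref else NULL)
      all_rois[[length(all_rois) + 1L]] <- calls
      fs <- field_summary(calls)
      fs$status <- "ok"
      field_rows[[i]] <- fs
    }
    fields <- dplyr::bind_rows(field_rows)
    all_fields[[length(all_fields) + 1L]] <- fields
    ok_fields <- dplyr::filter(fields, .data$status == "ok")
    if (nrow(ok_fields) > 0L) {
      ok_fields$group <- g$group[1L]
      all_slides[[length(all_slides) + 1L]] <- slide_summary(ok_fields)
    }
  }
  structure(list(rois = dplyr::bind_rows(all_rois),
                 fields = dplyr::bind_rows(all_fields),
                 slides = dplyr::bind_rows(all_slides)),
            class = "net_quantification")
}

#' @export
print.net_quantification <- function(x, ...) {
  cat("<net_quantification> ", nrow(x$slides), " slide-condition(s), ",
      nrow(x$fields), " field(s), ", nrow(x$rois), " ROI(s)\n", sep = "")
  print(x$slides)
  invisible(x)
}

#' Run the quantification pipeline and write result tables
#'
#' Thin orchestration over [quantify_study()] and [write_results()]: loads
#' the manifest and optional YAML configuration, quantifies every field, and
#' writes `rois.csv`, `fields.csv`, `slides.csv` plus a `config_snapshot.yaml`
#' capturing the exact configuration and package version.
#'
#' @param manifest_path Manifest CSV path.
#' @param out_dir Output directory.
#' @param config_path Optional YAML configuration ([read_net_config()]).
#' @param quiet Passed to [quantify_study()].
#' @return Invisibly, the `net_quantification` object.
#' @export
run_quantify <- function(manifest_path, out_dir, config_path = NULL,
                         quiet = FALSE) {
  config <- if (is.null(config_path)) net_config() else read_net_config(config_path)
  result <- quantify_study(load_manifest(manifest_path), config, quiet = quiet)
  write_results(result, out_dir)
  write_config_snapshot(config, file.path(out_dir, "config_snapshot.yaml"))
  invisible(result)
}

#' Run the quality-control step on a slide table
#'
#' Merges manual recount overrides (if given), flags slides outside
#' `mean +/- k*SD` within their (group, condition) stratum, and writes
#' `qc_report.json` and `slides_final.csv`. Flagged slides without an
#' override keep the automated value and are marked `outlier_unreviewed` so
#' no data is silently dropped.
#'
#' @param slides_path `slides.csv` from [run_quantify()] (or a compatible
#'   tibble).
#' @param out_dir Output directory.
#' @param k Interval width in SDs (default 2).
#' @param overrides_path Optional CSV `slide_id,condition,manual_net_percent`.
#' @return Invisibly, a list with the final `slides` tibble and the
#'   `net_qc_report`.
#' @export
run_qc <- function(slides_path, out_dir, k = 2.0, overrides_path = NULL) {
  slides <- if (is.character(slides_path)) {
    readr::read_csv(slides_path, show_col_types = FALSE, progress = FALSE)
  } else slides_path
  slides <- apply_overrides(slides, overrides_path)
  report <- flag_outliers(slides, k = k)
  flagged_key <- paste(report$flagged$slide_id, report$flagged$condition)
  key <- paste(slides$slide_id, slides$condition)
  slides$qc_flag <- dplyr::case_when(
    slides$provenance == "manual" ~ "manual",
    key %in% flagged_key ~ "outlier_unreviewed",
    TRUE ~ "ok")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_qc_report(report, file.path(out_dir, "qc_report.json"))
  readr::write_csv(slides, file.path(out_dir, "slides_final.csv"),
                   progress = FALSE)
  invisible(list(slides = slides, report = report))
}

#' Run the Bland-Altman method comparison
#'
#' Reads paired by-eye and automated NET percentages, computes the agreement
#' summary (differences oriented by-eye minus automated) and writes
#' `bland_altman.csv` plus a plot.
#'
#' @param pairs_path CSV with columns `net_percent_eye`, `net_percent_auto`
#'   (extra identity columns are carried along but unused).
#' @param out_dir Output directory.
#' @param plot_format `"png"` (default) or `"svg"`.
#' @return Invisibly, the [bland_altman()] result.
#' @export
run_compare <- function(pairs_path, out_dir, plot_format = "png") {
  pairs <- if (is.character(pairs_path)) {
    readr::read_csv(pairs_path, show_col_types = FALSE, progress = FALSE)
  } else pairs_path
  res <- bland_altman(pairs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(glance(res), file.path(out_dir, "bland_altman.csv"),
                   progress = FALSE)
  bland_altman_plot(res, file.path(out_dir,
                                   paste0("bland_altman.", plot_format)))
  invisible(res)
}

#' Run the synthetic-study simulator
#'
#' Reads an optional YAML scene description and writes images, manifest and
#' ground truth via [simulate_study()]. The YAML may contain a `scene` block
#' (arguments of [scene_spec()]), a `slides` list (each with `slide_id`,
#' `condition`, `group`, `net_fraction`), `n_fields` and `seed`.
#'
#' @param out_dir Output directory.
#' @param spec_path Optional YAML path; defaults are used when `NULL`.
#' @param seed Master seed (overrides the YAML value when non-`NULL`).
#' @return Invisibly, the list returned by [simulate_study()].
#' @export
run_simulate <- function(out_dir, spec_path = NULL, seed = NULL) {
  y <- if (!is.null(spec_path)) yaml::read_yaml(spec_path) else list()
  spec <- do.call(scene_spec, y$scene %||% list())
  slides <- if (!is.null(y$slides)) {
    dplyr::bind_rows(lapply(y$slides, tibble::as_tibble))
  } else {
    formals(simulate_study)$slides |> eval()
  }
  simulate_study(out_dir, slides = slides,
                 n_fields = y$n_fields %||% 10L, spec = spec,
                 seed = seed %||% y$seed %||% 1L)
}
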