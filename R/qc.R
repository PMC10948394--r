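#' Flag outlier slides for visual recount
#'
#' Implements the supervised quality-control rule: within every
#' (group, condition) stratum, slides whose NET percentage falls strictly
#' outside `mean +/- k * SD` (sample SD, n - 1) are flagged for visual
#' reassessment. Strata with fewer than 3 slides cannot support the rule and
#' are reported as unflaggable.
#'
#' @param slide_results Tibble with columns `slide_id`, `condition`, `group`
#'   and a NET percentage column (`final_net_percent` if present, else
#'   `net_percent`). Rows with `NA` percentages are ignored for the
#'   statistics and never flagged.
#' @param k Width of the acceptance interval in SDs (default 2).
#' @return A `net_qc_report`: list with `strata` (one row per stratum: `group`,
#'   `condition`, `n`, `mean`, `sd`, `lower`, `upper`, `flaggable`), `flagged`
#'   (slides outside their interval, with values and bounds), and `k`.
#' @export
flag_outliers <- function(slide_results, k = 2.0) {
  value_col <- if ("final_net_percent" %in% names(slide_results)) {
    "final_net_percent"
  } else "net_percent"
  d <- slide_results |>
    dplyr::mutate(.value = .data[[value_col]]) |>
    dplyr::filter(!is.na(.data$.value))
  strata <- d |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$.value),
      sd = ifelse(dplyr::n() > 1L, stats::sd(.data$.value), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lower = .data$mean - k * .data$sd,
      upper = .data$mean + k * .data$sd,
      flaggable = .data$n >= 3L
    )
  flagged <- d |>
    dplyr::inner_join(dplyr::filter(strata, .data$flaggable),
                      by = c("group", "condition")) |>
    dplyr::filter(.data$.value < .data$lower | .data$.value > .data$upper) |>
    dplyr::select(dplyr::all_of(c("slide_id", "condition", "group")),
                  net_percent = ".value", "lower", "upper") |>
    dplyr::arrange(.data$group, .data$condition, .data$slide_id)
  structure(list(strata = strata, flagged = flagged, k = k,
                 value_column = value_col),
            class = "net_qc_report")
}

#' @export
print.net_qc_report <- function(x, ...) {
  cat("<net_qc_report> mean +/- ", x$k, " SD within (group, condition)\n",
      sep = "")
  cat(nrow(x$strata), "strata;", nrow(x$flagged), "slide(s) flagged\n")
  if (nrow(x$flagged) > 0L) print(x$flagged)
  invisible(x)
}

#' @export
tidy.net_qc_report <- function(x, ...) {
  dplyr::mutate(x$strata,
                flagged_slides = purrr::map2_chr(.data$group, .data$condition,
                  function(g, cc) {
                    s <- x$flagged$slide_id[x$flagged$group == g &
                                            x$flagged$condition == cc]
                    paste(s, collapse = ";")
                  }))
}

#' @export
glance.net_qc_report <- function(x, ...) {
  tibble::tibble(k = x$k, n_strata = nrow(x$strata),
                 n_flaggable = sum(x$strata$flaggable),
                 n_flagged = nrow(x$flagged))
}

#' Merge manual recount overrides into slide results
#'
#' Where a flagged slide was visually recounted, the by-eye NET percentage
#' replaces the automated one in `final_net_percent`; the automated value is
#' always preserved in `net_percent` and the provenance recorded. Slides
#' without an override keep the automated value with provenance
#' `"automated"`. The operation is idempotent.
#'
#' @param slide_results Tibble with `slide_id`, `condition`, `net_percent`.
#' @param overrides Tibble (or CSV path) with columns `slide_id`, `condition`,
#'   `manual_net_percent` in `[0, 100]`.
#' @return `slide_results` with columns `manual_override`,
#'   `final_net_percent` and `provenance` (`"automated"` or `"manual"`).
#' @export
apply_overrides <- function(slide_results, overrides = NULL) {
  if (is.character(overrides)) {
    overrides <- readr::read_csv(overrides, show_col_types = FALSE,
                                 progress = FALSE)
  }
  out <- slide_results
  if (!"manual_override" %in% names(out)) out$manual_override <- NA_real_
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    required <- c("slide_id", "condition", "manual_net_percent")
    missing <- setdiff(required, names(overrides))
    if (length(missing) > 0L) {
      stop("override table missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    bad_val <- !is.na(overrides$manual_net_percent) &
      (overrides$manual_net_percent < 0 | overrides$manual_net_percent > 100)
    if (any(bad_val)) {
      stop("manual_net_percent outside [0, 100] for slide(s): ",
           paste(overrides$slide_id[bad_val], collapse = ", "), call. = FALSE)
    }
    key_res <- paste(out$slide_id, out$condition, sep = "\r")
    key_ovr <- paste(overrides$slide_id, overrides$condition, sep = "\r")
    unknown <- !key_ovr %in% key_res
    if (any(unknown)) {
      stop("override targets unknown slide/condition: ",
           paste(sprintf("(%s, %s)", overrides$slide_id[unknown],
                         overrides$condition[unknown]), collapse = "; "),
           call. = FALSE)
    }
    if (anyDuplicated(key_ovr)) {
      stop("duplicate override rows for the same (slide_id, condition)",
           call. = FALSE)
    }
    idx <- match(key_res, key_ovr)
    hit <- !is.na(idx)
    out$manual_override[hit] <- overrides$manual_net_percent[idx[hit]]
  }
  out$final_net_percent <- ifelse(is.na(out$manual_override), out$net_percent,
                                  out$manual_override)
  out$provenance <- ifelse(is.na(out$manual_override), "automated", "manual")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a QC report as JSON
#'
#' @param report A `net_qc_report` from [flag_outliers()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(
    list(k = report$k, value_column = report$value_column,
         strata = report$strata, flagged = report$flagged),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
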