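#' Bland-Altman agreement between two methods
#'
#' Quantifies agreement between paired measurements of the same quantity by
#' two methods (here: by-eye and automated NET percentages). The bias is the
#' mean of the per-pair differences `method1 - method2`, their sample SD
#' gives the 95% limits of agreement `bias +/- 1.96 * SD`. With differences
#' oriented by-eye minus automated, a positive bias reads "the automated
#' method undercounts".
#'
#' @param data Data frame of paired measurements.
#' @param method1,method2 Column names (tidy-eval) holding the two methods'
#'   values; defaults `net_percent_eye` and `net_percent_auto`.
#' @param multiplier Limits-of-agreement multiplier (default 1.96).
#' @return Object of class `bland_altman` with fields `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `multiplier`, `method1`, `method2`,
#'   `n_incomplete`, and `pairs` (tibble of per-pair `mean` and `difference`
#'   for plotting).
#' @export
bland_altman <- function(data, method1 = net_percent_eye,
                         method2 = net_percent_auto, multiplier = 1.96) {
  v1 <- dplyr::pull(data, {{ method1 }})
  v2 <- dplyr::pull(data, {{ method2 }})
  name1 <- rlang::as_name(rlang::enquo(method1))
  name2 <- rlang::as_name(rlang::enquo(method2))
  complete <- !is.na(v1) & !is.na(v2)
  n_incomplete <- sum(!complete)
  if (n_incomplete > 0L) {
    message("dropping ", n_incomplete, " incomplete pair(s)")
  }
  v1 <- v1[complete]; v2 <- v2[complete]
  n <- length(v1)
  if (n < 2L) {
    stop("Bland-Altman analysis needs at least 2 complete pairs; got ", n,
         call. = FALSE)
  }
  diffs <- v1 - v2
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  loa <- loa_from_summary(bias, sd_diff, multiplier = multiplier)
  structure(
    list(n = n, bias = bias, sd_diff = sd_diff,
         loa_low = loa[["loa_low"]], loa_high = loa[["loa_high"]],
         multiplier = multiplier, method1 = name1, method2 = name2,
         n_incomplete = n_incomplete,
         pairs = tibble::tibble(mean = (v1 + v2) / 2, difference = diffs)),
    class = "bland_altman"
  )
}

#' Limits of agreement from summary statistics
#'
#' Convenience entry point when only the printed bias and SD of differences
#' are available: the 95% limits of agreement are `bias +/- 1.96 * sd_diff`.
#'
#' @param bias Mean of paired differences.
#' @param sd_diff Sample SD of paired differences.
#' @param multiplier Interval half-width in SDs (default 1.96).
#' @return Named numeric vector `c(loa_low, loa_high)`.
#' @export
loa_from_summary <- function(bias, sd_diff, multiplier = 1.96) {
  c(loa_low = bias - multiplier * sd_diff,
    loa_high = bias + multiplier * sd_diff)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> ", x$method1, " - ", x$method2, ", n = ", x$n, "\n",
      sprintf("  bias (SD) = %.4g (%.4g)\n", x$bias, x$sd_diff),
      sprintf("  95%% limits of agreement = %.4g; %.4g\n", x$loa_low, x$loa_high),
      sep = "")
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("bias", "sd_diff", "loa_low", "loa_high"),
    estimate = c(x$bias, x$sd_diff, x$loa_low, x$loa_high)
  )
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 multiplier = x$multiplier, n_incomplete = x$n_incomplete)
}

#' @rdname bland_altman_plot
#' @param object A `bland_altman` result.
#' @param ... Unused.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", linewidth = 0.5) +
    ggplot2::labs(
      x = paste0("Mean of ", object$method1, " and ", object$method2),
      y = paste0("Difference (", object$method1, " - ", object$method2, ")"),
      title = sprintf("Bland-Altman: bias %.2f, 95%% LoA [%.2f, %.2f], n = %d",
                      object$bias, object$loa_low, object$loa_high, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Save a Bland-Altman plot
#'
#' Scatter of per-pair (mean, difference) with horizontal lines at the bias
#' and both limits of agreement.
#'
#' @param result A [bland_altman()] result.
#' @param out_path Output image path (extension picks the device, e.g.
#'   `.png` or `.svg`).
#' @param width,height Plot size in inches.
#' @return Invisibly, `out_path`.
#' @export
bland_altman_plot <- function(result, out_path, width = 5, height = 4) {
  stopifnot(inherits(result, "bland_altman"))
  p <- autoplot.bland_altman(result)
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = 150)
  invisible(out_path)
}
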