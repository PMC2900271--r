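# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-expression result
#'
#' @param x A `dge_de` object from [run_de()].
#' @param ... Unused.
#' @return The per-tag result tibble, sorted by adjusted p.
#' @method tidy dge_de
#' @export
tidy.dge_de <- function(x, ...) {
  x$table
}

#' One-row summary of a differential-expression result
#'
#' @param x A `dge_de` object.
#' @param ... Unused.
#' @return Tibble: `n_tags_tested`, `n_tags_filtered`, `dispersion`,
#'   `fdr_level`, `n_significant`.
#' @method glance dge_de
#' @export
glance.dge_de <- function(x, ...) {
  tibble::tibble(
    n_tags_tested = x$n_tags_tested,
    n_tags_filtered = x$n_tags_filtered,
    dispersion = x$dispersion,
    fdr_level = x$config$fdr_level,
    n_significant = sum(x$table$significant)
  )
}

#' Tidy a qPCR standard curve
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return Coefficient table of the underlying linear fit.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  co <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"]
  )
}

#' One-row summary of a qPCR standard curve
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return Tibble: `slope`, `intercept`, `r_squared`, `efficiency`.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, efficiency = x$efficiency)
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `dge_de` object.
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 adjusted p, significant
#'   tags highlighted.
#' @method autoplot dge_de
#' @export
autoplot.dge_de <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2_fc,
    y = -log10(pmax(.data$adj_p, .Machine$double.xmin)),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$config$fdr_level),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (post / pre)",
                  y = "-log10 adjusted p",
                  colour = paste0("FDR ≤ ", object$config$fdr_level)) +
    ggplot2::theme_minimal()
}

#' Standard-curve plot
#'
#' @param object A `standard_curve` object.
#' @param ... Unused.
#' @return A ggplot of Ct against log2 dilution with the fitted line.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  d <- dplyr::mutate(object$data, log2_dilution = log2(.data$dilution))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_dilution, .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "log2 dilution factor", y = "Ct",
                  subtitle = sprintf("slope %.3f, R² %.4f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Abundance-profile plot
#'
#' Cumulative share of annotated reads against gene rank: the long-tailed
#' shape of a transcriptome in which a handful of genes dominate.
#'
#' @param profile Output of [abundance_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_abundance_profile <- function(profile, ...) {
  d <- dplyr::mutate(profile, rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$cumulative_pct)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "gene rank (by total reads)",
                  y = "cumulative % of annotated reads") +
    ggplot2::theme_minimal()
}
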