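# qPCR validation: reference-gene standard curve, relative quantification,
# and paired t-tests on normalised quantities.

#' Fit a qPCR standard curve to a reference dilution series
#'
#' Least-squares fit of Ct against `log2(dilution factor)` for a serial
#' dilution of a reference sample (e.g. 1:1, 1:2, ..., 1:64). The slope is
#' in cycles per two-fold dilution; a perfectly efficient reaction has
#' slope 1 on this scale. Amplification efficiency per cycle is
#' `2^(1/|slope|) - 1`.
#'
#' @param dilution Dilution factors (1, 2, 4, ...); at least 3 distinct.
#' @param ct Observed Ct values, same length.
#'
#' @return Object of class `standard_curve`: `slope`, `intercept` (Ct at
#'   dilution 1), `r_squared`, `efficiency` (`NA` with a warning when the
#'   slope is 0), `data` (the input points), `model` (the `lm` fit).
#' @export
fit_standard_curve <- function(dilution, ct) {
  stopifnot(length(dilution) == length(ct))
  if (length(unique(dilution)) < 3L) {
    rlang::abort("need at least 3 distinct dilution points.")
  }
  if (any(dilution <= 0) || any(ct <= 0)) {
    rlang::abort("dilution factors and Ct values must be positive.")
  }
  d <- tibble::tibble(log2_dilution = log2(dilution), ct = ct)
  fit <- stats::lm(ct ~ log2_dilution, data = d)
  slope <- unname(stats::coef(fit)[2L])
  # suppressWarnings: summary.lm warns on exactly collinear (perfect) fits,
  # which are expected for noise-free validation series
  r2 <- suppressWarnings(summary(fit)$r.squared)
  eff <- if (abs(slope) < 1e-12) {
    rlang::warn("flat standard curve (slope 0); efficiency undefined.")
    NA_real_
  } else {
    2^(1 / abs(slope)) - 1
  }
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2, efficiency = eff,
         data = tibble::tibble(dilution = dilution, ct = ct), model = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: slope %.3f cycles/log2-dilution, intercept %.2f, R^2 %.4f, efficiency %s\n",
    x$slope, x$intercept, x$r_squared,
    if (is.na(x$efficiency)) "NA" else sprintf("%.3f", x$efficiency)
  ))
  invisible(x)
}

#' Interpolate relative quantities from a standard curve and normalise
#'
#' Duplicate wells are averaged (arithmetic mean Ct) per (sample, gene),
#' each Ct is converted to a relative quantity
#' `2^((intercept - ct) / slope)` on the curve's concentration scale, and
#' each target quantity is divided by the reference-gene quantity of the
#' same sample. Samples missing the reference gene are dropped with a
#' warning. Normalised quantities are invariant to any per-sample scaling.
#'
#' @param ct_table Tibble `sample_id`, `subject_id`, `timepoint`, `gene_id`,
#'   `replicate`, `ct`.
#' @param curve A [fit_standard_curve()] object.
#' @param reference_gene Gene id of the reference (normaliser).
#'
#' @return Tibble `sample_id`, `subject_id`, `timepoint`, `gene_id`,
#'   `quantity`, `norm_quantity` (reference rows have `norm_quantity` 1).
#' @export
relative_quantify <- function(ct_table, curve, reference_gene) {
  stopifnot(inherits(curve, "standard_curve"))
  needed <- c("sample_id", "subject_id", "timepoint", "gene_id", "ct")
  stopifnot(all(needed %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) rlang::abort("Ct values must be positive.")
  if (abs(curve$slope) < 1e-12) {
    rlang::abort("cannot quantify on a flat standard curve.")
  }
  mean_ct <- ct_table |>
    dplyr::group_by(.data$sample_id, .data$subject_id, .data$timepoint,
                    .data$gene_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    dplyr::mutate(quantity = 2^((curve$intercept - .data$ct) / curve$slope))
  ref <- mean_ct |>
    dplyr::filter(.data$gene_id == reference_gene) |>
    dplyr::select("sample_id", ref_quantity = "quantity")
  no_ref <- setdiff(unique(mean_ct$sample_id), ref$sample_id)
  if (length(no_ref) > 0L) {
    rlang::warn(paste0("dropping sample(s) without reference Ct: ",
                       paste(no_ref, collapse = ", ")))
  }
  mean_ct |>
    dplyr::inner_join(ref, by = "sample_id") |>
    dplyr::mutate(norm_quantity = .data$quantity / .data$ref_quantity) |>
    dplyr::select("sample_id", "subject_id", "timepoint", "gene_id",
                  "quantity", "norm_quantity")
}

#' Paired t-test and fold change for one gene's normalised quantities
#'
#' Pairs pre/post normalised quantities by subject, computes the fold change
#' as the ratio of the post mean to the pre mean, and a two-sided paired
#' Student's t-test on per-subject differences (df = number of pairs - 1).
#' The test runs on linear quantities by default, matching a
#' ratio-of-means fold-change report; set `log2_scale = TRUE` to test log2
#' quantities instead.
#'
#' @param quantities Output of [relative_quantify()] restricted to one gene,
#'   or any tibble with `subject_id`, `timepoint`, `norm_quantity`.
#' @param log2_scale Test log2-transformed quantities (default `FALSE`).
#'
#' @return One-row tibble: `n_pairs`, `fold_change`, `t_statistic`, `df`,
#'   `p`, `degenerate` (`TRUE` when the paired differences have zero
#'   variance, in which case `p` is `NA` and `t_statistic` is 0 for zero
#'   mean difference).
#' @export
paired_t_fc <- function(quantities, log2_scale = FALSE) {
  stopifnot(all(c("subject_id", "timepoint", "norm_quantity") %in%
                  names(quantities)))
  wide <- quantities |>
    dplyr::select("subject_id", "timepoint", "norm_quantity") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = "norm_quantity") |>
    tidyr::drop_na()
  if (!all(c("pre", "post") %in% names(wide)) || nrow(wide) < 2L) {
    rlang::abort("need at least 2 complete pre/post pairs.")
  }
  fc <- mean(wide$post) / mean(wide$pre)
  x <- if (log2_scale) log2(wide$post) else wide$post
  y <- if (log2_scale) log2(wide$pre) else wide$pre
  d <- x - y
  if (stats::sd(d) < 1e-12) {
    return(tibble::tibble(
      n_pairs = nrow(wide), fold_change = fc,
      t_statistic = if (abs(mean(d)) < 1e-12) 0 else NaN,
      df = nrow(wide) - 1L, p = NA_real_, degenerate = TRUE
    ))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    n_pairs = nrow(wide), fold_change = fc,
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, degenerate = FALSE
  )
}

#' Full qPCR validation: curve fit, quantification, per-gene paired tests
#'
#' @param ct_table Ct measurements (see [relative_quantify()]).
#' @param curve_table Tibble `dilution`, `ct` for the reference dilution
#'   series.
#' @param reference_gene Reference gene id (present in `ct_table`).
#' @param log2_scale Passed to [paired_t_fc()].
#'
#' @return Tibble, one row per non-reference gene: `gene_id`, `n_pairs`,
#'   `fold_change`, `t_statistic`, `df`, `p`, `degenerate`.
#' @export
run_qpcr <- function(ct_table, curve_table, reference_gene, log2_scale = FALSE) {
  curve <- fit_standard_curve(curve_table$dilution, curve_table$ct)
  quant <- relative_quantify(ct_table, curve, reference_gene)
  quant |>
    dplyr::filter(.data$gene_id != reference_gene) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(~ paired_t_fc(.x, log2_scale = log2_scale)) |>
    dplyr::ungroup()
}
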