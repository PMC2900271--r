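# Negative-binomial exact-test differential expression with a common
# dispersion shared across tags, and BH-FDR control.

#' Differential-expression configuration
#'
#' @param fdr_level FDR threshold for the `significant` flag (default 0.05).
#' @param dispersion_grid Candidate common-dispersion values; default 61
#'   log-spaced points spanning 1e-6 to 10.
#' @param prior_count Pseudocount (in TPM units) added to both group means
#'   before the log2 fold change (default 0.5).
#' @param min_total_count Tags with total count below this across all samples
#'   are excluded before testing (default 5).
#'
#' @return A list of class `de_config`.
#' @export
de_config <- function(fdr_level = 0.05,
                      dispersion_grid = 10^seq(-6, 1, length.out = 61),
                      prior_count = 0.5,
                      min_total_count = 5) {
  stopifnot(fdr_level > 0, fdr_level < 1, prior_count >= 0,
            all(dispersion_grid > 0), !is.unsorted(dispersion_grid))
  structure(
    list(fdr_level = fdr_level, dispersion_grid = dispersion_grid,
         prior_count = prior_count, min_total_count = min_total_count),
    class = "de_config"
  )
}

#' Estimate a common negative-binomial dispersion by grid profile likelihood
#'
#' A single dispersion phi is shared by all tags. For each candidate phi the
#' per-tag per-group fitted mean is `(group total / group library total) *
#' sample library size` (the conditional MLE of the mean under the model),
#' and the summed NB log-likelihood over all tags and samples is profiled;
#' the grid argmax is returned. Deterministic and oracle-checkable, unlike
#' quantile-conditional estimators.
#'
#' @param counts Long tibble `tag`, `sample_id`, `count`.
#' @param groups Tibble `sample_id`, `group` (two levels).
#' @param dispersion_grid Candidate values, sorted ascending.
#'
#' @return The grid value maximising the profile log-likelihood.
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       dispersion_grid = 10^seq(-6, 1, length.out = 61)) {
  wide <- counts_to_matrix(counts)
  if (sum(wide) == 0) {
    rlang::abort("all-zero count matrix; cannot estimate dispersion.")
  }
  grp <- groups$group[match(colnames(wide), groups$sample_id)]
  if (anyNA(grp)) rlang::abort("`groups` must cover every sample in `counts`.")
  lib <- colSums(wide)
  mu <- matrix(0, nrow(wide), ncol(wide))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    gtot <- rowSums(wide[, cols, drop = FALSE])
    glib <- sum(lib[cols])
    mu[, cols] <- outer(gtot / glib, lib[cols])
  }
  pos <- mu > 0
  y <- wide[pos]
  m <- mu[pos]
  ll <- vapply(dispersion_grid, function(phi) {
    sum(stats::dnbinom(y, size = 1 / phi, mu = m, log = TRUE))
  }, numeric(1))
  dispersion_grid[which.max(ll)]
}

#' Conditional split probabilities for the NB exact test
#'
#' Given group sums with total `T = sum_a + sum_b`, library-equalised
#' samples, and common dispersion `phi`, returns the probability of every
#' split `(a, T - a)` conditional on the total. Group sums are NB with size
#' `n/phi`; the common mean parameter cancels under conditioning. In the
#' `phi -> 0` limit this is the binomial `(T, n_a/(n_a+n_b))` distribution.
#'
#' @param total Total count `T` (nonnegative integer).
#' @param n_a,n_b Number of (equalised) samples in each group.
#' @param phi Common dispersion (>= 0).
#'
#' @return Numeric vector of length `total + 1`; probabilities of
#'   `a = 0..total`, summing to 1.
#' @export
nb_split_probs <- function(total, n_a, n_b, phi) {
  stopifnot(total >= 0, n_a >= 1, n_b >= 1, phi >= 0)
  a <- 0:total
  if (phi < 1e-10) {
    return(stats::dbinom(a, total, n_a / (n_a + n_b)))
  }
  mu <- max(total / (n_a + n_b), 1e-8)
  lp <- stats::dnbinom(a, size = n_a / phi, mu = n_a * mu, log = TRUE) +
    stats::dnbinom(total - a, size = n_b / phi, mu = n_b * mu, log = TRUE)
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Negative-binomial exact test for a two-group count split
#'
#' Conditions on the total count of a tag across both groups and enumerates
#' every possible split between groups. The two-sided p-value is the sum of
#' the probabilities of all splits no more probable than the observed one
#' (probability ordering, the standard construction for exact conditional
#' tests with asymmetric split distributions). Counts must be pre-scaled to
#' a common effective library size so that group sums are exchangeable up to
#' group size.
#'
#' @param sum_a,sum_b Observed group sums (equalised counts).
#' @param n_a,n_b Samples per group.
#' @param phi Common dispersion.
#'
#' @return p-value in (0, 1]. `sum_a + sum_b == 0` gives 1.
#' @export
nb_exact_test <- function(sum_a, n_a, sum_b, n_b, phi) {
  total <- sum_a + sum_b
  if (total == 0) {
    return(1)
  }
  p <- nb_split_probs(total, n_a, n_b, phi)
  p_obs <- p[sum_a + 1L]
  # relative tolerance so floating-point ties (e.g. symmetric splits) count
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` keeping the edge cases
#' explicit: empty input returns empty output, and inputs are validated to
#' lie in `[0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) {
    return(numeric())
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("p-values must be in [0, 1] and non-missing.")
  }
  stats::p.adjust(p, method = "BH")
}

#' Scale counts to a common effective library size
#'
#' Counts are scaled to the geometric mean library size and rounded to the
#' nearest integer — a simplification of quantile-based equalisation,
#' adequate when library sizes are within a few-fold of each other.
#'
#' @param counts Long tibble `tag`, `sample_id`, `count`.
#' @param library_sizes Optional tibble `sample_id`, `library_size`; default
#'   column sums of `counts`.
#'
#' @return List: `counts` (equalised long tibble), `effective_size`.
#' @export
equalize_libraries <- function(counts, library_sizes = NULL) {
  if (is.null(library_sizes)) {
    library_sizes <- counts |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(library_size = sum(.data$count), .groups = "drop")
  }
  if (any(library_sizes$library_size <= 0)) {
    rlang::abort("every sample needs a positive library size to equalise.")
  }
  target <- exp(mean(log(library_sizes$library_size)))
  eq <- counts |>
    dplyr::left_join(library_sizes, by = "sample_id") |>
    dplyr::mutate(count = as.integer(round(.data$count * target / .data$library_size))) |>
    dplyr::select("tag", "sample_id", "count")
  list(counts = eq, effective_size = target)
}

#' Two-group differential expression of tag counts
#'
#' Runs the full exact-test pipeline: low-count filtering, common-dispersion
#' estimation, library equalisation, per-tag NB exact test on group sums,
#' TPM-based log2 fold changes with a pseudocount, and BH-FDR adjustment.
#' Pairing of subjects is not modelled (classic unpaired two-group
#' comparison); subject identifiers, when present in `samples`, are carried
#' as metadata only.
#'
#' @param counts Long tibble `tag`, `sample_id`, `count` of unambiguous tag
#'   counts (e.g. `match_and_count()$counts`).
#' @param samples Tibble `sample_id`, `timepoint` (`pre`/`post`), optionally
#'   `subject_id`.
#' @param config A [de_config()].
#'
#' @return Object of class `dge_de`: list with `table` (tibble sorted by
#'   `adj_p`: `tag`, `mean_tpm_pre`, `mean_tpm_post`, `log2_fc`, `p`,
#'   `adj_p`, `significant`), `dispersion`, `n_tags_tested`,
#'   `n_tags_filtered`, `config`, `samples`.
#' @export
run_de <- function(counts, samples, config = de_config()) {
  stopifnot(inherits(config, "de_config"))
  if (!all(c("sample_id", "timepoint") %in% names(samples))) {
    rlang::abort("`samples` needs columns sample_id and timepoint.")
  }
  if (!all(samples$timepoint %in% c("pre", "post"))) {
    rlang::abort("`timepoint` must be 'pre' or 'post'.")
  }
  if (length(unique(samples$timepoint)) < 2L) {
    rlang::abort("both timepoints must be present.")
  }
  counts <- dplyr::semi_join(counts, samples, by = "sample_id")
  lib <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(library_size = sum(.data$count), .groups = "drop") |>
    tidyr::complete(sample_id = samples$sample_id,
                    fill = list(library_size = 0L))
  grp_lib <- dplyr::left_join(lib, samples, by = "sample_id") |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(total = sum(.data$library_size), .groups = "drop")
  if (any(grp_lib$total == 0)) {
    rlang::abort("a timepoint group has zero total library size.")
  }

  totals <- counts |>
    dplyr::group_by(.data$tag) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  kept <- totals$tag[totals$total >= config$min_total_count]
  n_filtered <- nrow(totals) - length(kept)
  counts_f <- dplyr::filter(counts, .data$tag %in% kept)
  if (nrow(counts_f) == 0L) {
    rlang::abort("no tags pass the minimum total count filter.")
  }

  groups <- dplyr::transmute(samples, sample_id = .data$sample_id,
                             group = .data$timepoint)
  phi <- estimate_common_dispersion(counts_f, groups, config$dispersion_grid)

  eq <- equalize_libraries(counts_f, lib)
  wide_eq <- counts_to_matrix(eq$counts, all_samples = samples$sample_id)
  grp <- samples$timepoint[match(colnames(wide_eq), samples$sample_id)]
  n_pre <- sum(grp == "pre")
  n_post <- sum(grp == "post")
  sum_pre <- rowSums(wide_eq[, grp == "pre", drop = FALSE])
  sum_post <- rowSums(wide_eq[, grp == "post", drop = FALSE])
  pvals <- vapply(seq_along(sum_pre), function(i) {
    nb_exact_test(sum_post[i], n_post, sum_pre[i], n_pre, phi)
  }, numeric(1))

  wide_raw <- counts_to_matrix(counts_f, all_samples = samples$sample_id)
  libs <- lib$library_size[match(colnames(wide_raw), lib$sample_id)]
  tpm <- sweep(wide_raw, 2, ifelse(libs > 0, libs, 1), "/") * 1e6
  grp_raw <- samples$timepoint[match(colnames(wide_raw), samples$sample_id)]
  mean_pre <- rowMeans(tpm[, grp_raw == "pre", drop = FALSE])
  mean_post <- rowMeans(tpm[, grp_raw == "post", drop = FALSE])

  tab <- tibble::tibble(
    tag = rownames(wide_eq),
    mean_tpm_pre = unname(mean_pre[rownames(wide_eq)]),
    mean_tpm_post = unname(mean_post[rownames(wide_eq)]),
    log2_fc = unname(log2((mean_post[rownames(wide_eq)] + config$prior_count) /
                            (mean_pre[rownames(wide_eq)] + config$prior_count))),
    p = pvals
  ) |>
    dplyr::mutate(
      adj_p = bh_adjust(.data$p),
      significant = .data$adj_p <= config$fdr_level
    ) |>
    dplyr::arrange(.data$adj_p, .data$p, .data$tag)

  structure(
    list(table = tab, dispersion = phi,
         n_tags_tested = nrow(tab), n_tags_filtered = n_filtered,
         config = config, samples = tibble::as_tibble(samples)),
    class = "dge_de"
  )
}

#' @export
print.dge_de <- function(x, ...) {
  cat("Tag-level differential expression (NB exact test)\n")
  cat(sprintf("  tags tested: %d (filtered: %d)\n",
              x$n_tags_tested, x$n_tags_filtered))
  cat(sprintf("  common dispersion: %.4g\n", x$dispersion))
  cat(sprintf("  significant at FDR %.2g: %d\n",
              x$config$fdr_level, sum(x$table$significant)))
  invisible(x)
}

counts_to_matrix <- function(counts, all_samples = NULL) {
  wide <- counts |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L, id_cols = "tag")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$tag
  if (!is.null(all_samples)) {
    extra <- setdiff(all_samples, colnames(m))
    if (length(extra) > 0L) {
      m <- cbind(m, matrix(0L, nrow(m), length(extra),
                           dimnames = list(NULL, extra)))
    }
    m <- m[, all_samples, drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}
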