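# Term overrepresentation (EASE-penalised Fisher) and ranked-list
# segmentation enrichment with BH correction.

#' One-tailed Fisher/hypergeometric overrepresentation test with EASE penalty
#'
#' Tests whether a foreground gene set is enriched for a term relative to a
#' background universe, via the hypergeometric upper-tail probability
#' `P(X >= hits)`. With `ease_penalty` the observed hit count is reduced by
#' one (floored at zero) before the tail computation — the conservative EASE
#' score, which guards against terms carried by a single gene. Fold
#' enrichment is always computed from unpenalised counts.
#'
#' @param fg_genes Foreground gene ids (subset of `bg_genes`).
#' @param bg_genes Background universe gene ids.
#' @param term_genes Gene ids annotated to the term (subset of `bg_genes`).
#' @param ease_penalty Apply the EASE hit reduction (default `TRUE`).
#'
#' @return One-row tibble: `hits`, `fg_size`, `bg_hits`, `bg_size`,
#'   `fold_enrichment`, `p`.
#' @export
fisher_overrep <- function(fg_genes, bg_genes, term_genes, ease_penalty = TRUE) {
  fg_genes <- unique(fg_genes)
  bg_genes <- unique(bg_genes)
  term_genes <- unique(term_genes)
  if (length(fg_genes) == 0L) rlang::abort("empty foreground gene set.")
  if (!all(fg_genes %in% bg_genes)) {
    rlang::abort("foreground must be a subset of the background.")
  }
  term_genes <- intersect(term_genes, bg_genes)
  hits <- length(intersect(fg_genes, term_genes))
  fg_size <- length(fg_genes)
  bg_hits <- length(term_genes)
  bg_size <- length(bg_genes)
  eff_hits <- if (ease_penalty) max(hits - 1L, 0L) else hits
  p <- stats::phyper(eff_hits - 1L, bg_hits, bg_size - bg_hits, fg_size,
                     lower.tail = FALSE)
  fe <- if (bg_hits > 0L) (hits / fg_size) / (bg_hits / bg_size) else NA_real_
  tibble::tibble(
    hits = hits, fg_size = fg_size, bg_hits = bg_hits, bg_size = bg_size,
    fold_enrichment = fe, p = min(1, p)
  )
}

#' Scan an annotation set for overrepresented terms
#'
#' Applies [fisher_overrep()] to every term, adjusts across terms with BH,
#' and sorts by adjusted p. Terms with no background hits are skipped with a
#' warning. The background defaults to the full gene-model universe of the
#' experiment; pass it explicitly.
#'
#' @param fg_genes Foreground gene ids.
#' @param bg_genes Background universe.
#' @param annotation Tibble `term_id`, `gene_id` (long form; see
#'   [read_gmt()]), optionally with `term_name`.
#' @param fdr_level FDR threshold for the `significant` flag (default 0.05).
#' @param ease_penalty As in [fisher_overrep()] (default `TRUE`).
#'
#' @return Tibble, one row per tested term, sorted by `adj_p`: term columns
#'   plus `hits`, `fg_size`, `bg_hits`, `bg_size`, `fold_enrichment`, `p`,
#'   `adj_p`, `significant`.
#' @export
ease_scan <- function(fg_genes, bg_genes, annotation, fdr_level = 0.05,
                      ease_penalty = TRUE) {
  empty <- tibble::tibble(
    term_id = character(), hits = integer(), fg_size = integer(),
    bg_hits = integer(), bg_size = integer(), fold_enrichment = double(),
    p = double(), adj_p = double(), significant = logical()
  )
  if (is.null(annotation) || nrow(annotation) == 0L) {
    return(empty)
  }
  terms <- split(annotation$gene_id, annotation$term_id)
  bg_genes <- unique(bg_genes)
  usable <- vapply(terms, function(g) length(intersect(g, bg_genes)) > 0L,
                   logical(1))
  if (any(!usable)) {
    rlang::warn(paste0(sum(!usable),
                       " term(s) with zero background hits skipped."))
  }
  terms <- terms[usable]
  if (length(terms) == 0L) {
    return(empty)
  }
  rows <- purrr::imap(terms, function(genes, id) {
    dplyr::mutate(
      fisher_overrep(fg_genes, bg_genes, genes, ease_penalty = ease_penalty),
      term_id = id, .before = 1
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(adj_p = bh_adjust(.data$p),
                  significant = .data$adj_p <= fdr_level) |>
    dplyr::arrange(.data$adj_p, .data$p, .data$term_id)
  if ("term_name" %in% names(annotation)) {
    meta <- dplyr::distinct(annotation, .data$term_id, .data$term_name)
    out <- dplyr::left_join(out, meta, by = "term_id") |>
      dplyr::relocate("term_name", .after = "term_id")
  }
  out
}

#' Ranked-list segmentation enrichment (FatiScan-style)
#'
#' Detects terms whose genes are asymmetrically distributed along a ranked
#' gene list (e.g. ranked by differential expression). The list is cut at
#' `n_partitions` evenly spaced rank positions; at each cut every term is
#' tested with a two-sided Fisher's exact test on the 2x2 table (top block
#' vs bottom block) x (in term vs not). BH adjustment is applied across the
#' full term-by-partition family (conservative), and each term reports its
#' minimum adjusted p, the cut achieving it, and the direction (`up` when
#' the term is overrepresented above the cut). Rank-based, hence invariant
#' to monotone transformations of the scores.
#'
#' @param ranked Tibble `gene_id`, `score`; ranked by `score` descending
#'   (ties broken by `gene_id`). Gene ids must be unique.
#' @param annotation Tibble `term_id`, `gene_id`; genes absent from the
#'   ranked list are ignored, terms with fewer than 2 remaining genes are
#'   skipped.
#' @param n_partitions Number of evenly spaced cut points (default 30); the
#'   realised cut set is symmetrised so reversing the ranking visits the
#'   same partitions.
#' @param fdr_level FDR threshold for the `significant` flag.
#'
#' @return Tibble, one row per tested term, sorted by `adj_p`: `term_id`,
#'   `best_partition` (rank index of the cut), `direction`, `hits_top`,
#'   `top_size`, `hits_total`, `n_genes`, `p`, `adj_p`, `significant`.
#' @export
fatiscan <- function(ranked, annotation, n_partitions = 30, fdr_level = 0.05) {
  stopifnot(all(c("gene_id", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene_id)) {
    rlang::abort("`ranked` gene ids must be unique.")
  }
  ord <- order(-ranked$score, ranked$gene_id)
  genes <- ranked$gene_id[ord]
  n <- length(genes)
  if (n_partitions < 1 || n_partitions >= n) {
    rlang::abort("`n_partitions` must be in [1, length(ranked) - 1].")
  }
  cuts <- round(seq_len(n_partitions) * n / (n_partitions + 1))
  cuts <- unique(pmin(pmax(cuts, 1L), n - 1L))
  cuts <- sort(unique(c(cuts, n - cuts)))

  empty <- tibble::tibble(
    term_id = character(), best_partition = integer(), direction = character(),
    hits_top = integer(), top_size = integer(), hits_total = integer(),
    n_genes = integer(), p = double(), adj_p = double(), significant = logical()
  )
  if (is.null(annotation) || nrow(annotation) == 0L) {
    return(empty)
  }
  terms <- split(annotation$gene_id, annotation$term_id)
  terms <- purrr::map(terms, ~ intersect(unique(.x), genes))
  terms <- terms[vapply(terms, length, integer(1)) >= 2L]
  if (length(terms) == 0L) {
    return(empty)
  }

  rank_of <- stats::setNames(seq_len(n), genes)
  tests <- purrr::imap(terms, function(tg, id) {
    r <- sort(rank_of[tg])
    total <- length(r)
    purrr::map(cuts, function(k) {
      a <- sum(r <= k)                       # term genes in the top block
      tab <- matrix(c(a, k - a, total - a, n - k - (total - a)), 2L)
      list(term_id = id, cut = k, hits_top = a, top_size = k,
           hits_total = total,
           p = stats::fisher.test(tab)$p.value)
    })
  })
  flat <- dplyr::bind_rows(purrr::flatten(tests))
  flat$adj_p <- bh_adjust(flat$p)

  flat |>
    dplyr::group_by(.data$term_id) |>
    dplyr::arrange(.data$adj_p, .data$p, .data$cut, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      term_id = .data$term_id,
      best_partition = as.integer(.data$cut),
      direction = dplyr::if_else(
        .data$hits_top / .data$top_size > .data$hits_total / n, "up", "down"
      ),
      hits_top = as.integer(.data$hits_top),
      top_size = as.integer(.data$top_size),
      hits_total = as.integer(.data$hits_total),
      n_genes = n,
      p = .data$p,
      adj_p = .data$adj_p,
      significant = .data$adj_p <= fdr_level
    ) |>
    dplyr::arrange(.data$adj_p, .data$p, .data$term_id)
}

#' Ranking score for segmentation enrichment of a DE result
#'
#' The conventional signed significance score `sign(log2_fc) * -log10(p)`:
#' strongly up-regulated tags rank first, strongly down-regulated last.
#'
#' @param de_table A tibble with `log2_fc` and `p` (e.g. `tidy(run_de(...))`)
#'   plus a `gene_id` column.
#' @return Tibble `gene_id`, `score` suitable for [fatiscan()]; for genes
#'   represented by several tags the largest-magnitude score is kept.
#' @export
de_ranking <- function(de_table) {
  stopifnot(all(c("gene_id", "log2_fc", "p") %in% names(de_table)))
  de_table |>
    dplyr::mutate(score = sign(.data$log2_fc) *
                    -log10(pmax(.data$p, .Machine$double.xmin))) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(abs(.data$score)), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "score")
}

#' Read a GMT annotation file into long form
#'
#' @param path Path to a GMT file (term, description, genes...).
#' @return Tibble `term_id`, `term_name`, `gene_id`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      rlang::abort("GMT lines need at least term, description and one gene.")
    }
    tibble::tibble(term_id = f[1L], term_name = f[2L], gene_id = f[-(1:2)])
  })
  dplyr::bind_rows(rows)
}

#' Write long-form annotation to a GMT file
#'
#' @param annotation Tibble `term_id`, `gene_id`, optionally `term_name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotation, path) {
  if (!"term_name" %in% names(annotation)) {
    annotation$term_name <- annotation$term_id
  }
  lines <- annotation |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(genes = paste(.data$gene_id, collapse = "\t"),
                     .groups = "drop") |>
    dplyr::arrange(.data$term_id) |>
    dplyr::mutate(line = paste(.data$term_id, .data$term_name, .data$genes,
                               sep = "\t")) |>
    dplyr::pull(.data$line)
  readr::write_lines(lines, path)
  invisible(path)
}
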