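# Read filtering, exact tag matching, count matrices, TPM and abundance
# profiling.

#' Quality-filter 17 nt tag reads
#'
#' Accepts reads that are exactly `expected_length` nt, contain no `N`, and
#' whose base qualities are all at least `min_quality` (Phred). With
#' `strip_anchor`, reads of length `expected_length + 4` that begin with the
#' `CATG` anchor have the anchor removed first. The quality filter itself is
#' deliberately simple and configurable; default Q20.
#'
#' @param reads Path to a FASTQ file (optionally gzipped), or a data frame
#'   with columns `seq` and optionally `qual` (Phred+33 strings; when absent,
#'   reads are assumed to pass the quality threshold).
#' @param min_quality Minimum per-base Phred quality (default 20).
#' @param expected_length Tag length (default 17).
#' @param strip_anchor Strip a leading `CATG` from reads 4 nt longer than
#'   `expected_length` (default `FALSE`).
#'
#' @return A list: `tags` — tibble `tag`, `count` over accepted reads;
#'   `accounting` — one-row tibble with `n_raw` and `n_usable`.
#' @export
filter_reads <- function(reads, min_quality = 20, expected_length = 17L,
                         strip_anchor = FALSE) {
  if (is.character(reads) && length(reads) == 1L) {
    fq <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(reads, quality.scoring = "phred"),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    seqs <- as.character(fq)
    minq <- vapply(as(Biostrings::quality(fq), "IntegerList"), function(q) {
      if (length(q) == 0L) 0L else min(q)
    }, integer(1))
  } else if (is.data.frame(reads)) {
    if (!"seq" %in% names(reads)) {
      rlang::abort("`reads` data frame needs a `seq` column.")
    }
    seqs <- toupper(reads$seq)
    if ("qual" %in% names(reads)) {
      if (any(nchar(reads$qual) != nchar(seqs))) {
        bad <- which(nchar(reads$qual) != nchar(seqs))[1L]
        rlang::abort(paste0("malformed read record at index ", bad,
                            ": sequence/quality length mismatch."))
      }
      minq <- vapply(reads$qual, function(q) {
        if (!nzchar(q)) 0L else min(utf8ToInt(q)) - 33L
      }, integer(1), USE.NAMES = FALSE)
    } else {
      minq <- rep(93L, length(seqs))
    }
  } else {
    rlang::abort("`reads` must be a FASTQ path or a data frame with `seq`.")
  }

  n_raw <- length(seqs)
  if (strip_anchor) {
    has_anchor <- nchar(seqs) == expected_length + 4L &
      stringr::str_starts(seqs, stringr::fixed(ANCHOR))
    seqs[has_anchor] <- stringr::str_sub(seqs[has_anchor], 5L)
  }
  keep <- nchar(seqs) == expected_length &
    !stringr::str_detect(seqs, stringr::fixed("N")) &
    minq >= min_quality
  accepted <- seqs[keep]
  tags <- if (length(accepted) > 0L) {
    tibble::as_tibble(table(tag = accepted)) |>
      dplyr::transmute(tag = .data$tag, count = as.integer(.data$n))
  } else {
    tibble::tibble(tag = character(), count = integer())
  }
  list(
    tags = tags,
    accounting = tibble::tibble(n_raw = n_raw, n_usable = length(accepted))
  )
}

#' Match tags against a catalogue and build the count matrix
#'
#' Each distinct tag is classified into exactly one of four categories:
#' `cdna_unambiguous` (present in exactly one gene's transcripts),
#' `cdna_ambiguous` (present in two or more genes), `genomic_only` (absent
#' from cDNA but present in the genome digest), or `unmatched`. Matching is
#' exact — no mismatches are tolerated, since a single substitution in a
#' 17-mer usually produces a different (or no) catalogue entry. Only
#' unambiguous cDNA tags enter the returned matrix; a tag unique to one gene
#' stays `cdna_unambiguous` even when it also occurs in intergenic genome.
#'
#' @param tag_counts Long tibble `sample_id`, `tag`, `count` (e.g. stacked
#'   [filter_reads()] outputs).
#' @param catalog A `tag_catalog` from [build_catalog()].
#'
#' @return A list: `counts` — long tibble `tag`, `sample_id`, `count`
#'   restricted to unambiguous cDNA tags; `library_sizes` — tibble
#'   `sample_id`, `library_size` (total unambiguous cDNA reads, the
#'   "annotated reads" denominator for TPM); `accounting` — per-sample
#'   category read counts, their fractions of usable, and the overlapping
#'   `n_matched_genome` count.
#' @export
match_and_count <- function(tag_counts, catalog) {
  stopifnot(all(c("sample_id", "tag", "count") %in% names(tag_counts)))
  cdna <- dplyr::filter(catalog, .data$origin == "cdna")
  tag_class <- cdna |>
    dplyr::distinct(.data$tag, .data$n_gene_copies) |>
    dplyr::transmute(
      tag = .data$tag,
      category = dplyr::if_else(.data$n_gene_copies == 1L,
                                "cdna_unambiguous", "cdna_ambiguous")
    )
  genomic_tags <- unique(catalog$tag[catalog$origin == "genomic"])

  classified <- tag_counts |>
    dplyr::left_join(tag_class, by = "tag") |>
    dplyr::mutate(
      in_genome = .data$tag %in% genomic_tags,
      category = dplyr::case_when(
        !is.na(.data$category) ~ .data$category,
        .data$in_genome ~ "genomic_only",
        TRUE ~ "unmatched"
      )
    )

  samples <- unique(tag_counts$sample_id)
  cat_levels <- c("cdna_unambiguous", "cdna_ambiguous", "genomic_only", "unmatched")
  accounting <- classified |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_usable = sum(.data$count),
      n_matched_cdna = sum(.data$count[.data$category %in%
                                         c("cdna_unambiguous", "cdna_ambiguous")]),
      n_unambiguous_cdna = sum(.data$count[.data$category == "cdna_unambiguous"]),
      n_matched_genome = sum(.data$count[.data$in_genome]),
      !!!rlang::set_names(
        purrr::map(cat_levels,
                   ~ rlang::quo(sum(count[category == !!.x]))),
        paste0("n_", cat_levels)
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(paste0("n_", cat_levels)),
      ~ dplyr::if_else(.data$n_usable > 0, . / .data$n_usable, 0),
      .names = "frac_{sub('n_', '', .col)}"
    ))

  counts <- classified |>
    dplyr::filter(.data$category == "cdna_unambiguous") |>
    dplyr::group_by(.data$tag, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  library_sizes <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(library_size = sum(.data$count), .groups = "drop") |>
    tidyr::complete(sample_id = samples,
                    fill = list(library_size = 0L)) |>
    dplyr::mutate(library_size = as.integer(.data$library_size))

  list(counts = counts, library_sizes = library_sizes, accounting = accounting)
}

#' Collapse tag counts to gene counts and TPM
#'
#' Genes represented by multiple transcripts (hence possibly multiple
#' unambiguous tags, at any site rank) have their tag counts summed.
#' Tags-per-million uses each sample's unambiguous-cDNA library size:
#' `tpm = count / library_size * 1e6`, so TPM columns sum to one million
#' whenever the library size is nonzero.
#'
#' @param matched Output of [match_and_count()] (list with `counts` and
#'   `library_sizes`), or a long tibble `tag`, `sample_id`, `count` of
#'   unambiguous tags (library sizes then recomputed as column sums).
#' @param catalog The `tag_catalog` used for matching.
#'
#' @return Long tibble `gene_id`, `sample_id`, `count`, `tpm`.
#' @export
gene_counts_tpm <- function(matched, catalog) {
  if (is.data.frame(matched)) {
    counts <- matched
    library_sizes <- counts |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(library_size = sum(.data$count), .groups = "drop")
  } else {
    counts <- matched$counts
    library_sizes <- matched$library_sizes
  }
  tag2gene <- catalog |>
    dplyr::filter(.data$origin == "cdna", .data$n_gene_copies == 1L) |>
    dplyr::distinct(.data$tag, .data$gene_id)

  samples <- unique(library_sizes$sample_id)
  out <- counts |>
    dplyr::inner_join(tag2gene, by = "tag") |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(gene_id, sample_id = samples,
                    fill = list(count = 0L)) |>
    dplyr::left_join(library_sizes, by = "sample_id") |>
    dplyr::mutate(
      tpm = dplyr::if_else(.data$library_size > 0,
                           .data$count / .data$library_size * 1e6, 0)
    ) |>
    dplyr::select("gene_id", "sample_id", "count", "tpm")
  if (any(library_sizes$library_size == 0)) {
    rlang::warn("one or more samples have zero library size; their TPM is 0.")
  }
  out
}

#' Ranked gene abundance profile
#'
#' Ranks genes by total reads across all samples and reports each gene's
#' percentage share of the annotated transcriptome plus the running
#' cumulative share (the layout used to describe the most abundant
#' transcripts of a tissue).
#'
#' @param gene_counts Long tibble from [gene_counts_tpm()] (needs `gene_id`,
#'   `sample_id`, `count`).
#'
#' @return Tibble sorted by `total_reads` descending: `gene_id`,
#'   `total_reads`, `pct_all`, `cumulative_pct`.
#' @export
abundance_profile <- function(gene_counts) {
  totals <- gene_counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(total_reads = sum(.data$count), .groups = "drop")
  grand <- sum(totals$total_reads)
  if (grand == 0) {
    rlang::abort("all gene counts are zero; no abundance profile.")
  }
  totals |>
    dplyr::arrange(dplyr::desc(.data$total_reads), .data$gene_id) |>
    dplyr::mutate(
      pct_all = .data$total_reads / grand * 100,
      cumulative_pct = cumsum(.data$pct_all)
    )
}

#' Annotate tag genomic positions by proximity to gene spans
#'
#' Classifies each positioned tag as `intragenic` (anchor inside a gene
#' span), `proximal` (within `window` bp of the nearest span boundary,
#' strand-agnostic), or `unassigned`. Distances are measured to the 0-based
#' half-open span boundaries; ties at the minimum distance report every tied
#' gene (one row each).
#'
#' @param positions Tibble with `tag`, `chrom`, `pos` (0-based anchor).
#' @param gene_models Gene-model data frame (uses `gene_id`, `chrom`,
#'   `start`, `end`; transcript rows are collapsed to gene spans).
#' @param window Maximum distance in bp for `proximal` (default 5000).
#'
#' @return Tibble `tag`, `chrom`, `pos`, `category`, `gene_id`, `distance`
#'   (`NA` gene and distance for `unassigned`).
#' @export
proximity_annotate <- function(positions, gene_models, window = 5000) {
  stopifnot(all(c("tag", "chrom", "pos") %in% names(positions)))
  spans <- gene_models |>
    dplyr::group_by(.data$gene_id, .data$chrom) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  unknown <- setdiff(unique(positions$chrom), unique(spans$chrom))
  if (length(unknown) > 0L) {
    rlang::warn(paste0("chromosome(s) not in gene models: ",
                       paste(unknown, collapse = ", "),
                       "; their tags are unassigned."))
  }
  cand <- positions |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::left_join(spans, by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(
      distance = pmax(.data$start - .data$pos, .data$pos - .data$end, 0)
    ) |>
    dplyr::group_by(.data$.row) |>
    dplyr::filter(is.na(.data$distance) | .data$distance == min(.data$distance)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      category = dplyr::case_when(
        is.na(.data$distance) ~ "unassigned",
        .data$distance == 0 ~ "intragenic",
        .data$distance <= window ~ "proximal",
        TRUE ~ "unassigned"
      ),
      gene_id = dplyr::if_else(.data$category == "unassigned",
                               NA_character_, .data$gene_id),
      distance = dplyr::if_else(.data$category == "unassigned",
                                NA_real_, as.numeric(.data$distance))
    ) |>
    dplyr::distinct(.data$.row, .data$tag, .data$chrom, .data$pos,
                    .data$category, .data$gene_id, .data$distance)
  dplyr::select(cand, "tag", "chrom", "pos", "category", "gene_id", "distance")
}
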