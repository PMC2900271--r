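# In-silico NlaIII digestion: tag extraction, genome digestion, catalogue
# construction and catalogue-level statistics.

TAG_LEN <- 17L
ANCHOR <- "CATG"

#' Extract DGE tags from a transcript sequence
#'
#' Scans a transcript (5'->3' sense orientation) for NlaIII recognition sites
#' (`CATG`) and emits the 17 nt immediately 3' of each qualifying site. A site
#' qualifies when it has at least 17 nt of 3' flank and the resulting 17-mer
#' contains no `N`. Ranks are assigned from the 3' end: the 3'-most qualifying
#' site gets `site_rank = 1` (the *canonical* tag, the expected product of
#' oligo(dT) capture followed by the first NlaIII cut from the 3' end), with
#' ranks increasing upstream.
#'
#' @param sequence A single nucleotide string over `A`,`C`,`G`,`T`,`N`.
#'
#' @return A tibble with one row per qualifying site, ordered by `site_rank`:
#'   `tag` (17 nt, excludes the CATG anchor), `site_rank`, and `offset`
#'   (0-based position of the first base of the CATG anchor in the transcript).
#' @export
#'
#' @examples
#' extract_tags(paste0("AAACATG", strrep("T", 17), "GG"))
extract_tags <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    rlang::abort("`sequence` must be a single non-NA character string.")
  }
  sequence <- toupper(sequence)
  if (nzchar(sequence) && stringr::str_detect(sequence, "[^ACGTN]")) {
    rlang::abort("`sequence` contains characters outside {A,C,G,T,N}.")
  }
  empty <- tibble::tibble(
    tag = character(), site_rank = integer(), offset = integer()
  )
  if (!nzchar(sequence)) {
    return(empty)
  }
  starts <- stringr::str_locate_all(sequence, stringr::fixed(ANCHOR))[[1L]][, 1L]
  if (length(starts) == 0L) {
    return(empty)
  }
  tags <- stringr::str_sub(sequence, starts + 4L, starts + 3L + TAG_LEN)
  ok <- nchar(tags) == TAG_LEN & !stringr::str_detect(tags, stringr::fixed("N"))
  starts <- starts[ok]
  tags <- tags[ok]
  if (length(starts) == 0L) {
    return(empty)
  }
  ord <- order(starts, decreasing = TRUE)
  tibble::tibble(
    tag = tags[ord],
    site_rank = seq_along(ord),
    offset = as.integer(starts[ord] - 1L)
  )
}

#' In-silico digestion of genomic sequence on both strands
#'
#' Finds every NlaIII site on both strands of each chromosome and emits the
#' 17 nt tag 3' of the site on the strand that produced it. Because `CATG` is
#' its own reverse complement, plus- and minus-strand sites share forward
#' anchors; `pos` always records the 0-based offset of the first base of
#' `CATG` on the forward strand. Entries are deduplicated by
#' (tag, chromosome, position, strand). Tags containing `N` are suppressed.
#'
#' @param genome A named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#'
#' @return A tibble with columns `tag`, `chrom`, `pos` (0-based anchor),
#'   `strand` (`+`/`-`).
#' @export
digest_genome <- function(genome) {
  genome <- as_chrom_set(genome)
  if (length(genome) == 0L) {
    return(tibble::tibble(
      tag = character(), chrom = character(),
      pos = integer(), strand = character()
    ))
  }
  per_chrom <- purrr::imap(genome, function(seq, chrom) {
    len <- nchar(seq)
    fwd <- extract_tags(seq)
    fwd <- tibble::tibble(
      tag = fwd$tag, chrom = chrom, pos = fwd$offset, strand = "+"
    )
    rc <- extract_tags(revcomp(seq))
    # anchor at 0-based q on the reverse complement starts, on the forward
    # strand, at len - q - 4 (CATG is palindromic)
    rev <- tibble::tibble(
      tag = rc$tag, chrom = chrom,
      pos = as.integer(len - rc$offset - 4L), strand = "-"
    )
    dplyr::bind_rows(fwd, rev)
  })
  dplyr::distinct(
    dplyr::bind_rows(per_chrom),
    .data$tag, .data$chrom, .data$pos, .data$strand
  )
}

#' Build a tag catalogue from gene models and a genome
#'
#' Digests every transcript into cDNA tag entries and the genome into genomic
#' entries, then annotates each cDNA tag with the number of distinct genes
#' carrying the same tag sequence (`n_gene_copies`; a tag present in two or
#' more genes is ambiguous and cannot be used for quantification) and the
#' number of genomic occurrences (`n_genomic_copies`).
#'
#' @param gene_models A data frame with one row per transcript: columns
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end` (0-based
#'   half-open gene span) and `sequence` (the transcript sequence, 5'->3').
#' @param genome As in [digest_genome()]; may be `NULL` to skip genomic
#'   digestion (then `n_genomic_copies` is `NA`).
#'
#' @return A tibble of class `tag_catalog`: one row per catalogue entry with
#'   columns `tag`, `origin` (`cdna`/`genomic`), `gene_id`, `transcript_id`,
#'   `site_rank`, `chrom`, `pos`, `strand`, `n_gene_copies`,
#'   `n_genomic_copies`.
#' @export
build_catalog <- function(gene_models, genome = NULL) {
  gene_models <- validate_gene_models(gene_models)
  cdna <- gene_models |>
    dplyr::mutate(.tags = purrr::map(.data$sequence, extract_tags)) |>
    dplyr::select("gene_id", "transcript_id", ".tags") |>
    tidyr::unnest(".tags") |>
    dplyr::transmute(
      tag = .data$tag,
      origin = "cdna",
      gene_id = .data$gene_id,
      transcript_id = .data$transcript_id,
      site_rank = .data$site_rank,
      chrom = NA_character_,
      pos = NA_integer_,
      strand = NA_character_
    )

  copies <- cdna |>
    dplyr::distinct(.data$tag, .data$gene_id) |>
    dplyr::count(.data$tag, name = "n_gene_copies")
  cdna <- dplyr::left_join(cdna, copies, by = "tag")

  if (is.null(genome)) {
    genomic <- tibble::tibble(
      tag = character(), origin = character(), gene_id = character(),
      transcript_id = character(), site_rank = integer(),
      chrom = character(), pos = integer(), strand = character(),
      n_gene_copies = integer()
    )
    gcount <- tibble::tibble(tag = character(), n_genomic_copies = integer())
  } else {
    gtags <- digest_genome(genome)
    gcount <- dplyr::count(gtags, .data$tag, name = "n_genomic_copies")
    genomic <- gtags |>
      dplyr::transmute(
        tag = .data$tag,
        origin = "genomic",
        gene_id = NA_character_,
        transcript_id = NA_character_,
        site_rank = NA_integer_,
        chrom = .data$chrom,
        pos = .data$pos,
        strand = .data$strand,
        n_gene_copies = NA_integer_
      )
  }

  out <- dplyr::bind_rows(cdna, genomic) |>
    dplyr::left_join(gcount, by = "tag") |>
    dplyr::mutate(
      n_genomic_copies = if (is.null(genome)) {
        NA_integer_
      } else {
        dplyr::coalesce(.data$n_genomic_copies, 0L)
      }
    )
  class(out) <- c("tag_catalog", class(out))
  out
}

#' Catalogue-level quantifiability statistics
#'
#' A gene is *with site* when at least one of its transcripts yields at least
#' one tag; it is *quantifiable* when at least one of its canonical tags
#' (site rank 1 of any transcript) is carried by no other gene, i.e. an
#' unambiguous measuring tag exists for it.
#'
#' @param catalog A `tag_catalog` built from `gene_models`.
#' @param gene_models The gene-model data frame the catalogue was built from.
#'
#' @return A one-row tibble: `n_genes`, `n_genes_with_site`,
#'   `n_genes_unique_canonical`, `frac_with_site`,
#'   `frac_nonunique_among_sited`, `frac_quantifiable`.
#' @export
catalog_stats <- function(catalog, gene_models) {
  gene_models <- validate_gene_models(gene_models)
  if (nrow(gene_models) == 0L) {
    rlang::abort("`gene_models` is empty.")
  }
  genes <- unique(gene_models$gene_id)
  cdna <- dplyr::filter(catalog, .data$origin == "cdna")
  sited <- unique(cdna$gene_id)
  quant <- cdna |>
    dplyr::filter(.data$site_rank == 1L, .data$n_gene_copies == 1L) |>
    dplyr::pull(.data$gene_id) |>
    unique()
  n <- length(genes)
  n_sited <- sum(genes %in% sited)
  n_quant <- sum(genes %in% quant)
  tibble::tibble(
    n_genes = n,
    n_genes_with_site = n_sited,
    n_genes_unique_canonical = n_quant,
    frac_with_site = n_sited / n,
    frac_nonunique_among_sited =
      if (n_sited > 0L) (n_sited - n_quant) / n_sited else NA_real_,
    frac_quantifiable = n_quant / n
  )
}

# -- helpers ------------------------------------------------------------------

as_chrom_set <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L &&
               grepl("[^ACGTNacgtn]", genome) && file.exists(genome)) {
    out <- as.character(Biostrings::readDNAStringSet(genome))
    names(out) <- sub("\\s.*$", "", names(out))
  } else if (is.character(genome)) {
    out <- toupper(genome)
    if (is.null(names(out)) && length(out) > 0L) {
      names(out) <- paste0("chr", seq_along(out))
    }
  } else {
    rlang::abort("`genome` must be a named character vector, DNAStringSet or FASTA path.")
  }
  toupper(out)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

validate_gene_models <- function(gene_models) {
  needed <- c("gene_id", "transcript_id", "chrom", "strand",
              "start", "end", "sequence")
  missing <- setdiff(needed, names(gene_models))
  if (length(missing) > 0L) {
    rlang::abort(paste0(
      "`gene_models` is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(gene_models$transcript_id)) {
    rlang::abort("duplicate transcript ids in `gene_models`.")
  }
  if (any(gene_models$start >= gene_models$end)) {
    rlang::abort("gene spans must satisfy start < end (0-based half-open).")
  }
  if (any(!nzchar(gene_models$sequence))) {
    rlang::abort("empty transcript sequence in `gene_models`.")
  }
  tibble::as_tibble(gene_models)
}
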