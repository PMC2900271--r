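# Readers and writers for the pipeline's standard formats. TSV outputs use
# fixed column orders so downstream diffs are stable.

#' Write a tag catalogue as TSV
#'
#' Columns: tag, origin, gene_id, transcript_id, site_rank, chrom, pos,
#' strand, n_gene_copies, n_genomic_copies.
#'
#' @param catalog A `tag_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  cols <- c("tag", "origin", "gene_id", "transcript_id", "site_rank",
            "chrom", "pos", "strand", "n_gene_copies", "n_genomic_copies")
  readr::write_tsv(dplyr::select(catalog, dplyr::all_of(cols)), path,
                   progress = FALSE)
  invisible(path)
}

#' Read a tag catalogue TSV written by [write_catalog()]
#'
#' @param path Path to the TSV.
#' @return A `tag_catalog` tibble.
#' @export
read_catalog <- function(path) {
  out <- readr::read_tsv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      tag = "c", origin = "c", gene_id = "c", transcript_id = "c",
      site_rank = "i", chrom = "c", pos = "i", strand = "c",
      n_gene_copies = "i", n_genomic_copies = "i"
    )
  )
  class(out) <- c("tag_catalog", class(out))
  out
}

#' Write gene models as GFF3 plus a transcript FASTA
#'
#' GFF3 uses 1-based closed coordinates per the standard (internal
#' representation is 0-based half-open). Each gene gets a `gene` feature and
#' one `mRNA` feature per transcript; transcript sequences go to the FASTA
#' with the transcript id as header.
#'
#' @param gene_models Gene-model tibble (see [build_catalog()]).
#' @param gff3_path Output GFF3 path.
#' @param fasta_path Output transcript FASTA path.
#' @return Invisibly, a list of the two paths.
#' @export
write_gene_models <- function(gene_models, gff3_path, fasta_path) {
  gm <- validate_gene_models(gene_models)
  gene_rows <- gm |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  glines <- sprintf("%s\tdgetag\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    gene_rows$chrom, gene_rows$start + 1L, gene_rows$end,
                    gene_rows$strand, gene_rows$gene_id)
  tlines <- sprintf("%s\tdgetag\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                    gm$chrom, gm$start + 1L, gm$end, gm$strand,
                    gm$transcript_id, gm$gene_id)
  readr::write_lines(c("##gff-version 3", glines, tlines), gff3_path)
  seqs <- Biostrings::DNAStringSet(gm$sequence)
  names(seqs) <- gm$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(list(gff3 = gff3_path, fasta = fasta_path))
}

#' Read gene models from GFF3 plus a transcript FASTA
#'
#' Expects the layout written by [write_gene_models()]: `gene` features with
#' `ID=`, `mRNA` features with `ID=...;Parent=...`, and transcript sequences
#' keyed by transcript id in the FASTA.
#'
#' @param gff3_path GFF3 path.
#' @param fasta_path Transcript FASTA path.
#' @return Gene-model tibble (0-based half-open spans).
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  lines <- readr::read_lines(gff3_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    rlang::abort(paste0("GFF3 line ", bad[1L], " does not have 9 columns."))
  }
  tab <- tibble::tibble(
    chrom = vapply(fields, `[`, "", 1L),
    type = vapply(fields, `[`, "", 3L),
    start1 = as.integer(vapply(fields, `[`, "", 4L)),
    end1 = as.integer(vapply(fields, `[`, "", 5L)),
    strand = vapply(fields, `[`, "", 7L),
    attrs = vapply(fields, `[`, "", 9L)
  )
  mrna <- dplyr::filter(tab, .data$type == "mRNA")
  get_attr <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]+)"))[, 2L]
    m
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tid <- get_attr(mrna$attrs, "ID")
  if (anyNA(tid)) rlang::abort("mRNA feature without ID attribute.")
  missing <- setdiff(tid, names(seqs))
  if (length(missing) > 0L) {
    rlang::abort(paste0("transcript(s) missing from FASTA: ",
                        paste(utils::head(missing, 3), collapse = ", ")))
  }
  tibble::tibble(
    gene_id = get_attr(mrna$attrs, "Parent"),
    transcript_id = tid,
    chrom = mrna$chrom,
    strand = mrna$strand,
    start = mrna$start1 - 1L,
    end = mrna$end1,
    sequence = unname(as.character(seqs[tid]))
  )
}

#' Check a file against a standard format's basic schema
#'
#' Supported formats: `fasta`, `fastq`, `gff3`, `gmt`, `tsv`. Returns a
#' tibble of line-anchored violations; an empty tibble means the file
#' passed every check.
#'
#' @param path File path.
#' @param format One of `"fasta"`, `"fastq"`, `"gff3"`, `"gmt"`, `"tsv"`.
#' @return Tibble `line`, `message`.
#' @export
validate_formats <- function(path, format) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  format <- match.arg(format, c("fasta", "fastq", "gff3", "gmt", "tsv"))
  lines <- readr::read_lines(path)
  viol <- function(line, message) tibble::tibble(line = line, message = message)
  out <- switch(
    format,
    fasta = {
      v <- list()
      if (length(lines) == 0L || !startsWith(lines[1L], ">")) {
        v <- c(v, list(viol(1L, "FASTA must start with a '>' header.")))
      }
      seq_lines <- which(!startsWith(lines, ">") & nzchar(lines))
      bad <- seq_lines[grepl("[^A-Za-z*.-]", lines[seq_lines])]
      if (length(bad) > 0L) {
        v <- c(v, list(viol(bad, "invalid characters in sequence line.")))
      }
      v
    },
    fastq = {
      v <- list()
      if (length(lines) %% 4L != 0L) {
        v <- c(v, list(viol(length(lines),
                            "FASTQ line count not a multiple of 4.")))
      }
      n_rec <- length(lines) %/% 4L
      for (r in seq_len(n_rec)) {
        i <- 4L * (r - 1L)
        if (!startsWith(lines[i + 1L], "@")) {
          v <- c(v, list(viol(i + 1L, "record header must start with '@'.")))
        }
        if (!startsWith(lines[i + 3L], "+")) {
          v <- c(v, list(viol(i + 3L, "separator line must start with '+'.")))
        }
        if (nchar(lines[i + 2L]) != nchar(lines[i + 4L])) {
          v <- c(v, list(viol(i + 2L,
                              "sequence and quality lengths differ.")))
        }
      }
      v
    },
    gff3 = {
      body <- which(!startsWith(lines, "#") & nzchar(lines))
      v <- list()
      for (i in body) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) != 9L) {
          v <- c(v, list(viol(i, "GFF3 feature must have 9 tab-separated columns.")))
          next
        }
        s <- suppressWarnings(as.integer(f[4L]))
        e <- suppressWarnings(as.integer(f[5L]))
        if (is.na(s) || is.na(e) || s < 1L || e < s) {
          v <- c(v, list(viol(i, "feature must satisfy 1 <= start <= end.")))
        }
      }
      v
    },
    gmt = {
      body <- which(nzchar(lines))
      bad <- body[lengths(strsplit(lines[body], "\t", fixed = TRUE)) < 3L]
      if (length(bad) > 0L) {
        list(viol(bad, "GMT lines need term, description and >= 1 gene."))
      } else {
        list()
      }
    },
    tsv = {
      body <- which(nzchar(lines))
      if (length(body) == 0L) {
        list()
      } else {
        nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
        bad <- body[nf != nf[1L]]
        if (length(bad) > 0L) {
          list(viol(bad, "inconsistent number of tab-separated columns."))
        } else {
          list()
        }
      }
    }
  )
  if (length(out) == 0L) {
    tibble::tibble(line = integer(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}
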