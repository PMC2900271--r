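# Shared fixtures and independent oracles used across the test files.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent oracle: naive scan of every CATG occurrence with a full 17 nt
# 3' flank, written without reference to the implementation
naive_tag_scan <- function(seq) {
  n <- nchar(seq)
  out <- list()
  for (i in seq_len(max(n - 3L, 0L))) {
    if (substr(seq, i, i + 3L) == "CATG" && i + 20L <= n) {
      tag <- substr(seq, i + 4L, i + 20L)
      if (!grepl("N", tag, fixed = TRUE)) {
        out[[length(out) + 1L]] <- list(anchor = i - 1L, tag = tag)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(tag = character(), site_rank = integer(),
                          offset = integer()))
  }
  d <- dplyr::bind_rows(out)
  d <- d[order(-d$anchor), ]
  tibble::tibble(tag = d$tag, site_rank = seq_len(nrow(d)),
                 offset = as.integer(d$anchor))
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# a 4-gene toy model set: A unique canonical, B no site, C and D identical
# canonical tags
toy_gene_models <- function() {
  tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    transcript_id = c("A.t1", "B.t1", "C.t1", "D.t1"),
    chrom = "chr1",
    strand = "+",
    start = c(0L, 100L, 200L, 300L),
    end = c(50L, 140L, 250L, 350L),
    sequence = c(
      paste0("GGG", "CATG", strrep("A", 17)),
      strrep("T", 40),
      paste0("TTT", "CATG", strrep("G", 17)),
      paste0("CCC", "CATG", strrep("G", 17))
    )
  )
}

# long tibble of tag counts from a named count list: list(s1 = c(tag = n))
as_tag_counts <- function(per_sample) {
  purrr::imap(per_sample, function(v, sid) {
    tibble::tibble(sample_id = sid, tag = names(v), count = as.integer(v))
  }) |> dplyr::bind_rows()
}

# exact two-sided binomial test by probability ordering (closed-form oracle
# for the Poisson limit of the NB exact test)
binom_two_tail <- function(x, n, p = 0.5) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

small_sim_config <- function(seed = 1L, library_size = 5000L, ...) {
  sim_config(
    seed = seed, genome_length = 60000L, n_genes = 60L,
    transcript_length = c(150L, 300L), library_size = library_size,
    ...
  )
}
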