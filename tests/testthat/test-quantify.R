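make_catalog <- function() {
  gm <- tibble::tibble(
    gene_id = c("G1", "G1", "G2", "G3", "G4"),
    transcript_id = c("G1.t1", "G1.t2", "G2.t1", "G3.t1", "G4.t1"),
    chrom = "chr1", strand = "+",
    start = c(0L, 0L, 100L, 200L, 300L), end = c(60L, 60L, 160L, 260L, 360L),
    sequence = c(
      paste0("CATG", strrep("A", 17)),                        # tag A17
      paste0("CATG", strrep("T", 17), "CATG", strrep("A", 17)), # T17 + A17
      paste0("CATG", strrep("C", 17)),                        # tag C17
      paste0("CATG", strrep("G", 17)),                        # shared with G4
      paste0("CC", "CATG", strrep("G", 17))
    )
  )
  genome <- c(chr1 = paste0("CATG", strrep("A", 17), "GG",
                            "CATG", strrep("A", 9), "C", strrep("A", 7), "TT"))
  list(gm = gm, catalog = build_catalog(gm, genome))
}

test_that("read filtering enforces length, N content and minimum quality", {
  reads <- tibble::tibble(
    seq = c(strrep("A", 17), paste0(strrep("A", 8), "N", strrep("A", 8)),
            strrep("A", 16), strrep("C", 17)),
    qual = c(strrep("I", 17), strrep("I", 17), strrep("I", 16),
             paste0(strrep("I", 16), "#"))  # '#' is Q2
  )
  res <- filter_reads(reads, min_quality = 20)
  expect_equal(res$accounting$n_raw, 4L)
  expect_equal(res$accounting$n_usable, 1L)
  expect_equal(res$tags$tag, strrep("A", 17))

  # anchor stripping accepts a 21 nt read beginning with CATG
  res2 <- filter_reads(tibble::tibble(seq = paste0("CATG", strrep("G", 17))),
                       strip_anchor = TRUE)
  expect_equal(res2$tags$tag, strrep("G", 17))

  bad <- tibble::tibble(seq = strrep("A", 17), qual = "II")
  expect_error(filter_reads(bad), "index 1")
})

test_that("FASTQ files round-trip through filtering", {
  tmp <- withr::local_tempdir()
  reads <- tibble::tibble(
    sample_id = "s1",
    seq = c(strrep("A", 17), strrep("C", 17), strrep("C", 17)),
    qual = strrep("I", 17)
  )
  paths <- write_fastq(reads, tmp)
  res <- filter_reads(paths[["s1"]])
  expect_equal(res$accounting$n_usable, 3L)
  expect_equal(dplyr::arrange(res$tags, tag)$count, c(1L, 2L))
})

test_that("tags classify into exactly one category and only unambiguous ones are counted", {
  cat_ <- make_catalog()$catalog
  tc <- as_tag_counts(list(
    s1 = c(10, 5, 3, 2, 4) |>
      stats::setNames(c(strrep("A", 17), strrep("C", 17), strrep("G", 17),
                        paste0(strrep("A", 9), "C", strrep("A", 7)),
                        paste0(strrep("T", 8), "G", strrep("T", 8))))
  ))
  m <- match_and_count(tc, cat_)
  acc <- m$accounting
  # partition property: category counts sum to usable
  expect_equal(acc$n_cdna_unambiguous + acc$n_cdna_ambiguous +
                 acc$n_genomic_only + acc$n_unmatched, acc$n_usable)
  expect_equal(acc$n_cdna_unambiguous, 15L)  # A17 (G1) + C17 (G2)
  expect_equal(acc$n_cdna_ambiguous, 3L)     # G17 shared by G3, G4
  expect_equal(acc$n_genomic_only, 2L)
  expect_equal(acc$n_unmatched, 4L)
  expect_setequal(m$counts$tag, c(strrep("A", 17), strrep("C", 17)))
  # A17 is also in the genome, but gene-unique: stays unambiguous
  expect_true(strrep("A", 17) %in% m$counts$tag)
  expect_equal(m$library_sizes$library_size, 15L)
})

test_that("single-base perturbations of a matched tag never match the same entry", {
  cat_ <- make_catalog()$catalog
  tag <- strrep("A", 17)
  for (i in c(1, 9, 17)) {
    mut <- tag
    substr(mut, i, i) <- "G"
    tc <- as_tag_counts(list(s1 = stats::setNames(1, mut)))
    m <- match_and_count(tc, cat_)
    expect_false(mut %in% m$counts$tag)
  }
})

test_that("gene counts sum tags across ranks and TPM columns sum to one million", {
  cat_ <- make_catalog()$catalog
  tc <- as_tag_counts(list(
    s1 = stats::setNames(c(30L, 70L, 150L),
                         c(strrep("A", 17), strrep("T", 17), strrep("C", 17))),
    s2 = stats::setNames(250L, strrep("C", 17))
  ))
  m <- match_and_count(tc, cat_)
  g <- gene_counts_tpm(m, cat_)
  # G1 carries both the canonical A17 and the noncanonical T17
  expect_equal(g$count[g$gene_id == "G1" & g$sample_id == "s1"], 100L)
  expect_equal(g$tpm[g$gene_id == "G1" & g$sample_id == "s1"], 4e5)
  expect_equal(g$tpm[g$gene_id == "G2" & g$sample_id == "s2"], 1e6)
  sums <- g |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(tpm = sum(tpm))
  expect_equal(sums$tpm, rep(1e6, 2), tolerance = 1e-12)
})

test_that("abundance profile ranks genes with exact shares and a 100% total", {
  g <- tibble::tibble(
    gene_id = c("A", "B"), sample_id = "s1", count = c(69L, 31L),
    tpm = c(69, 31) * 1e4
  )
  prof <- abundance_profile(g)
  expect_equal(prof$gene_id, c("A", "B"))
  expect_equal(prof$pct_all, c(69, 31))
  expect_equal(prof$cumulative_pct, c(69, 100))
  expect_equal(prof$cumulative_pct[nrow(prof)], 100, tolerance = 0.05)

  # permutation invariance
  prof2 <- abundance_profile(g[c(2, 1), ])
  expect_equal(prof, prof2)

  expect_error(abundance_profile(dplyr::mutate(g, count = 0L)), "zero")
})

test_that("proximity annotation distinguishes intragenic, proximal and unassigned", {
  gm <- tibble::tibble(
    gene_id = "G1", transcript_id = "G1.t1", chrom = "chr1", strand = "+",
    start = 1000L, end = 2000L, sequence = paste0("CATG", strrep("A", 17))
  )
  pos <- tibble::tibble(
    tag = c("t1", "t2", "t3"), chrom = "chr1", pos = c(2500L, 8000L, 1500L)
  )
  ann <- proximity_annotate(pos, gm, window = 5000)
  expect_equal(ann$category[ann$tag == "t1"], "proximal")
  expect_equal(ann$distance[ann$tag == "t1"], 500)
  expect_equal(ann$category[ann$tag == "t2"], "unassigned")
  expect_equal(ann$category[ann$tag == "t3"], "intragenic")
  expect_equal(ann$distance[ann$tag == "t3"], 0)

  # ties at equal distance report all tied genes
  gm2 <- dplyr::bind_rows(gm, dplyr::mutate(gm, gene_id = "G2",
                                            transcript_id = "G2.t1",
                                            start = 3000L, end = 4000L))
  tie <- proximity_annotate(tibble::tibble(tag = "t", chrom = "chr1",
                                           pos = 2500L), gm2)
  expect_setequal(tie$gene_id, c("G1", "G2"))

  expect_warning(
    un <- proximity_annotate(tibble::tibble(tag = "t", chrom = "chrX",
                                            pos = 1L), gm),
    "chromosome"
  )
  expect_equal(un$category, "unassigned")
})
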