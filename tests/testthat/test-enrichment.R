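toy_annotation <- function() {
  tibble::tibble(
    term_id = rep(c("T1", "T2", "T3", "T4", "T5"), each = 4),
    gene_id = c(sprintf("g%02d", 1:4), sprintf("g%02d", 5:8),
                sprintf("g%02d", 9:12), sprintf("g%02d", 13:16),
                sprintf("g%02d", c(1, 5, 9, 13)))
  )
}

test_that("overrepresentation p equals brute-force hypergeometric tail summation", {
  bg <- sprintf("g%03d", 1:100)
  term <- bg[1:10]
  fg <- c(bg[1:5], bg[21:25])  # 5 hits in a foreground of 10
  res <- fisher_overrep(fg, bg, term, ease_penalty = FALSE)
  expect_equal(res$fold_enrichment, 5)
  # enumeration oracle: sum of hypergeometric point masses for >= 5 hits
  oracle <- sum(sapply(5:10, function(k) {
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)
  }))
  expect_equal(res$p, oracle, tolerance = 1e-12)

  # EASE penalty shifts the tail by one hit
  res_e <- fisher_overrep(fg, bg, term, ease_penalty = TRUE)
  oracle_e <- sum(sapply(4:10, function(k) {
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)
  }))
  expect_equal(res_e$p, oracle_e, tolerance = 1e-12)
})

test_that("EASE edge cases: whole-background terms and single hits", {
  bg <- sprintf("g%03d", 1:50)
  fg <- bg[1:10]
  whole <- fisher_overrep(fg, bg, bg, ease_penalty = FALSE)
  expect_equal(whole$p, 1)
  expect_equal(whole$fold_enrichment, 1)

  one_hit <- fisher_overrep(fg, bg, bg[10:12], ease_penalty = TRUE)
  expect_equal(one_hit$hits, 1L)
  expect_equal(one_hit$p, 1)

  expect_error(fisher_overrep(character(), bg, bg[1:3]), "empty foreground")
  expect_error(fisher_overrep("not_in_bg", bg, bg[1:3]), "subset")
})

test_that("EASE-penalised p is never below the plain Fisher p", {
  set.seed(8)
  bg <- sprintf("g%03d", 1:200)
  for (i in 1:50) {
    fg <- sample(bg, sample(5:60, 1))
    term <- sample(bg, sample(3:80, 1))
    p_plain <- fisher_overrep(fg, bg, term, ease_penalty = FALSE)$p
    p_ease <- fisher_overrep(fg, bg, term, ease_penalty = TRUE)$p
    expect_gte(p_ease, p_plain - 1e-12)
  }
})

test_that("ease_scan ranks a fully loaded term first and handles degenerate input", {
  bg <- sprintf("g%02d", 1:40)
  ann <- toy_annotation()
  res <- ease_scan(ann$gene_id[ann$term_id == "T2"], bg, ann,
                   ease_penalty = FALSE)
  expect_equal(res$term_id[1], "T2")
  expect_equal(res$adj_p[1], min(res$adj_p))
  expect_true(all(res$adj_p >= res$p))

  expect_equal(nrow(ease_scan(bg[1:5], bg, ann[0, ])), 0L)
  expect_warning(
    ease_scan(bg[1:5], bg,
              tibble::tibble(term_id = "TX", gene_id = "absent")),
    "skipped"
  )
})

test_that("null foregrounds produce few significant terms at the FDR level", {
  set.seed(9)
  bg <- sprintf("g%03d", 1:300)
  ann <- tibble::tibble(
    term_id = rep(sprintf("T%02d", 1:20), each = 15),
    gene_id = unlist(lapply(1:20, function(i) sample(bg, 15)))
  )
  frac_sig <- replicate(20, {
    fg <- sample(bg, 30)
    res <- ease_scan(fg, bg, ann, fdr_level = 0.05, ease_penalty = FALSE)
    mean(res$significant)
  })
  expect_lte(mean(frac_sig), 0.05 + 1.96 * stats::sd(frac_sig) / sqrt(20))
})

test_that("fatiscan recovers a planted top-block term with oracle-checked Fisher p", {
  genes <- sprintf("g%03d", 1:60)
  ranked <- tibble::tibble(gene_id = genes, score = rev(seq_along(genes)))
  # all 10 genes of TM sit at ranks 1..10
  ann <- tibble::tibble(
    term_id = c(rep("TM", 10), rep("BG", 20)),
    gene_id = c(genes[1:10], genes[31:50])
  )
  res <- fatiscan(ranked, ann, n_partitions = 5)
  tm <- dplyr::filter(res, term_id == "TM")
  expect_equal(tm$direction, "up")
  expect_equal(tm$best_partition, 10L)
  # brute-force two-sided Fisher oracle at the winning cut
  tab <- matrix(c(10, 0, 0, 50), 2)
  expect_equal(tm$p, stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  expect_true(tm$significant)
})

test_that("fatiscan is rank-based and reversal flips directions but keeps p-values", {
  set.seed(10)
  genes <- sprintf("g%03d", 1:80)
  ranked <- tibble::tibble(gene_id = genes,
                           score = sort(stats::rnorm(80), decreasing = TRUE))
  ann <- tibble::tibble(
    term_id = rep(c("A", "B"), each = 12),
    gene_id = c(genes[1:12], genes[61:72])
  )
  res1 <- fatiscan(ranked, ann, n_partitions = 7)
  # monotone transform of the scores changes nothing
  res2 <- fatiscan(dplyr::mutate(ranked, score = rank(score)^3), ann,
                   n_partitions = 7)
  expect_equal(res1, res2)
  # reversal
  res3 <- fatiscan(dplyr::mutate(ranked, score = -score), ann,
                   n_partitions = 7)
  m <- match(res1$term_id, res3$term_id)
  expect_equal(res3$p[m], res1$p, tolerance = 1e-9)
  expect_true(all(res3$direction[m] != res1$direction))
})

test_that("fatiscan handles absent genes, small terms and bad partition counts", {
  genes <- sprintf("g%03d", 1:30)
  ranked <- tibble::tibble(gene_id = genes, score = 30:1)
  ann <- tibble::tibble(term_id = c("T1", "T1", "T2"),
                        gene_id = c(genes[1], "absent1", "absent2"))
  # T1 keeps one gene (< 2) and T2 none: both skipped
  expect_equal(nrow(fatiscan(ranked, ann, n_partitions = 4)), 0L)
  expect_error(fatiscan(ranked, ann, n_partitions = 0), "n_partitions")
  expect_error(fatiscan(ranked, ann, n_partitions = 30), "n_partitions")
  expect_error(
    fatiscan(dplyr::bind_rows(ranked, ranked[1, ]), ann, n_partitions = 4),
    "unique"
  )
})

test_that("permuted rankings rarely produce significant terms", {
  set.seed(11)
  genes <- sprintf("g%03d", 1:100)
  ann <- tibble::tibble(
    term_id = rep(sprintf("T%d", 1:5), each = 12),
    gene_id = unlist(lapply(1:5, function(i) sample(genes, 12)))
  )
  clean <- replicate(20, {
    ranked <- tibble::tibble(gene_id = genes, score = sample(100))
    res <- fatiscan(ranked, ann, n_partitions = 10, fdr_level = 0.05)
    !any(res$significant)
  })
  expect_gte(mean(clean), 0.95)
})

test_that("GMT files round-trip", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  ann <- toy_annotation()
  write_gmt(ann, tmp)
  back <- read_gmt(tmp)
  expect_equal(
    dplyr::arrange(back[, c("term_id", "gene_id")], term_id, gene_id),
    dplyr::arrange(ann, term_id, gene_id)
  )
  expect_error(read_gmt(withr::local_tempfile(lines = "one\tfield")), "GMT")
})

test_that("DE ranking score orders strong up-regulation first", {
  tab <- tibble::tibble(
    gene_id = c("a", "b", "c", "c"),
    log2_fc = c(2, -2, 0.5, 1),
    p = c(1e-6, 1e-6, 0.5, 0.01)
  )
  r <- de_ranking(tab)
  expect_equal(nrow(r), 3L)
  expect_equal(r$score[r$gene_id == "a"], 6)
  expect_equal(r$score[r$gene_id == "b"], -6)
  expect_equal(r$score[r$gene_id == "c"], 2)  # strongest tag kept
})
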