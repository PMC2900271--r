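# helper: long count tibble from a tags x samples matrix
mat_to_counts <- function(m) {
  d <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(d) <- c("tag", "sample_id", "count")
  tibble::as_tibble(d) |>
    dplyr::mutate(tag = as.character(tag), sample_id = as.character(sample_id),
                  count = as.integer(count))
}

sim_count_matrix <- function(n_tags, n_a, n_b, phi, mean_range = c(5, 200),
                             seed = 1) {
  set.seed(seed)
  mu <- stats::runif(n_tags, mean_range[1], mean_range[2])
  n <- n_a + n_b
  m <- sapply(seq_len(n), function(j) {
    if (phi > 0) {
      stats::rnbinom(n_tags, size = 1 / phi, mu = mu)
    } else {
      stats::rpois(n_tags, mu)
    }
  })
  dimnames(m) <- list(sprintf("t%04d", seq_len(n_tags)),
                      c(sprintf("a%d", seq_len(n_a)),
                        sprintf("b%d", seq_len(n_b))))
  m
}

groups_for <- function(m, n_a) {
  tibble::tibble(sample_id = colnames(m),
                 group = rep(c("A", "B"), c(n_a, ncol(m) - n_a)))
}

test_that("common dispersion is recovered from simulated counts", {
  # Poisson data: estimate collapses toward the grid floor
  m0 <- sim_count_matrix(500, 7, 6, phi = 0, seed = 11)
  phi0 <- estimate_common_dispersion(mat_to_counts(m0), groups_for(m0, 7))
  expect_lte(phi0, 0.05)

  # phi = 0.2: estimate lands in [0.1, 0.3]
  m2 <- sim_count_matrix(500, 7, 6, phi = 0.2, seed = 12)
  phi2 <- estimate_common_dispersion(mat_to_counts(m2), groups_for(m2, 7))
  expect_gte(phi2, 0.1)
  expect_lte(phi2, 0.3)

  # identical counts in every sample: no excess variance, grid minimum
  mc <- matrix(7L, nrow = 20, ncol = 6,
               dimnames = list(sprintf("t%d", 1:20), sprintf("s%d", 1:6)))
  grid <- 10^seq(-6, 1, length.out = 61)
  phic <- estimate_common_dispersion(mat_to_counts(mc), groups_for(mc, 3), grid)
  expect_equal(phic, grid[1])
})

test_that("common dispersion agrees with edgeR's estimate in order of magnitude", {
  skip_if_not_installed("edgeR")
  m <- sim_count_matrix(400, 7, 6, phi = 0.15, seed = 13)
  phi <- estimate_common_dispersion(mat_to_counts(m), groups_for(m, 7))
  dge <- edgeR::DGEList(counts = m,
                        group = rep(c("A", "B"), c(7, 6)))
  dge <- edgeR::estimateCommonDisp(dge)
  expect_equal(log10(phi), log10(dge$common.dispersion), tolerance = 0.25)
})

test_that("exact test matches the closed-form binomial two-tail in the Poisson limit", {
  # n_a = n_b = 1, T = 10, split 10/0: p = 2 * 0.5^10
  expect_equal(nb_exact_test(10, 1, 0, 1, 0), 2 * 0.5^10, tolerance = 1e-12)

  # same split at phi = 0.5 is strictly less extreme (heavier tails)
  expect_gt(nb_exact_test(10, 1, 0, 1, 0.5), nb_exact_test(10, 1, 0, 1, 0))

  # across totals up to 200 and unbalanced designs, phi <= 1e-8 equals the
  # binomial probability-ordering two-tail to 1e-6
  set.seed(3)
  for (total in sample(1:200, 60)) {
    n_a <- sample(1:7, 1)
    n_b <- sample(1:7, 1)
    a <- sample(0:total, 1)
    expect_equal(
      nb_exact_test(a, n_a, total - a, n_b, 1e-9),
      binom_two_tail(a, total, n_a / (n_a + n_b)),
      tolerance = 1e-6,
      label = sprintf("T=%d a=%d n_a=%d n_b=%d", total, a, n_a, n_b)
    )
  }
})

test_that("exact test probabilities normalise and the modal split has p = 1", {
  for (phi in c(0, 0.01, 0.2, 1)) {
    for (total in c(1, 10, 57, 200)) {
      pr <- nb_split_probs(total, 7, 6, phi)
      expect_equal(sum(pr), 1, tolerance = 1e-10)
      mode_a <- which.max(pr) - 1L
      expect_equal(nb_exact_test(mode_a, 7, total - mode_a, 6, phi), 1)
    }
  }
  expect_equal(nb_exact_test(0, 3, 0, 3, 0.2), 1)  # T = 0
})

test_that("exact test is symmetric under group-label swap", {
  set.seed(4)
  for (i in 1:30) {
    total <- sample(1:150, 1)
    a <- sample(0:total, 1)
    n_a <- sample(1:7, 1); n_b <- sample(1:7, 1)
    phi <- stats::runif(1, 0, 1)
    expect_equal(nb_exact_test(a, n_a, total - a, n_b, phi),
                 nb_exact_test(total - a, n_b, a, n_a, phi),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up formula and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(numeric()), numeric())
  set.seed(5)
  p <- stats::runif(50)
  expect_true(all(bh_adjust(p) >= p))
  # permutation invariance after rank restoration
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_de ties the pieces together on degenerate and symmetric inputs", {
  samples <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    timepoint = c("pre", "pre", "post", "post")
  )
  cnt <- tibble::tibble(
    tag = "t1", sample_id = samples$sample_id, count = 50L
  )
  de <- run_de(cnt, samples)
  expect_equal(de$table$p, 1)
  expect_equal(de$table$log2_fc, 0)
  expect_false(de$table$significant)

  # label swap negates log2 fold changes and keeps p
  swapped <- dplyr::mutate(samples,
                           timepoint = dplyr::recode(timepoint, pre = "post",
                                                     post = "pre"))
  m <- sim_count_matrix(50, 2, 2, phi = 0.1, seed = 6)
  colnames(m) <- samples$sample_id
  cnt2 <- mat_to_counts(m)
  de_a <- run_de(cnt2, samples)
  de_b <- run_de(cnt2, swapped)
  expect_equal(de_a$table$p[order(de_a$table$tag)],
               de_b$table$p[order(de_b$table$tag)], tolerance = 1e-9)
  expect_equal(de_a$table$log2_fc[order(de_a$table$tag)],
               -de_b$table$log2_fc[order(de_b$table$tag)], tolerance = 1e-9)

  # low-count filter is applied and reported
  cnt3 <- dplyr::bind_rows(
    cnt2, tibble::tibble(tag = "rare", sample_id = "s1", count = 2L)
  )
  de_c <- run_de(cnt3, samples)
  expect_equal(de_c$n_tags_filtered, 1L)
  expect_false("rare" %in% de_c$table$tag)

  expect_error(run_de(cnt, samples[1:2, ]), "timepoint")
})

test_that("tidiers summarise DE results", {
  samples <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                            timepoint = rep(c("pre", "post"), each = 3))
  m <- sim_count_matrix(40, 3, 3, phi = 0.1, seed = 7)
  colnames(m) <- samples$sample_id
  de <- run_de(mat_to_counts(m), samples)
  expect_s3_class(tidy(de), "tbl_df")
  expect_equal(nrow(glance(de)), 1L)
  expect_equal(glance(de)$n_tags_tested, nrow(tidy(de)))
  expect_s3_class(autoplot(de), "ggplot")
})
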