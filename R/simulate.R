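# Synthetic-data generator: genomes, gene models, tag libraries and qPCR
# plates with the statistical structure the analysis pipeline assumes.
# Every output is a pure function of (config, seed); each sample has its own
# independently derived random stream so dropping one library leaves the
# others byte-identical.

#' Simulation configuration
#'
#' Defaults emulate the design of a paired pre/post exercise-training DGE
#' study: 7 subjects sampled at two timepoints with one failed library
#' dropped (13 libraries), a long-tailed log-normal abundance distribution,
#' negative-binomial count noise with common dispersion, a small fraction of
#' genes carrying planted fold changes, per-base sequencing error, and a
#' fraction of reads drawn from intergenic genomic tags. Library depth is
#' scaled down from the study's millions of reads to keep a full run at
#' desk scale.
#'
#' @param seed Base random seed.
#' @param genome_length Genome length in bp.
#' @param n_genes Number of genes (one transcript each).
#' @param gc_content Background GC proportion.
#' @param frac_genes_no_site Fraction of genes constructed without any
#'   qualifying NlaIII site (not measurable by DGE).
#' @param frac_shared_canonical Fraction of genes built in pairs sharing an
#'   identical 3'-terminal 21-mer (hence an ambiguous canonical tag).
#' @param transcript_length Range (min, max) of transcript lengths in nt.
#' @param n_subjects Number of paired subjects (default 7).
#' @param drop_one_library Drop one pre-timepoint library (default `TRUE`),
#'   emulating a failed sample: 2n-1 libraries in total.
#' @param library_size Reads per library (default 200000).
#' @param abundance_sigma Log-normal sdlog of baseline gene abundances
#'   (default 2.6, calibrated so a couple of dozen genes out of thousands
#'   jointly hold roughly half of the reads, as deep tag profiling of
#'   skeletal muscle observes).
#' @param dispersion Negative-binomial overdispersion of counts between
#'   biological replicates (default 0.2).
#' @param de_fraction Fraction of genes with a planted fold change.
#' @param de_log2fc_range Range of planted |log2 fold changes|; sign random.
#' @param error_rate Per-base substitution error rate in emitted reads.
#' @param intergenic_read_fraction Fraction of each library drawn from
#'   genomic-only (intergenic) tags.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 300000L,
                       n_genes = 200L,
                       gc_content = 0.5,
                       frac_genes_no_site = 0.09,
                       frac_shared_canonical = 0.13,
                       transcript_length = c(200L, 600L),
                       n_subjects = 7L,
                       drop_one_library = TRUE,
                       library_size = 200000L,
                       abundance_sigma = 2.6,
                       dispersion = 0.2,
                       de_fraction = 0.05,
                       de_log2fc_range = c(0.5, 4.9),
                       error_rate = 0.005,
                       intergenic_read_fraction = 0.3) {
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes), gc_content = gc_content,
    frac_genes_no_site = frac_genes_no_site,
    frac_shared_canonical = frac_shared_canonical,
    transcript_length = as.integer(transcript_length),
    n_subjects = as.integer(n_subjects),
    drop_one_library = isTRUE(drop_one_library),
    library_size = as.integer(library_size),
    abundance_sigma = abundance_sigma, dispersion = dispersion,
    de_fraction = de_fraction, de_log2fc_range = de_log2fc_range,
    error_rate = error_rate,
    intergenic_read_fraction = intergenic_read_fraction
  )
  props <- c(cfg$gc_content, cfg$frac_genes_no_site, cfg$frac_shared_canonical,
             cfg$de_fraction, cfg$error_rate, cfg$intergenic_read_fraction)
  stopifnot(all(props >= 0), all(props <= 1), cfg$n_subjects >= 2,
            cfg$dispersion >= 0, cfg$library_size >= 1,
            length(cfg$transcript_length) == 2L,
            cfg$transcript_length[1] >= 60L)
  if (cfg$de_fraction > 1) rlang::abort("de_fraction must be <= 1.")
  structure(cfg, class = "sim_config")
}

# derive a per-stream seed from the base seed; kept under 2^31
stream_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + stream * 7919) %% 2147483647)
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# remove every CATG occurrence by rewriting its G; guarantees no qualifying
# site anywhere in the sequence
strip_catg <- function(seq) {
  while (grepl(ANCHOR, seq, fixed = TRUE)) {
    pos <- regexpr(ANCHOR, seq, fixed = TRUE)[1]
    substr(seq, pos + 3L, pos + 3L) <- "A"
  }
  seq
}

#' Generate a synthetic genome, gene models and transcript set
#'
#' Transcripts are random sequences ending in `CATG` plus a unique random
#' 17-mer, so every sited gene has a well-defined canonical tag at its 3'
#' terminus (internal sites arise by chance and provide noncanonical
#' ranks). A configured fraction of genes is built with no qualifying site
#' at all, and another fraction in pairs sharing an identical 3'-terminal
#' 21-mer, making their canonical tags ambiguous. Genes are embedded
#' non-overlapping, on random strands, in a random background genome.
#'
#' @param config A [sim_config()].
#'
#' @return List: `genome` (named character vector, one chromosome),
#'   `gene_models` (tibble as required by [build_catalog()]), `truth_sites`
#'   (tibble `gene_id`, `class` in no_site/shared/unique, `canonical_tag`).
#' @export
generate_genome_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, 1L, {
    n <- config$n_genes
    n_nosite <- round(config$frac_genes_no_site * n)
    n_shared <- 2L * floor(config$frac_shared_canonical * n / 2)
    n_unique <- n - n_nosite - n_shared
    stopifnot(n_unique >= 0)
    classes <- sample(c(rep("no_site", n_nosite), rep("shared", n_shared),
                        rep("unique", n_unique)))
    gene_ids <- sprintf("G%04d", seq_len(n))
    lens <- sample(seq(config$transcript_length[1], config$transcript_length[2]),
                   n, replace = TRUE)

    # unique 17-mer canonical tags, CATG-free so the terminal site stays
    # 3'-most; shared pairs reuse one tag
    n_tags_needed <- n_unique + n_shared / 2
    tags <- character(0)
    while (length(tags) < n_tags_needed) {
      cand <- strip_catg(random_dna(TAG_LEN + 8L, config$gc_content))
      cand <- substr(cand, 1L, TAG_LEN)
      if (nchar(cand) == TAG_LEN && !cand %in% tags) tags <- c(tags, cand)
    }
    idx_unique <- which(classes == "unique")
    idx_shared <- which(classes == "shared")
    tag_of <- character(n)
    tag_of[idx_unique] <- tags[seq_len(n_unique)]
    if (n_shared > 0L) {
      shared_tags <- tags[n_unique + seq_len(n_shared / 2)]
      tag_of[idx_shared] <- rep(shared_tags, each = 2L)
    }

    seqs <- vapply(seq_len(n), function(i) {
      body_len <- lens[i] - (TAG_LEN + 4L)
      body <- random_dna(max(body_len, 20L), config$gc_content)
      if (classes[i] == "no_site") {
        strip_catg(random_dna(lens[i], config$gc_content))
      } else {
        paste0(body, ANCHOR, tag_of[i])
      }
    }, character(1))

    total_gene_bp <- sum(nchar(seqs))
    spare <- config$genome_length - total_gene_bp
    if (spare < n + 1L) {
      rlang::abort("genome_length too small to pack the gene set.")
    }
    gaps <- as.vector(stats::rmultinom(1, spare, rep(1, n + 1L)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    pieces <- character(2L * n + 1L)
    starts <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- random_dna(gaps[i], config$gc_content)
      pos <- pos + gaps[i]
      starts[i] <- pos
      embedded <- if (strand[i] == "+") seqs[i] else revcomp(seqs[i])
      pieces[2L * i] <- embedded
      pos <- pos + nchar(seqs[i])
    }
    pieces[2L * n + 1L] <- random_dna(gaps[n + 1L], config$gc_content)
    genome <- c(chr1 = paste(pieces, collapse = ""))

    models <- tibble::tibble(
      gene_id = gene_ids,
      transcript_id = paste0(gene_ids, ".t1"),
      chrom = "chr1",
      strand = strand,
      start = starts,
      end = starts + nchar(seqs),
      sequence = seqs
    )
    truth_sites <- tibble::tibble(
      gene_id = gene_ids, class = classes,
      canonical_tag = dplyr::na_if(tag_of, "")
    )
    list(genome = genome, gene_models = models, truth_sites = truth_sites)
  })
}

#' Simulate per-gene ground truth
#'
#' Baseline relative abundances are log-normal (sdlog `abundance_sigma`)
#' normalised to sum to 1; a `de_fraction` of genes receives a planted log2
#' fold change drawn uniformly from `de_log2fc_range` with random sign.
#' Non-DE genes have log2 fold change exactly 0.
#'
#' @param config A [sim_config()].
#' @param gene_ids Gene identifiers (from [generate_genome_models()]).
#'
#' @return Tibble `gene_id`, `baseline`, `log2_fc`, `is_de`.
#' @export
simulate_truth <- function(config, gene_ids) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, 2L, {
    n <- length(gene_ids)
    ab <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sigma)
    ab <- ab / sum(ab)
    n_de <- round(config$de_fraction * n)
    de_idx <- if (n_de > 0) sample(n, n_de) else integer(0)
    lfc <- numeric(n)
    if (n_de > 0) {
      mag <- stats::runif(n_de, config$de_log2fc_range[1],
                          config$de_log2fc_range[2])
      lfc[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    }
    tibble::tibble(gene_id = gene_ids, baseline = ab, log2_fc = lfc,
                   is_de = lfc != 0)
  })
}

#' Sample sheet for the paired design
#'
#' @param config A [sim_config()].
#' @return Tibble `sample_id`, `subject_id`, `timepoint`; when
#'   `drop_one_library` the last subject's pre-timepoint library is absent.
#' @export
sim_sample_sheet <- function(config) {
  sheet <- tidyr::expand_grid(
    subject_id = sprintf("H%02d", seq_len(config$n_subjects)),
    timepoint = c("pre", "post")
  ) |>
    dplyr::mutate(sample_id = paste0(.data$subject_id, "_", .data$timepoint),
                  .before = 1)
  if (config$drop_one_library) {
    drop <- paste0(sprintf("H%02d", config$n_subjects), "_pre")
    sheet <- dplyr::filter(sheet, .data$sample_id != drop)
  }
  sheet
}

#' Simulate per-gene read counts for every library
#'
#' Genic reads per sample are Dirichlet-multinomial: per-gene gamma weights
#' with shape `1/dispersion` and mean `baseline * 2^log2_fc` (post
#' timepoint only), conditioned on the exact genic library size by a
#' multinomial draw — a gamma-mixed Poisson conditioned on its total, so
#' marginal counts are negative-binomial-like with the configured common
#' overdispersion and per-sample totals are exact.
#'
#' @param truth From [simulate_truth()].
#' @param config A [sim_config()].
#' @param sheet Optional sample sheet; default [sim_sample_sheet()].
#'
#' @return List: `counts` (long tibble `gene_id`, `sample_id`, `count`),
#'   `sheet`, `genic_library_size`.
#' @export
simulate_counts <- function(truth, config, sheet = sim_sample_sheet(config)) {
  stopifnot(inherits(config, "sim_config"))
  genic_size <- config$library_size -
    round(config$intergenic_read_fraction * config$library_size)
  if (config$library_size <= 0) rlang::abort("library size must be positive.")
  full <- sim_sample_sheet(sim_config_full(config))
  per_sample <- purrr::map(seq_len(nrow(sheet)), function(i) {
    sid <- sheet$sample_id[i]
    stream <- 100L + match(sid, full$sample_id)
    with_stream(config$seed, stream, {
      mean_ab <- if (sheet$timepoint[i] == "post") {
        truth$baseline * 2^truth$log2_fc
      } else {
        truth$baseline
      }
      w <- if (config$dispersion > 0) {
        stats::rgamma(length(mean_ab), shape = 1 / config$dispersion,
                      scale = mean_ab * config$dispersion)
      } else {
        mean_ab
      }
      if (sum(w) == 0) w <- mean_ab
      counts <- as.vector(stats::rmultinom(1, genic_size, w / sum(w)))
      tibble::tibble(gene_id = truth$gene_id, sample_id = sid, count = counts)
    })
  })
  list(counts = dplyr::bind_rows(per_sample), sheet = sheet,
       genic_library_size = genic_size)
}

# the undropped design, used to anchor per-sample streams
sim_config_full <- function(config) {
  cfg <- config
  cfg$drop_one_library <- FALSE
  cfg
}

#' Emit tag reads (FASTQ-style) for every library
#'
#' Each genic read is the canonical tag of its gene (the 3'-most site, as
#' targeted by the library chemistry); an `intergenic_read_fraction` of each
#' library is drawn uniformly from genomic-only tags in the catalogue.
#' Per-base substitution errors are applied at `error_rate`. Per-sample read
#' totals equal `library_size` exactly. Genes without a canonical tag in the
#' catalogue contribute no reads (their abundance mass is reallocated by the
#' multinomial draw over tagged genes).
#'
#' @param truth From [simulate_truth()].
#' @param catalog `tag_catalog` built from the generated models and genome.
#' @param config A [sim_config()].
#' @param sheet Optional sample sheet.
#'
#' @return List: `reads` (tibble `sample_id`, `seq`, `qual`), `truth`,
#'   `sheet`, `counts` (the genic count table actually emitted).
#' @export
simulate_libraries <- function(truth, catalog, config,
                               sheet = sim_sample_sheet(config)) {
  cdna <- dplyr::filter(catalog, .data$origin == "cdna", .data$site_rank == 1L)
  canon <- cdna |>
    dplyr::distinct(.data$gene_id, .data$tag) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  tagged_truth <- dplyr::semi_join(truth, canon, by = "gene_id")
  if (nrow(tagged_truth) == 0L) {
    rlang::abort("no gene in `truth` has a canonical tag in the catalogue.")
  }
  tagged_truth$baseline <- tagged_truth$baseline / sum(tagged_truth$baseline)
  sim <- simulate_counts(tagged_truth, config, sheet)
  genomic_only <- setdiff(catalog$tag[catalog$origin == "genomic"],
                          catalog$tag[catalog$origin == "cdna"])
  n_inter <- config$library_size - sim$genic_library_size
  if (n_inter > 0L && length(genomic_only) == 0L) {
    rlang::abort("intergenic reads requested but no genomic-only tags exist.")
  }
  tag_of_gene <- stats::setNames(canon$tag, canon$gene_id)
  full <- sim_sample_sheet(sim_config_full(config))

  reads <- purrr::map(seq_len(nrow(sheet)), function(i) {
    sid <- sheet$sample_id[i]
    stream <- 1000L + match(sid, full$sample_id)
    with_stream(config$seed, stream, {
      gcounts <- dplyr::filter(sim$counts, .data$sample_id == sid)
      seqs <- rep(tag_of_gene[gcounts$gene_id], gcounts$count)
      if (n_inter > 0L) {
        seqs <- c(seqs, sample(genomic_only, n_inter, replace = TRUE))
      }
      seqs <- apply_sequencing_errors(unname(seqs), config$error_rate)
      tibble::tibble(sample_id = sid, seq = seqs,
                     qual = strrep("I", TAG_LEN))
    })
  })
  list(reads = dplyr::bind_rows(reads), truth = tagged_truth, sheet = sheet,
       counts = sim$counts)
}

apply_sequencing_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) {
    return(seqs)
  }
  n_err <- stats::rbinom(length(seqs), TAG_LEN, error_rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(TAG_LEN, n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate a qPCR plate from simulation truth
#'
#' A gene's Ct in a sample is `base_ct - log2(relative abundance x
#' 2^(timepoint effect)) + N(0, noise_sd)`, measured in duplicate. A
#' synthetic reference gene with constant relative abundance and zero fold
#' change is measured in every sample, and a 1:1 ... 1:64 serial dilution
#' series of the reference provides the standard curve (slope exactly 1
#' Ct per doubling at zero noise).
#'
#' @param truth From [simulate_truth()].
#' @param config A [sim_config()].
#' @param gene_ids Genes to assay (subset of `truth$gene_id`).
#' @param noise_sd Gaussian Ct noise in cycles (default 0.2).
#' @param reference_gene Name for the synthetic reference (default "REF").
#' @param sheet Optional sample sheet.
#'
#' @return List: `ct_table` (tibble `sample_id`, `subject_id`, `timepoint`,
#'   `gene_id`, `replicate`, `ct`), `curve_table` (tibble `dilution`, `ct`).
#' @export
simulate_qpcr <- function(truth, config, gene_ids, noise_sd = 0.2,
                          reference_gene = "REF",
                          sheet = sim_sample_sheet(config)) {
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0.")
  if (!all(gene_ids %in% truth$gene_id)) {
    rlang::abort("all `gene_ids` must be present in `truth`.")
  }
  base_ct <- 35
  ref_abund <- 0.01
  with_stream(config$seed, 3L, {
    assay <- dplyr::bind_rows(
      dplyr::filter(truth, .data$gene_id %in% gene_ids),
      tibble::tibble(gene_id = reference_gene, baseline = ref_abund,
                     log2_fc = 0, is_de = FALSE)
    )
    grid <- tidyr::expand_grid(sheet, assay, replicate = 1:2)
    ct_table <- grid |>
      dplyr::mutate(
        ct = base_ct -
          log2(.data$baseline *
                 ifelse(.data$timepoint == "post", 2^.data$log2_fc, 1)) +
          stats::rnorm(dplyr::n(), 0, noise_sd)
      ) |>
      dplyr::select("sample_id", "subject_id", "timepoint", "gene_id",
                    "replicate", "ct")
    dil <- 2^(0:6)
    curve_table <- tibble::tibble(
      dilution = dil,
      ct = base_ct - log2(ref_abund / dil) +
        stats::rnorm(length(dil), 0, noise_sd)
    )
    list(ct_table = ct_table, curve_table = curve_table)
  })
}

#' Write simulated reads as per-sample FASTQ files
#'
#' @param reads Tibble `sample_id`, `seq`, `qual`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_sample <- split(reads, reads$sample_id)
  paths <- purrr::imap_chr(by_sample, function(d, sid) {
    path <- file.path(dir, paste0(sid, ".fastq"))
    ids <- paste0("@", sid, ":", seq_len(nrow(d)))
    readr::write_lines(
      as.vector(rbind(ids, d$seq, "+", d$qual)), path
    )
    path
  })
  paths
}
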