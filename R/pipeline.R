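# End-to-end orchestration: digest -> quantify -> de -> enrich (-> qpcr),
# with a manifest recording configuration and per-stage row counts.

#' Pipeline configuration
#'
#' Paths may be `NULL` for stages that are skipped. All thresholds carry the
#' module defaults.
#'
#' @param genome_fasta Genome FASTA path.
#' @param models_gff3 Gene-model GFF3 path.
#' @param transcripts_fasta Transcript FASTA path.
#' @param reads_fastq Named character vector of per-sample FASTQ paths
#'   (names = sample ids).
#' @param sample_sheet Tibble `sample_id`, `subject_id`, `timepoint`, or a
#'   TSV path with those columns.
#' @param annotation_gmt GMT annotation path (`NULL` skips enrichment).
#' @param qpcr_ct TSV path of Ct measurements (`NULL` skips qPCR).
#' @param qpcr_curve TSV path of the reference dilution series.
#' @param reference_gene qPCR reference gene id.
#' @param min_quality FASTQ quality threshold (default 20).
#' @param strip_anchor Strip leading CATG anchors in reads (default FALSE).
#' @param fdr_level FDR threshold used throughout (default 0.05).
#' @param proximity_window Proximity annotation window in bp (default 5000).
#' @param n_partitions Segmentation enrichment partitions (default 30).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param out_dir Output directory.
#'
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, models_gff3, transcripts_fasta,
                            reads_fastq, sample_sheet,
                            annotation_gmt = NULL,
                            qpcr_ct = NULL, qpcr_curve = NULL,
                            reference_gene = "REF",
                            min_quality = 20, strip_anchor = FALSE,
                            fdr_level = 0.05, proximity_window = 5000,
                            n_partitions = 30, seed = 1L,
                            out_dir = "dgetag_run") {
  structure(
    list(genome_fasta = genome_fasta, models_gff3 = models_gff3,
         transcripts_fasta = transcripts_fasta, reads_fastq = reads_fastq,
         sample_sheet = sample_sheet, annotation_gmt = annotation_gmt,
         qpcr_ct = qpcr_ct, qpcr_curve = qpcr_curve,
         reference_gene = reference_gene, min_quality = min_quality,
         strip_anchor = strip_anchor, fdr_level = fdr_level,
         proximity_window = proximity_window, n_partitions = n_partitions,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full tag-DGE pipeline
#'
#' Executes digest, quantify, differential expression, enrichment (when an
#' annotation is supplied) and qPCR validation (when Ct tables are
#' supplied), writing fixed-column TSV/JSON outputs and a `manifest.json`
#' with the package version, a configuration hash, and per-stage status and
#' row counts. Re-running with the same inputs reproduces identical output
#' bytes. A failing stage keeps earlier outputs on disk, marks the failure
#' in the manifest, then raises the error.
#'
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list of in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$genome_fasta, config$models_gff3,
              config$transcripts_fasta, unname(config$reads_fastq),
              config$annotation_gmt, config$qpcr_ct, config$qpcr_curve)) {
    if (!is.null(p) && !file.exists(p)) {
      rlang::abort(paste0("missing input file: ", p))
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "dgetag",
    version = as.character(utils::packageVersion("dgetag")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    stages = list()
  )
  results <- list()
  finish_stage <- function(name, rows) {
    manifest$stages[[name]] <<- list(status = "ok", rows = rows)
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      rlang::abort(paste0("stage '", name, "' failed: ",
                          conditionMessage(e)), parent = e)
    })
  }

  run_stage("digest", function() {
    models <- read_gene_models(config$models_gff3, config$transcripts_fasta)
    catalog <- build_catalog(models, config$genome_fasta)
    stats <- catalog_stats(catalog, models)
    write_catalog(catalog, file.path(out_dir, "catalog.tsv"))
    jsonlite::write_json(as.list(stats), file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    results$models <<- models
    results$catalog <<- catalog
    results$catalog_stats <<- stats
    finish_stage("digest", nrow(catalog))
  })

  run_stage("quantify", function() {
    sheet <- config$sample_sheet
    if (is.character(sheet)) {
      sheet <- readr::read_tsv(sheet, show_col_types = FALSE, progress = FALSE)
    }
    tag_counts <- purrr::imap(config$reads_fastq, function(path, sid) {
      filt <- filter_reads(path, min_quality = config$min_quality,
                           strip_anchor = config$strip_anchor)
      dplyr::mutate(filt$tags, sample_id = sid)
    }) |> dplyr::bind_rows()
    matched <- match_and_count(tag_counts, results$catalog)
    genes <- gene_counts_tpm(matched, results$catalog)
    profile <- abundance_profile(genes)
    readr::write_tsv(matched$counts, file.path(out_dir, "tag_counts.tsv"),
                     progress = FALSE)
    readr::write_tsv(genes, file.path(out_dir, "gene_tpm.tsv"),
                     progress = FALSE)
    readr::write_tsv(profile, file.path(out_dir, "abundance_profile.tsv"),
                     progress = FALSE)
    jsonlite::write_json(matched$accounting,
                         file.path(out_dir, "accounting.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results$sheet <<- sheet
    results$matched <<- matched
    results$gene_counts <<- genes
    results$profile <<- profile
    finish_stage("quantify", nrow(matched$counts))
  })

  run_stage("de", function() {
    de <- run_de(results$matched$counts, results$sheet,
                 de_config(fdr_level = config$fdr_level))
    tag2gene <- results$catalog |>
      dplyr::filter(.data$origin == "cdna", .data$n_gene_copies == 1L) |>
      dplyr::distinct(.data$tag, .data$gene_id)
    de_tab <- dplyr::left_join(de$table, tag2gene, by = "tag") |>
      dplyr::relocate("gene_id", .after = "tag")
    readr::write_tsv(de_tab, file.path(out_dir, "de.tsv"), progress = FALSE)
    results$de <<- de
    results$de_table <<- de_tab
    finish_stage("de", nrow(de_tab))
  })

  if (!is.null(config$annotation_gmt)) {
    run_stage("enrich", function() {
      annotation <- read_gmt(config$annotation_gmt)
      bg <- unique(results$models$gene_id)
      expressed <- results$gene_counts |>
        dplyr::group_by(.data$gene_id) |>
        dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
        dplyr::filter(.data$total > 0) |>
        dplyr::pull(.data$gene_id)
      overrep <- ease_scan(expressed, bg, annotation,
                           fdr_level = config$fdr_level)
      ranked <- de_ranking(results$de_table |>
                             dplyr::filter(!is.na(.data$gene_id)))
      rankscan <- if (nrow(ranked) > config$n_partitions) {
        fatiscan(ranked, annotation, n_partitions = config$n_partitions,
                 fdr_level = config$fdr_level)
      } else {
        NULL
      }
      readr::write_tsv(overrep, file.path(out_dir, "enrich_overrep.tsv"),
                       progress = FALSE)
      if (!is.null(rankscan)) {
        readr::write_tsv(rankscan, file.path(out_dir, "enrich_rankscan.tsv"),
                         progress = FALSE)
      }
      results$overrep <<- overrep
      results$rankscan <<- rankscan
      finish_stage("enrich",
                   nrow(overrep) + if (is.null(rankscan)) 0L else nrow(rankscan))
    })
  }

  if (!is.null(config$qpcr_ct) && !is.null(config$qpcr_curve)) {
    run_stage("qpcr", function() {
      ct <- readr::read_tsv(config$qpcr_ct, show_col_types = FALSE,
                            progress = FALSE)
      curve <- readr::read_tsv(config$qpcr_curve, show_col_types = FALSE,
                               progress = FALSE)
      qres <- run_qpcr(ct, curve, config$reference_gene)
      readr::write_tsv(qres, file.path(out_dir, "qpcr.tsv"), progress = FALSE)
      results$qpcr <<- qres
      finish_stage("qpcr", nrow(qres))
    })
  }

  write_manifest()
  results$manifest <- manifest
  invisible(results)
}
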