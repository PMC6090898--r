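#' Pipeline configuration
#'
#' Bundles the per-stage parameters of [run_pipeline()]. Thresholds default
#' to the published analysis values: fold change 2, p < 0.05, 10,000
#' resamplings at alpha 0.05, motif p < 1e-6, minimum gene coverage 2 and
#' an SD multiplier of 1 on the log2-ratio merge rule.
#'
#' @param sim A [sim_config()] for the synthetic dataset stage.
#' @param operon A [boundary_params()].
#' @param fc_threshold,alpha DE calling thresholds (defaults 2, 0.05).
#' @param pseudo Pseudo-RPKM for fold changes (default 0.1).
#' @param prior_df Dispersion shrinkage weight (default 10).
#' @param n_resamples,enrich_alpha Enrichment resampling parameters
#'   (defaults 10000, 0.05).
#' @param direction Which DE genes enter enrichment: "both", "up" or
#'   "down" (default "both").
#' @param motif_iupac IUPAC string of the scanned motif (default the cre
#'   weight-matrix pattern `HWNMHAHSVNDHNHHN`).
#' @param motif_consensus Consensus the PWM is weighted toward (default
#'   the cre consensus; NULL for uniform-within-set probabilities).
#' @param scan A [scan_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "operons", "de", "enrichment", "motif")`.
#' @param seed Global seed; per-stage seeds are derived from it by fixed
#'   offsets so single stages can be re-run reproducibly.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            operon = boundary_params(),
                            fc_threshold = 2, alpha = 0.05, pseudo = 0.1,
                            prior_df = 10,
                            n_resamples = 10000L, enrich_alpha = 0.05,
                            direction = "both",
                            motif_iupac = "HWNMHAHSVNDHNHHN",
                            motif_consensus = "ATGAAAACGTTTTCAA",
                            scan = scan_config(),
                            stages = c("simulate", "operons", "de",
                                       "enrichment", "motif"),
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(operon, "boundary_params"),
            inherits(scan, "scan_config"))
  bad <- setdiff(stages, c("simulate", "operons", "de", "enrichment", "motif"))
  if (length(bad)) bail("unknown stage '%s'", bad[1])
  if (!direction %in% c("both", "up", "down"))
    bail("direction must be 'both', 'up' or 'down'")
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> operon reconstruction -> RPKM/DE -> category
#' enrichment -> motif scan as one reproducible run. Every stage writes its
#' outputs under `outdir`; a `summary.yaml` collects headline numbers
#' (operon count, DE up/down counts, significant categories, motif hits and
#' truth-vs-recovered comparisons), `run.log` records every parameter and
#' threshold used, and `MANIFEST.tsv` lists each output file with its MD5
#' hash. Identical config and seed give byte-identical outputs. A stage
#' failure aborts with the stage name; outputs written so far are kept and
#' the manifest is marked incomplete.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(outdir, config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed, stages = config$stages)
  log_lines <- c("bactx pipeline run",
                 sprintf("seed: %d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = ",")),
                 sprintf("fc_threshold: %g  alpha: %g", config$fc_threshold,
                         config$alpha),
                 sprintf("n_resamples: %d  enrich_alpha: %g",
                         config$n_resamples, config$enrich_alpha),
                 sprintf("motif: %s  p_threshold: %g", config$motif_iupac,
                         config$scan$p_threshold),
                 sprintf("min_gene_coverage: %g  sd_multiplier: %g",
                         config$operon$min_gene_coverage,
                         config$operon$sd_multiplier))
  outputs <- character(0)
  finish_manifest <- function(complete) {
    mf <- data.frame(file = basename(outputs),
                     md5 = unname(tools::md5sum(outputs)),
                     stringsAsFactors = FALSE)
    mf <- rbind(mf, data.frame(file = "#status",
                               md5 = if (complete) "complete" else "incomplete"))
    write_tsv(mf, file.path(outdir, "MANIFEST.tsv"))
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(log_lines, file.path(outdir, "run.log"))
      finish_manifest(FALSE)
      bail("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  emit <- function(path) outputs <<- c(outputs, path)

  ds <- NULL
  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      ds <<- simulate_dataset(config$sim)
      emit(write_genome(ds$seqs, file.path(outdir, "genome.fasta")))
      emit(write_annotation(ds$ann, file.path(outdir, "genes.gff3")))
      bg <- write_coverage(ds$track,
                           file.path(outdir, "coverage.plus.bedgraph"),
                           file.path(outdir, "coverage.minus.bedgraph"))
      emit(bg[1]); emit(bg[2])
      emit(write_counts(ds$counts, file.path(outdir, "counts.tsv")))
      emit(write_truth(ds$truth, file.path(outdir, "truth.yaml")))
    })
  }
  if (is.null(ds) && any(c("operons", "de", "enrichment", "motif") %in%
                         config$stages) &&
      !"simulate" %in% config$stages)
    bail("stages beyond 'simulate' require the simulate stage in this run")

  if ("operons" %in% config$stages) {
    run_stage("operons", function() {
      cov <- gene_mean_coverage(ds$track, ds$ann)
      ops <- reconstruct_transcripts(cov, ds$ann, ds$track, config$operon)
      tab <- operon_table(ops)
      emit(write_tsv(tab, file.path(outdir, "operons.tsv")))
      summary$n_operons <<- length(ops)
      summary$n_low_coverage_excluded <<-
        nrow(attr(ops, "low_coverage_excluded"))
      truth_part <- lapply(ds$truth$operons, function(o) sort(o$genes))
      rec_part <- lapply(ops, function(o) sort(o$genes))
      summary$operons_recovered_exactly <<-
        sum(vapply(truth_part, function(tp)
          any(vapply(rec_part, identical, TRUE, y = tp)), TRUE))
      summary$n_true_operons <<- length(truth_part)
    })
  }
  de_tab <- NULL
  if ("de" %in% config$stages) {
    run_stage("de", function() {
      de_tab <<- de_analysis(ds$counts, ds$ann,
                             fc_threshold = config$fc_threshold,
                             alpha = config$alpha, pseudo = config$pseudo,
                             prior_df = config$prior_df)
      emit(write_tsv(de_tab, file.path(outdir, "de_results.tsv")))
      summary$n_de <<- sum(de_tab$is_de)
      summary$n_de_up <<- sum(de_tab$direction == "up")
      summary$n_de_down <<- sum(de_tab$direction == "down")
      truth_de <- ds$truth$de_genes$gene_id
      called <- de_tab$gene_id[de_tab$is_de]
      summary$de_true_positive <<- length(intersect(called, truth_de))
      summary$de_false_positive <<- length(setdiff(called, truth_de))
      summary$n_true_de <<- length(truth_de)
    })
  }
  if ("enrichment" %in% config$stages) {
    run_stage("enrichment", function() {
      if (is.null(de_tab)) bail("enrichment requires the 'de' stage")
      keep <- de_tab$is_de
      if (config$direction != "both")
        keep <- keep & de_tab$direction == config$direction
      de_set <- de_tab$gene_id[keep]
      set.seed(config$seed + 10L)
      enr <- resample_enrichment(ds$truth$category_map, de_set,
                                 n_resamples = config$n_resamples,
                                 alpha = config$enrich_alpha)
      emit(write_tsv(enr, file.path(outdir, "enrichment.tsv")))
      summary$significant_categories <<-
        enr$category[enr$significant]
      summary$enriched_category_truth <<- ds$truth$enriched_category
      summary$enriched_category_recovered <<-
        ds$truth$enriched_category %in% enr$category[enr$significant]
    })
  }
  if ("motif" %in% config$stages) {
    run_stage("motif", function() {
      x <- pwm_from_iupac(config$motif_iupac, gamma = config$scan$gamma,
                          consensus = config$motif_consensus)
      hits <- scan_motifs(x, ds$seqs, config$scan)
      assigned <- assign_hits_to_genes(hits, ds$ann, config$scan)
      emit(write_hits_bed(hits, file.path(outdir, "motif_hits.bed"),
                          name = "cre"))
      emit(write_tsv(assigned, file.path(outdir, "motif_hits.tsv")))
      summary$n_motif_hits <<- nrow(hits)
      summary$n_genes_with_cre <<-
        length(unique(assigned$gene_id[!is.na(assigned$gene_id)]))
      planted <- ds$truth$planted_sites
      if (nrow(planted)) {
        key_h <- paste(hits$contig, hits$start, hits$strand)
        key_p <- paste(planted$contig, planted$start, planted$strand)
        summary$planted_sites_recovered <<- sum(key_p %in% key_h)
        summary$n_planted_sites <<- nrow(planted)
      }
    })
  }
  writeLines(log_lines, file.path(outdir, "run.log"))
  yaml::write_yaml(summary, file.path(outdir, "summary.yaml"))
  outputs <- c(outputs, file.path(outdir, "run.log"),
               file.path(outdir, "summary.yaml"))
  finish_manifest(TRUE)
  invisible(summary)
}
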