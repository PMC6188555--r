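#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: the simulation (or input
#' paths), assignment thresholds, lineage genome labels and thresholds, and
#' signature thresholds. All randomness flows from the single `seed` through
#' the simulation config.
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param sim A [sim_config()]; its `seed` seeds the whole run.
#' @param thresholds [assignment_thresholds()].
#' @param outgroup,sisters Lineage genome labels.
#' @param fail_thresh,conserve_thresh Lineage remap thresholds.
#' @param p_thresh,lfc_thresh,detect_thresh Signature thresholds.
#' @param n_perm Permutations for the built-in differential test.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            thresholds = assignment_thresholds(),
                            outgroup = "outgroup",
                            sisters = c("sister1", "sister2"),
                            fail_thresh = 0.10, conserve_thresh = 0.95,
                            p_thresh = 0.05, lfc_thresh = 1,
                            detect_thresh = 0.5, n_perm = 2000L) {
  structure(list(out_dir = out_dir, sim = sim, thresholds = thresholds,
                 outgroup = outgroup, sisters = sisters,
                 fail_thresh = fail_thresh, conserve_thresh = conserve_thresh,
                 p_thresh = p_thresh, lfc_thresh = lfc_thresh,
                 detect_thresh = detect_thresh, n_perm = as.integer(n_perm)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file.
#' @return `write_pipeline_config` returns the path; `read_pipeline_config`
#'   the config.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$families <- as.list(x$sim$families)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  fam <- as.data.frame(x$sim$families, stringsAsFactors = FALSE)
  simargs <- x$sim
  simargs$families <- fam
  simargs$annotation_probs <- unlist(simargs$annotation_probs)
  simargs$lineage_probs <- unlist(simargs$lineage_probs)
  sim <- do.call(sim_config, simargs)
  args <- x[setdiff(names(x), "sim")]
  args$sisters <- unlist(args$sisters)
  do.call(pipeline_config, c(args, list(sim = sim)))
}

#' Run the full pipeline on a simulated data set
#'
#' Executes the stages in order: simulate, read QC, k-mer partition,
#' per-locus assembly, the unique-assignment cascade, quantification,
#' gene-context annotation, lineage classification, TFBS enrichment, and
#' case/control signatures. Every stage writes its table under `out_dir` and
#' is hashed into `manifest.json`; reruns with the same config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory result plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  stage_files <- list()
  log_stage <- function(stage, files, counts = NULL) {
    stage_files[[stage]] <<- files
    msg <- paste0("[", stage, "] ",
                  paste(names(counts), unlist(counts), sep = "=",
                        collapse = " "))
    message(msg)
  }

  # 1. simulate
  sim <- simulate_te_genome(config$sim)
  rd <- simulate_reads(sim, config$sim)
  labels <- lineage_labels(sim, config$sim)
  chains <- simulate_chains(sim, labels)
  ann <- simulate_annotations(sim, rd$transcripts$locus_id, config$sim)
  write_fasta(sim$genome, file.path(out, "genome.fa"))
  write_repeatmasker_out(sim$loci, file.path(out, "te_annotation.out"))
  for (s in names(rd$samples))
    write_fastq(rd$samples[[s]], file.path(out, paste0(s, ".fastq")))
  for (g in names(chains)) {
    write_chain(chains[[g]]$fwd, file.path(out, paste0(g, "_fwd.chain")))
    write_chain(chains[[g]]$rev, file.path(out, paste0(g, "_rev.chain")))
  }
  write_gtf(ann$genes, file.path(out, "genes.gtf"))
  write_bed(ann$tfbs, file.path(out, "tfbs.bed"))
  write_bed(ann$tads, file.path(out, "tads.bed"))
  log_stage("simulate",
            c("genome.fa", "te_annotation.out", "genes.gtf", "tfbs.bed",
              "tads.bed", paste0(names(rd$samples), ".fastq")),
            list(loci = nrow(sim$loci), expressed = nrow(rd$transcripts)))

  # 2. read QC
  qc <- lapply(rd$samples, filter_by_mean_quality)
  kept <- lapply(qc, `[[`, "kept")
  qc_tab <- data.frame(sample = names(qc),
                       kept = vapply(kept, nrow, 0L),
                       dropped = vapply(qc, `[[`, 0L, "dropped"),
                       empty = vapply(qc, `[[`, 0L, "empty"))
  write_tsv(qc_tab, file.path(out, "readqc.tsv"))
  log_stage("readqc", "readqc.tsv",
            list(kept = sum(qc_tab$kept), dropped = sum(qc_tab$dropped)))

  # 3. partition reads to candidate loci
  index <- build_kmer_index(sim$loci)
  all_reads <- do.call(rbind, kept)
  partition <- resolve_partition(all_reads, partition_reads(all_reads, index),
                                 sim$loci)
  part_tab <- data.frame(read_id = names(partition),
                         loci = vapply(partition, paste, "", collapse = ","))
  write_tsv(part_tab, file.path(out, "partition.tsv"))
  log_stage("partition", "partition.tsv",
            list(reads = length(partition),
                 unassigned = attr(partition, "unassigned")))

  # 4. per-locus assembly
  models <- list()
  for (lid in sim$loci$locus_id) {
    rid <- names(partition)[vapply(partition, function(x) lid %in% x, TRUE)]
    if (!length(rid)) next
    locus_reads <- all_reads[all_reads$read_id %in% rid, , drop = FALSE]
    models[[lid]] <- assemble_locus(locus_reads, sim$loci[
      sim$loci$locus_id == lid, , drop = FALSE])
  }
  models <- do.call(rbind, models)
  asm_tab <- models[, c("transcript_id", "locus_id", "n_fragments",
                        "support_reads", "spliced", "seq")]
  write_tsv(asm_tab, file.path(out, "assembly.tsv"))
  write_fasta(setNames(models$seq, models$transcript_id),
              file.path(out, "transcripts.fa"))
  log_stage("assemble", c("assembly.tsv", "transcripts.fa"),
            list(models = nrow(models), spliced = sum(models$spliced)))

  # 5. assignment cascade
  cascade <- run_cascade(models[, c("transcript_id", "locus_id", "seq")],
                         sim$loci, config$thresholds, index = index)
  write_tsv(cascade$assignments, file.path(out, "assignments.tsv"))
  jsonlite::write_json(cascade$report, file.path(out, "stage_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  assigned <- cascade$assignments[
    cascade$assignments$stage_reached == "assigned", , drop = FALSE]
  log_stage("assign", c("assignments.tsv", "stage_report.json"),
            list(input = nrow(cascade$assignments),
                 assigned = nrow(assigned)))

  # 6. quantification over assigned transcripts
  q_tx <- models[models$transcript_id %in% assigned$transcript_id,
                 c("transcript_id", "seq"), drop = FALSE]
  em <- expression_matrix(kept, q_tx)
  write_tsv(cbind(transcript_id = rownames(em$counts),
                  as.data.frame(em$counts)), file.path(out, "counts.tsv"))
  write_tsv(cbind(transcript_id = rownames(em$tpm),
                  as.data.frame(em$tpm)), file.path(out, "tpm.tsv"))
  log_stage("quantify", c("counts.tsv", "tpm.tsv"),
            list(transcripts = nrow(em$counts),
                 ambiguous = sum(em$ambiguous)))

  # 7. gene-context annotation of assigned loci
  asg_loci <- merge(assigned[, c("transcript_id", "locus_id")], sim$loci,
                    by = "locus_id")
  annot <- annotate_loci(asg_loci[, c("transcript_id", "chrom", "start",
                                      "end", "strand")], ann$genes)
  write_tsv(annot, file.path(out, "annotation.tsv"))
  log_stage("annotate", "annotation.tsv",
            list(records = nrow(annot),
                 intergenic = sum(annot$category == "intergenic")))

  # 8. lineage classification
  calls <- lineage_calls(
    sim$loci[sim$loci$locus_id %in% assigned$locus_id, , drop = FALSE],
    chains, outgroup = config$outgroup, sisters = config$sisters,
    fail_thresh = config$fail_thresh,
    conserve_thresh = config$conserve_thresh)
  fams <- family_summary(calls, sim$loci)
  write_tsv(calls, file.path(out, "lineage_calls.tsv"))
  write_tsv(fams, file.path(out, "family_summary.tsv"))
  log_stage("lineage", c("lineage_calls.tsv", "family_summary.tsv"),
            list(loci = nrow(calls),
                 human_specific = sum(calls$human_specific)))

  # 9. TFBS enrichment of expressed loci
  expr_iv <- sim$loci[sim$loci$locus_id %in% assigned$locus_id, , drop = FALSE]
  enr <- enrich_overlap(expr_iv, sim$loci, ann$tfbs, category = "TFBS")
  write_tsv(enr, file.path(out, "enrichment.tsv"))
  log_stage("enrich", "enrichment.tsv",
            list(x = enr$x, expected = round(enr$expected, 2)))

  # 10. case/control signatures
  keep_ids <- prefilter(em$counts, detect_frac = config$detect_thresh)
  sig <- NULL
  if (length(keep_ids) >= 1L) {
    de <- de_test(em$counts[keep_ids, , drop = FALSE],
                  rd$groups[colnames(em$counts)],
                  n_perm = config$n_perm, seed = config$sim$seed)
    sig <- stratify(de, p_thresh = config$p_thresh,
                    lfc_thresh = config$lfc_thresh,
                    detect_thresh = config$detect_thresh)
    write_tsv(sig, file.path(out, "signatures.tsv"))
  }
  log_stage("signatures", "signatures.tsv",
            list(tested = length(keep_ids),
                 up = sum(sig$signature == "up"),
                 down = sum(sig$signature == "down")))

  manifest <- list(stages = lapply(names(stage_files), function(s) {
    files <- stage_files[[s]]
    list(stage = s, files = files,
         md5 = unname(tools::md5sum(file.path(out, files))))
  }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, reads = rd, chains = chains, annotations = ann,
                 qc = qc_tab, partition = partition, models = models,
                 cascade = cascade, expression = em, annotation = annot,
                 lineage = calls, family_summary = fams, enrichment = enr,
                 signatures = sig, manifest = manifest))
}
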