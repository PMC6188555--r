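one_family_cfg <- function(seed = 5, n_copies = 2L, divergence = 0.05,
                           consensus_length = 300L, indel_rate = 0,
                           truncation_prob = 0, genome_length = 8000L, ...) {
  sim_config(seed = seed, genome_length = genome_length,
             families = data.frame(name = "FamA", te_class = "SINE",
                                   consensus_length = consensus_length,
                                   n_copies = n_copies,
                                   divergence = divergence,
                                   indel_rate = indel_rate,
                                   truncation_prob = truncation_prob,
                                   stringsAsFactors = FALSE), ...)
}

test_that("simulation is deterministic under a fixed seed", {
  cfg <- one_family_cfg(seed = 9, n_copies = 4L, n_expressed_loci = 3L,
                        reads_per_transcript = 8, read_length = 60L,
                        n_samples = 3L, error_rate = 0.01)
  a <- simulate_te_genome(cfg)
  b <- simulate_te_genome(cfg)
  expect_identical(a, b)
  ra <- simulate_reads(a, cfg)
  rb <- simulate_reads(b, cfg)
  expect_identical(ra, rb)
  expect_identical(lineage_labels(a, cfg), lineage_labels(b, cfg))
})

test_that("per-copy divergence produces the expected pairwise identity", {
  # two copies mutated independently at rate d from the same consensus:
  # expected pairwise identity ~ (1 - d)^2 + d^2/3 ~ 0.903 for d = 0.05
  cfg <- one_family_cfg(seed = 21, n_copies = 2L, divergence = 0.05)
  sim <- simulate_te_genome(cfg)
  a <- align_pair(sim$loci$ref_seq[1], sim$loci$ref_seq[2])
  expect_gt(a$identity, 0.86)
  expect_lt(a$identity, 0.945)
})

test_that("zero divergence yields copies identical to the consensus", {
  cfg <- one_family_cfg(seed = 3, n_copies = 3L, divergence = 0)
  sim <- simulate_te_genome(cfg)
  expect_true(all(sim$loci$ref_seq == sim$consensi[["FamA"]]))
  expect_true(all(sim$truth$n_subs == 0L))
})

test_that("forced truncation caps copies at the truncation fraction", {
  cfg <- one_family_cfg(seed = 4, n_copies = 6L, divergence = 0,
                        truncation_prob = 1, truncation_frac = 0.5)
  sim <- simulate_te_genome(cfg)
  expect_true(all(nchar(sim$loci$ref_seq) <= 150L))
  expect_true(all(sim$truth$truncated))
})

test_that("error-free reads are exact substrings of their transcript", {
  cfg <- one_family_cfg(seed = 6, n_copies = 3L, n_expressed_loci = 3L,
                        reads_per_transcript = 6, read_length = 60L,
                        error_rate = 0, n_samples = 2L)
  sim <- simulate_te_genome(cfg)
  rd <- simulate_reads(sim, cfg)
  for (s in names(rd$samples)) {
    reads <- rd$samples[[s]]
    src <- merge(reads, rd$read_truth, by = "read_id")
    tseq <- rd$transcripts$seq[match(src$transcript_id,
                                     rd$transcripts$transcript_id)]
    found <- mapply(function(r, t) grepl(r, t, fixed = TRUE) ||
                      grepl(revcomp_test(r), t, fixed = TRUE), src$seq, tseq)
    expect_true(all(found))
  }
})

test_that("flagged transcripts carry the configured fold change in cases", {
  cfg <- one_family_cfg(seed = 31, n_copies = 220L, divergence = 0.03,
                        consensus_length = 120L, genome_length = 80000L,
                        n_expressed_loci = 220L, reads_per_transcript = 10,
                        read_length = 50L, n_samples = 8L,
                        case_fraction = 0.5, de_fraction = 0.15,
                        de_log2fc = 2)
  sim <- simulate_te_genome(cfg)
  rd <- simulate_reads(sim, cfg, sequences = FALSE)
  is_case <- rd$groups == "case"
  de <- rd$de_truth$is_de
  expect_gte(sum(de), 30L)
  mean_case <- rowMeans(rd$counts_truth[de, is_case, drop = FALSE])
  mean_ctrl <- rowMeans(rd$counts_truth[de, !is_case, drop = FALSE])
  ratio <- mean(mean_case) / mean(mean_ctrl)
  expect_gt(ratio, 3.3)
  expect_lt(ratio, 4.7)
  # unflagged transcripts stay balanced
  bal <- mean(rowMeans(rd$counts_truth[!de, is_case, drop = FALSE])) /
    mean(rowMeans(rd$counts_truth[!de, !is_case, drop = FALSE]))
  expect_gt(bal, 0.9)
  expect_lt(bal, 1.1)
})

test_that("simulated chains realise the lineage labels they are given", {
  cfg <- one_family_cfg(seed = 8, n_copies = 8L)
  sim <- simulate_te_genome(cfg)
  labels <- data.frame(locus_id = sim$loci$locus_id,
                       class = "manual",
                       outgroup = rep(c(1, 0, 0.5, 1), 2),
                       sister1 = rep(c(1, 1, 1, 0), 2),
                       sister2 = rep(c(1, 1, 1, 0), 2),
                       stringsAsFactors = FALSE)
  chains <- simulate_chains(sim, labels)
  for (i in seq_len(nrow(sim$loci))) {
    iv <- sim$loci[i, ]
    fr_out <- liftover_fraction(iv, chains$outgroup$fwd)$fraction
    fr_s1 <- liftover_fraction(iv, chains$sister1$fwd)$fraction
    expect_equal(fr_out, labels$outgroup[i], tolerance = 0.01)
    expect_equal(fr_s1, labels$sister1[i], tolerance = 0.01)
  }
  # per-base oracle agrees on the partially deleted locus
  iv <- sim$loci[3, ]
  expect_equal(oracle_liftover_fraction(iv, chains$outgroup$fwd), 0.5,
               tolerance = 0.01)
  expect_error(simulate_chains(sim, within(labels, outgroup[1] <- 2)),
               "labels")
})

test_that("annotation truth labels drive overlap counts", {
  cfg <- one_family_cfg(seed = 12, n_copies = 10L, n_expressed_loci = 10L,
                        genome_length = 30000L,
                        tfbs_overlap_fraction = 0.5,
                        annotation_probs = c(cds = 0, exon_5utr = 0,
                                             exon_3utr = 0,
                                             exon_noncoding = 0, intron = 1,
                                             intergenic = 0))
  sim <- simulate_te_genome(cfg)
  ann <- simulate_annotations(sim, sim$loci$locus_id, cfg)
  expect_true(all(ann$truth$category == "intron"))
  x <- overlap_count(sim$loci, ann$tfbs[grepl("^TFBS", ann$tfbs$name), ])
  expect_equal(x, sum(ann$truth$tfbs_overlap))
  expect_equal(sum(ann$truth$tfbs_overlap), 5L)
  # zero overlap fraction gives x = 0 against locus-internal TFBS
  cfg0 <- one_family_cfg(seed = 12, n_copies = 10L, n_expressed_loci = 10L,
                         genome_length = 30000L, tfbs_overlap_fraction = 0)
  ann0 <- simulate_annotations(sim, sim$loci$locus_id, cfg0)
  expect_equal(overlap_count(sim$loci,
                             ann0$tfbs[grepl("^TFBS", ann0$tfbs$name), ]), 0L)
})
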