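two_loci <- function(seed = 30) {
  set.seed(seed)
  a <- random_seq(300)
  ch <- strsplit(a, "")[[1]]
  for (i in c(50, 150, 250)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  data.frame(locus_id = c("A", "B"), chrom = "chrS",
             start = c(0L, 1000L), end = c(300L, 1300L), strand = "+",
             te_class = "SINE", family = "Fam",
             ref_seq = c(a, paste(ch, collapse = "")),
             stringsAsFactors = FALSE)
}

test_that("a transcript identical to one locus is assigned uniquely", {
  loci <- two_loci()
  tx <- data.frame(transcript_id = "t1", seq = loci$ref_seq[1],
                   stringsAsFactors = FALSE)
  res <- run_cascade(tx, loci)
  asg <- res$assignments
  expect_equal(asg$stage_reached, "assigned")
  expect_equal(asg$locus_id, "A")
  expect_equal(asg$n_perfect_hits, 1L)
})

test_that("transcripts matching duplicate loci are removed as non-unique", {
  loci <- two_loci()
  loci$ref_seq[2] <- loci$ref_seq[1]  # exact duplicate copies
  tx <- data.frame(transcript_id = "t1", seq = loci$ref_seq[1],
                   stringsAsFactors = FALSE)
  res <- run_cascade(tx, loci)
  expect_equal(res$assignments$stage_reached, "non_unique_removed")
  expect_equal(res$assignments$n_perfect_hits, 2L)
  expect_true(is.na(res$assignments$locus_id))
})

test_that("low query coverage fails stage one", {
  loci <- two_loci()
  # 80% of the transcript aligns, 20% is foreign sequence
  set.seed(31)
  tx <- data.frame(transcript_id = "t1",
                   seq = paste0(substring(loci$ref_seq[1], 1, 240),
                                random_seq(60)),
                   stringsAsFactors = FALSE)
  res <- run_cascade(tx, loci)
  expect_equal(res$assignments$stage_reached, "coverage_fail")
  expect_lt(res$assignments$best_coverage, 0.9)
})

test_that("imperfect but close matches fail at the identity stages", {
  loci <- two_loci()
  ch <- strsplit(loci$ref_seq[1], "")[[1]]
  for (i in seq(10, 290, by = 10))  # 29 substitutions: identity ~0.90
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  tx <- data.frame(transcript_id = c("t90", "t99"),
                   locus_id = "A",  # partition candidate: dense substitution
                                    # erases shared k-mers for t90
                   seq = c(paste(ch, collapse = ""),
                           { c2 <- strsplit(loci$ref_seq[1], "")[[1]]
                             c2[150] <- setdiff(c("A", "C", "G", "T"),
                                                c2[150])[1]
                             paste(c2, collapse = "") }),
                   stringsAsFactors = FALSE)
  res <- run_cascade(tx, loci)
  expect_equal(res$assignments$stage_reached,
               c("identity_fail", "identity_fail"))
  expect_lt(res$assignments$best_identity[1], 0.95)
  expect_gte(res$assignments$best_identity[2], 0.95)  # fails only stage 3
})

test_that("a transcript with no candidates fails coverage with empty list", {
  loci <- two_loci()
  set.seed(32)
  tx <- data.frame(transcript_id = "t1", seq = random_seq(200),
                   stringsAsFactors = FALSE)
  res <- run_cascade(tx, loci)
  expect_equal(res$assignments$stage_reached, "coverage_fail")
  expect_true(is.na(res$assignments$best_identity))
})

test_that("stage counts partition the input and order does not matter", {
  loci <- two_loci()
  set.seed(33)
  tx <- data.frame(
    transcript_id = c("good", "junk", "dup"),
    seq = c(loci$ref_seq[1], random_seq(150), loci$ref_seq[2]),
    stringsAsFactors = FALSE)
  res <- run_cascade(tx, loci)
  expect_equal(sum(res$report$n), nrow(tx))
  shuffled <- tx[c(3, 1, 2), ]
  res2 <- run_cascade(shuffled, loci)
  m <- merge(res$assignments, res2$assignments, by = "transcript_id")
  expect_equal(m$stage_reached.x, m$stage_reached.y)
  expect_equal(m$locus_id.x, m$locus_id.y)
})

test_that("raising thresholds never grows the assigned set", {
  cfg <- sim_config(seed = 34, genome_length = 30000L,
                    families = data.frame(name = "F", te_class = "SINE",
                                          consensus_length = 250L,
                                          n_copies = 12L, divergence = 0.04,
                                          indel_rate = 0.005,
                                          truncation_prob = 0.2,
                                          stringsAsFactors = FALSE),
                    n_expressed_loci = 12L)
  sim <- simulate_te_genome(cfg)
  tx <- data.frame(transcript_id = paste0(sim$loci$locus_id, ".t"),
                   seq = sim$loci$ref_seq, stringsAsFactors = FALSE)
  # degrade some transcripts so stages actually separate
  set.seed(35)
  for (i in seq(1, 12, by = 3)) {
    ch <- strsplit(tx$seq[i], "")[[1]]
    pos <- sample(length(ch), 6)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    tx$seq[i] <- paste(ch, collapse = "")
  }
  idx <- build_kmer_index(sim$loci)
  loose <- run_cascade(tx, sim$loci, assignment_thresholds(0.80, 0.90, 0.95),
                       index = idx)
  strict <- run_cascade(tx, sim$loci, assignment_thresholds(0.90, 0.95, 1.0),
                        index = idx)
  loose_set <- loose$assignments$transcript_id[
    loose$assignments$stage_reached == "assigned"]
  strict_set <- strict$assignments$transcript_id[
    strict$assignments$stage_reached == "assigned"]
  expect_true(all(strict_set %in% loose_set))
})

test_that("retention percentages mirror the reporting convention", {
  asg <- data.frame(
    transcript_id = paste0("t", 1:100),
    stage_reached = c(rep("assigned", 40), rep("coverage_fail", 30),
                      rep("identity_fail", 25),
                      rep("non_unique_removed", 5)),
    stringsAsFactors = FALSE)
  rep_tab <- stage_report(asg)
  expect_equal(rep_tab$n[rep_tab$stage == "assigned"], 40L)
  expect_equal(rep_tab$pct[rep_tab$stage == "assigned"], 40)
  expect_equal(sum(rep_tab$n), 100L)
  all_fail <- data.frame(transcript_id = "t", stage_reached = "coverage_fail")
  expect_equal(sum(stage_report(all_fail)$n), 1L)
})

test_that("threshold constructor rejects invalid settings", {
  expect_error(assignment_thresholds(min_identity = 0.99,
                                     unique_identity = 0.95))
  expect_error(assignment_thresholds(min_query_coverage = 0))
})
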