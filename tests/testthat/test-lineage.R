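identity_chain <- function(L = 1000L, chrom = "chrT", qchrom = "chrQ",
                           score = 1000) {
  make_chain("1", score, chrom, L, 0L, L, qchrom, L, 0L, L,
             data.frame(size = L, dt = NA_real_, dq = NA_real_))
}

iv <- function(s, e, chrom = "chrT") {
  data.frame(chrom = chrom, start = s, end = e, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("an identity chain maps an interval onto itself", {
  ch <- identity_chain()
  res <- liftover_fraction(iv(100L, 200L), list(ch))
  expect_equal(res$fraction, 1)
  expect_equal(res$mapped$start, 100L)
  expect_equal(res$mapped$end, 200L)
})

test_that("an interval half inside a chain gap remaps at one half", {
  # blocks: [0,100) aligned, [100,200) gap (dt), [200,300) aligned
  ch <- make_chain("1", 1000, "chrT", 300L, 0L, 300L, "chrQ", 200L, 0L, 200L,
                   data.frame(size = c(100, 100), dt = c(100, NA),
                              dq = c(0, NA)))
  res <- liftover_fraction(iv(50L, 150L), list(ch))
  expect_equal(res$fraction, 0.5)
  expect_equal(oracle_liftover_fraction(iv(50L, 150L), list(ch)), 0.5)
})

test_that("minus-strand chain images match the per-base oracle", {
  ch <- make_chain("1", 1000, "chrT", 400L, 50L, 350L, "chrQ", 500L, 100L,
                   400L, data.frame(size = c(120, 180), dt = c(0, NA),
                                    dq = c(0, NA)), q_strand = "-")
  interval <- iv(80L, 160L)
  res <- liftover_fraction(interval, list(ch))
  expect_equal(res$fraction, 1)
  oracle <- oracle_map_bases(interval, ch)
  expect_equal(sort(unlist(Map(seq, res$mapped$start,
                               res$mapped$end - 1L))), sort(oracle))
})

test_that("liftover agrees with the per-base oracle on random chains", {
  set.seed(60)
  for (rep in 1:20) {
    n_blocks <- sample(1:5, 1)
    sizes <- sample(20:80, n_blocks, replace = TRUE)
    dt <- c(sample(0:50, n_blocks - 1, replace = TRUE), NA)
    dq <- c(sample(0:50, n_blocks - 1, replace = TRUE), NA)
    t_span <- sum(sizes) + sum(dt, na.rm = TRUE)
    q_span <- sum(sizes) + sum(dq, na.rm = TRUE)
    t_start <- sample(0:100, 1)
    q_start <- sample(0:100, 1)
    qs <- sample(c("+", "-"), 1)
    ch <- make_chain("1", 1000, "chrT", t_start + t_span + 50L,
                     t_start, t_start + t_span, "chrQ",
                     q_start + q_span + 50L, q_start, q_start + q_span,
                     data.frame(size = sizes, dt = dt, dq = dq),
                     q_strand = qs)
    s <- sample(0:(t_start + t_span - 10L), 1)
    interval <- iv(s, s + sample(10:120, 1))
    res <- liftover_fraction(interval, list(ch))
    oracle <- oracle_map_bases(interval, ch)
    expect_equal(res$fraction, mean(!is.na(oracle)))
    got <- if (nrow(res$mapped)) sort(unlist(Map(seq, res$mapped$start,
                                                 res$mapped$end - 1L)))
           else integer()
    expect_equal(got, sort(oracle[!is.na(oracle)]))
  }
})

test_that("the best-scoring chain wins when several overlap", {
  ch_good <- identity_chain(score = 2000)
  ch_bad <- make_chain("2", 10, "chrT", 1000L, 0L, 1000L, "chrOther", 1000L,
                       0L, 1000L,
                       data.frame(size = 1000, dt = NA_real_,
                                  dq = NA_real_))
  res <- liftover_fraction(iv(0L, 100L), list(ch_bad, ch_good))
  expect_equal(res$mapped$chrom[1], "chrQ")
  res2 <- liftover_fraction(iv(0L, 100L), list(ch_good, ch_bad))
  expect_equal(res2$mapped$chrom[1], "chrQ")
})

test_that("no overlapping chain gives fraction zero, not an error", {
  res <- liftover_fraction(iv(0L, 50L, chrom = "chrZ"),
                           list(identity_chain()))
  expect_equal(res$fraction, 0)
  expect_equal(nrow(res$mapped), 0L)
})

test_that("reciprocal mapping composes forward and backward chains", {
  ch <- identity_chain()
  rev <- make_chain("1", 1000, "chrQ", 1000L, 0L, 1000L, "chrT", 1000L, 0L,
                    1000L, data.frame(size = 1000, dt = NA_real_,
                                      dq = NA_real_))
  expect_equal(reciprocal_fraction(iv(100L, 300L), list(ch), list(rev)), 1)
  # reverse chain deletes the second half of the query genome
  rev_half <- make_chain("1", 1000, "chrQ", 1000L, 0L, 200L, "chrT", 1000L,
                         0L, 200L, data.frame(size = 200, dt = NA_real_,
                                              dq = NA_real_))
  expect_equal(reciprocal_fraction(iv(100L, 300L), list(ch), list(rev_half)),
               0.5)
  # disjoint chains recover nothing
  rev_off <- make_chain("1", 1000, "chrQ", 1000L, 500L, 600L, "chrElse",
                        1000L, 0L, 100L,
                        data.frame(size = 100, dt = NA_real_,
                                   dq = NA_real_))
  expect_equal(reciprocal_fraction(iv(100L, 300L), list(ch), list(rev_off)),
               0)
})

test_that("lineage flags follow the remap-fraction rules", {
  d1 <- c(outgroup = 0, sister1 = 1, sister2 = 1)
  r1 <- c(sister1 = 1, sister2 = 1)
  call <- classify_lineage("L1", d1, r1)
  expect_true(call$primate_specific)
  expect_true(call$highly_conserved_primates)
  expect_false(call$human_specific)

  d2 <- c(outgroup = 0, sister1 = 0.05, sister2 = 0.02)
  call2 <- classify_lineage("L2", d2, c(sister1 = 0, sister2 = 0))
  expect_true(call2$primate_specific)
  expect_true(call2$human_specific)
  expect_false(call2$highly_conserved_primates)

  d3 <- c(outgroup = 0.97, sister1 = 0.97, sister2 = 0.96)
  call3 <- classify_lineage("L3", d3, c(sister1 = 0.95, sister2 = 0.95))
  expect_false(call3$primate_specific)
  expect_true(call3$highly_conserved_primates)
  expect_false(call3$human_specific)

  # reciprocal failure blocks conservation even with direct success
  call4 <- classify_lineage("L4", d3, c(sister1 = 0.5, sister2 = 0.95))
  expect_false(call4$highly_conserved_primates)
  expect_error(classify_lineage("L5", c(outgroup = 1), c(sister1 = 1)),
               "missing")
})

test_that("lineage truth labels are recovered without error on chains", {
  cfg <- sim_config(seed = 61, genome_length = 20000L,
                    families = data.frame(name = "F", te_class = "SINE",
                                          consensus_length = 200L,
                                          n_copies = 12L, divergence = 0.03,
                                          indel_rate = 0, truncation_prob = 0,
                                          stringsAsFactors = FALSE))
  sim <- simulate_te_genome(cfg)
  labels <- lineage_labels(sim, cfg)
  chains <- simulate_chains(sim, labels)
  calls <- lineage_calls(sim$loci, chains)
  m <- merge(calls, labels, by = "locus_id")
  expect_equal(m$primate_specific,
               m$class %in% c("primate_specific", "human_specific"))
  expect_equal(m$human_specific, m$class == "human_specific")
  expect_equal(m$highly_conserved_primates,
               m$class %in% c("conserved_all", "primate_specific",
                              "partial_outgroup"))
})

test_that("raising the conservation threshold shrinks the conserved set", {
  set.seed(62)
  fracs <- runif(50, 0.5, 1)
  calls_lo <- vapply(fracs, function(f)
    classify_lineage("x", c(outgroup = 1, sister1 = f, sister2 = f),
                     c(sister1 = f, sister2 = f),
                     conserve_thresh = 0.7)$highly_conserved_primates, TRUE)
  calls_hi <- vapply(fracs, function(f)
    classify_lineage("x", c(outgroup = 1, sister1 = f, sister2 = f),
                     c(sister1 = f, sister2 = f),
                     conserve_thresh = 0.9)$highly_conserved_primates, TRUE)
  expect_true(all(calls_lo >= calls_hi))
})

test_that("family ratios and summaries follow the signed convention", {
  expect_equal(family_ratio(51, 354), 6.9)
  expect_equal(family_ratio(140, 10), -14)
  expect_equal(family_ratio(0, 5), Inf)
  expect_equal(family_ratio(5, 0), -Inf)
  expect_equal(family_ratio(0, 0), Inf)

  calls <- data.frame(locus_id = paste0("L", 1:6),
                      highly_conserved_primates = c(TRUE, TRUE, FALSE, FALSE,
                                                    FALSE, FALSE),
                      human_specific = c(FALSE, FALSE, TRUE, TRUE, TRUE,
                                         FALSE),
                      stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = paste0("L", 1:6),
                     family = c("A", "A", "A", "B", "B", "B"),
                     stringsAsFactors = FALSE)
  fs <- family_summary(calls, loci)
  a <- fs[fs$family == "A", ]
  expect_equal(a$n_conserved, 2L)
  expect_equal(a$n_human_specific, 1L)
  expect_equal(a$ratio, -2)
  expect_equal(a$pct_conserved_or_human_specific, 100)
})
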