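#' Simulation configuration
#'
#' Parameters of the synthetic study: a toy genome carrying several diverged
#' copies of TE family consensus sequences, strand-specific paired reads from
#' a case/control design, chain files for three non-focal genomes (an
#' outgroup playing the mouse role and two sister genomes playing the
#' chimpanzee/bonobo roles), and gene/TFBS/TAD annotations.
#'
#' Defaults mirror the study design the package emulates: 19 samples with 9
#' cases, 100 bp paired-end reads, a 2-fold differential-expression effect,
#' and copies separated by the private substitutions and short indels they
#' accumulated since insertion (per-copy divergence of 5--10%, the regime in
#' which sibling copies are distinguishable but confusable).
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param genome_length Background genome length in bp before TE insertion.
#' @param families Data frame with columns `name`, `te_class`,
#'   `consensus_length`, `n_copies`, `divergence` (per-base substitution
#'   rate), `indel_rate`, `truncation_prob`.
#' @param truncation_frac Fraction of the consensus retained (from the 3'
#'   end, the L1-style truncation) when a copy is truncated.
#' @param n_expressed_loci Number of loci that produce transcripts.
#' @param reads_per_transcript Mean read pairs per transcript per sample.
#' @param read_length Read length in bp.
#' @param error_rate Per-base sequencing error rate.
#' @param n_samples,case_fraction Sample design.
#' @param de_fraction Fraction of expressed transcripts that are
#'   differentially expressed (up in cases).
#' @param de_log2fc Log2 fold change applied to flagged transcripts in cases.
#' @param annotation_probs Named probabilities over gene-context categories
#'   (`cds`, `exon_5utr`, `exon_3utr`, `exon_noncoding`, `intron`,
#'   `intergenic`).
#' @param tfbs_overlap_fraction Fraction of expressed loci given an internal
#'   TFBS interval.
#' @param lineage_probs Named probabilities over lineage classes
#'   (`conserved_all`, `primate_specific`, `human_specific`,
#'   `partial_outgroup`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       families = data.frame(
                         name = c("AluSim", "L1Sim", "HervSim"),
                         te_class = c("SINE", "LINE", "LTR"),
                         consensus_length = c(300L, 900L, 600L),
                         n_copies = c(12L, 8L, 6L),
                         divergence = c(0.05, 0.08, 0.10),
                         indel_rate = c(0.005, 0.005, 0.005),
                         truncation_prob = c(0, 0.3, 0),
                         stringsAsFactors = FALSE),
                       truncation_frac = 0.5,
                       n_expressed_loci = 12L,
                       reads_per_transcript = 30,
                       read_length = 100L,
                       error_rate = 0.005,
                       n_samples = 19L,
                       case_fraction = 9 / 19,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       annotation_probs = c(cds = 0.05, exon_5utr = 0.05,
                                            exon_3utr = 0.10,
                                            exon_noncoding = 0.10,
                                            intron = 0.50,
                                            intergenic = 0.20),
                       tfbs_overlap_fraction = 0.5,
                       lineage_probs = c(conserved_all = 0.40,
                                         primate_specific = 0.40,
                                         human_specific = 0.15,
                                         partial_outgroup = 0.05)) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              families = families, truncation_frac = truncation_frac,
              n_expressed_loci = as.integer(n_expressed_loci),
              reads_per_transcript = reads_per_transcript,
              read_length = as.integer(read_length), error_rate = error_rate,
              n_samples = as.integer(n_samples), case_fraction = case_fraction,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              annotation_probs = annotation_probs,
              tfbs_overlap_fraction = tfbs_overlap_fraction,
              lineage_probs = lineage_probs)
  rates <- c(families$divergence, families$indel_rate,
             families$truncation_prob, truncation_frac, error_rate,
             case_fraction, de_fraction, tfbs_overlap_fraction)
  stopifnot(all(rates >= 0), all(rates <= 1))
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# apply substitutions, short indels (geometric length, p = 0.5, capped at
# 5 bp) and optional 5' truncation to a consensus
mutate_copy <- function(consensus, divergence, indel_rate, truncation_prob,
                        truncation_frac) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(consensus, "")[[1]]
  sub_at <- which(runif(length(ch)) < divergence)
  for (i in sub_at) ch[i] <- sample(setdiff(bases, ch[i]), 1)
  indel_at <- sort(which(runif(length(ch)) < indel_rate), decreasing = TRUE)
  n_indels <- length(indel_at)
  for (i in indel_at) {
    len <- min(rgeom(1, 0.5) + 1L, 5L)
    if (runif(1) < 0.5) {
      ch <- append(ch, sample(bases, len, replace = TRUE), after = i)
    } else {
      drop <- seq(i, min(i + len - 1L, length(ch)))
      ch <- ch[-drop]
    }
  }
  truncated <- runif(1) < truncation_prob
  if (truncated) {
    keep <- max(1L, floor(truncation_frac * length(ch)))
    ch <- tail(ch, keep)
  }
  list(seq = paste(ch, collapse = ""), n_subs = length(sub_at),
       n_indels = n_indels, truncated = truncated)
}

#' Simulate a toy genome carrying diverged TE copies
#'
#' Generates a random background genome, a random consensus per family, and
#' per-copy sequences mutated independently from the consensus (a star
#' phylogeny: each copy carries private substitutions and indels, the signal
#' the assignment cascade exploits). Copies are inserted at non-overlapping
#' positions on random strands; minus-strand copies appear reverse
#' complemented in the genome and their `ref_seq` is kept in TE orientation.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character vector, one chromosome),
#'   `loci` (TE locus table with `ref_seq`), `consensi` (per family) and
#'   `truth` (per-copy mutation record: `n_subs`, `n_indels`, `truncated`).
#' @export
simulate_te_genome <- function(cfg) {
  set.seed(cfg$seed)
  fam <- cfg$families
  copies <- list()
  consensi <- setNames(character(nrow(fam)), fam$name)
  for (f in seq_len(nrow(fam))) {
    consensi[f] <- random_dna(fam$consensus_length[f])
    for (i in seq_len(fam$n_copies[f])) {
      mut <- mutate_copy(consensi[f], fam$divergence[f], fam$indel_rate[f],
                         fam$truncation_prob[f], cfg$truncation_frac)
      copies[[length(copies) + 1L]] <-
        c(list(locus_id = paste0(fam$name[f], ".", length(copies) + 1L),
               family = fam$name[f], te_class = fam$te_class[f]), mut)
    }
  }
  n <- length(copies)
  # insertion points in the background, spliced in left to right
  points <- sort(sample.int(cfg$genome_length - 1L, n))
  if (any(diff(points) < 2L))
    points <- sort(seq(1L, cfg$genome_length - 1L,
                       length.out = n + 2L))[seq_len(n) + 1L]
  background <- random_dna(cfg$genome_length)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  pieces <- character(2L * n + 1L)
  starts <- integer(n)
  prev <- 0L
  offset <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substring(background, prev + 1L, points[i])
    s <- copies[[i]]$seq
    pieces[2L * i] <- if (strands[i] == "-") revcomp(s) else s
    starts[i] <- points[i] + offset
    offset <- offset + nchar(s)
    prev <- points[i]
  }
  pieces[2L * n + 1L] <- substring(background, prev + 1L, cfg$genome_length)
  genome <- c(chrS = paste(pieces, collapse = ""))

  loci <- data.frame(
    locus_id = vapply(copies, `[[`, "", "locus_id"),
    chrom = "chrS",
    start = starts,
    end = starts + vapply(copies, function(x) nchar(x$seq), 0L),
    strand = strands,
    te_class = vapply(copies, `[[`, "", "te_class"),
    family = vapply(copies, `[[`, "", "family"),
    ref_seq = vapply(copies, `[[`, "", "seq"),
    stringsAsFactors = FALSE)
  stopifnot(identical(extract_locus_seq(loci, genome), loci$ref_seq))
  truth <- data.frame(
    locus_id = loci$locus_id,
    n_subs = vapply(copies, `[[`, 0L, "n_subs"),
    n_indels = vapply(copies, `[[`, 0L, "n_indels"),
    truncated = vapply(copies, `[[`, TRUE, "truncated"),
    stringsAsFactors = FALSE)
  list(genome = genome, loci = loci, consensi = consensi, truth = truth)
}

#' Simulate strand-specific paired reads from expressed loci
#'
#' Chooses the expressed loci, assigns the case/control design, flags a
#' fraction of transcripts as differentially expressed (mean multiplied by
#' `2^de_log2fc` in cases), and draws Poisson read-pair counts per
#' transcript and sample. Mate 1 is on the transcript strand, mate 2 reverse
#' complemented; base errors are i.i.d. at `error_rate` and every base gets
#' the Phred score implied by that rate. Transcripts shorter than the read
#' length are skipped and counted.
#'
#' @param sim Output of [simulate_te_genome()].
#' @param cfg The [sim_config()] used.
#' @param sequences Generate the read sequences themselves (default TRUE).
#'   With FALSE only the design, truth tables and per-transcript pair counts
#'   are drawn -- sufficient (and much faster) for count-level studies of the
#'   detection filter and differential test.
#' @return List with `samples` (named list of read tables), `groups`
#'   (case/control per sample), `transcripts` (transcript table with true
#'   `locus_id`), `read_truth` (read to transcript map), `counts_truth`
#'   (transcripts x samples matrix of simulated pair counts), `de_truth`,
#'   and `n_skipped`.
#' @export
simulate_reads <- function(sim, cfg, sequences = TRUE) {
  set.seed(cfg$seed + 1L)
  eligible <- sim$loci
  n_expr <- min(cfg$n_expressed_loci, nrow(eligible))
  expr <- eligible[sort(sample.int(nrow(eligible), n_expr)), , drop = FALSE]
  transcripts <- data.frame(transcript_id = paste0(expr$locus_id, ".t1"),
                            locus_id = expr$locus_id, seq = expr$ref_seq,
                            stringsAsFactors = FALSE)
  n_de <- round(cfg$de_fraction * nrow(transcripts))
  de_ids <- sample(transcripts$transcript_id, n_de)
  de_truth <- data.frame(transcript_id = transcripts$transcript_id,
                         is_de = transcripts$transcript_id %in% de_ids,
                         stringsAsFactors = FALSE)
  n_case <- round(cfg$case_fraction * cfg$n_samples)
  groups <- c(rep("case", n_case), rep("control", cfg$n_samples - n_case))
  sample_ids <- sprintf("s%02d", seq_len(cfg$n_samples))
  names(groups) <- sample_ids

  qchar <- phred_encode(rep(
    max(2L, min(40L, round(-10 * log10(max(cfg$error_rate, 1e-4))))),
    cfg$read_length))
  n_skipped <- 0L
  counts_truth <- matrix(0L, nrow(transcripts), cfg$n_samples,
                         dimnames = list(transcripts$transcript_id,
                                         sample_ids))
  samples <- setNames(vector("list", cfg$n_samples), sample_ids)
  read_truth <- list()
  for (s in seq_len(cfg$n_samples)) {
    recs <- list()
    for (t in seq_len(nrow(transcripts))) {
      tseq <- transcripts$seq[t]
      tlen <- nchar(tseq)
      mu <- cfg$reads_per_transcript *
        if (de_truth$is_de[t] && groups[s] == "case") 2^cfg$de_log2fc else 1
      npairs <- rpois(1, mu)
      if (npairs == 0L) next
      if (tlen < cfg$read_length) {
        n_skipped <- n_skipped + 1L
        next
      }
      counts_truth[t, s] <- npairs
      if (!sequences) next
      frag <- pmin(tlen, pmax(cfg$read_length,
                              round(stats::rnorm(npairs, 2.5 * cfg$read_length,
                                                 0.3 * cfg$read_length))))
      start <- vapply(tlen - frag, function(m) sample.int(m + 1L, 1L) - 1L, 0L)
      m1 <- substring(tseq, start + 1L, start + cfg$read_length)
      m2 <- revcomp(substring(tseq, start + frag - cfg$read_length + 1L,
                              start + frag))
      ids <- sprintf("%s_%s_p%04d", sample_ids[s],
                     transcripts$transcript_id[t], seq_len(npairs))
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = rep(ids, 2L), mate = rep(c(1L, 2L), each = npairs),
        seq = add_seq_errors(c(m1, m2), cfg$error_rate),
        qual = qchar, stringsAsFactors = FALSE)
      read_truth[[length(read_truth) + 1L]] <- data.frame(
        read_id = ids, sample = sample_ids[s],
        transcript_id = transcripts$transcript_id[t],
        locus_id = transcripts$locus_id[t], stringsAsFactors = FALSE)
    }
    samples[[s]] <- if (length(recs)) do.call(rbind, recs) else
      data.frame(read_id = character(), mate = integer(), seq = character(),
                 qual = character(), stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    warning(n_skipped, " transcript/sample draws skipped: transcript ",
            "shorter than the read length")
  list(samples = samples, groups = groups, transcripts = transcripts,
       read_truth = do.call(rbind, read_truth), counts_truth = counts_truth,
       de_truth = de_truth, n_skipped = n_skipped)
}

add_seq_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Assign per-locus lineage labels for chain simulation
#'
#' Draws a lineage class per locus and converts it to the per-genome
#' present-base fractions [simulate_chains()] consumes: `conserved_all`
#' (fraction 1 everywhere), `primate_specific` (absent from the outgroup,
#' present in sisters), `human_specific` (absent from outgroup and sisters),
#' `partial_outgroup` (half the locus deleted in the outgroup).
#'
#' @param sim Output of [simulate_te_genome()].
#' @param cfg The [sim_config()].
#' @return Data frame with `locus_id`, `class`, and fraction columns
#'   `outgroup`, `sister1`, `sister2`.
#' @export
lineage_labels <- function(sim, cfg) {
  set.seed(cfg$seed + 2L)
  cls <- sample(names(cfg$lineage_probs), nrow(sim$loci), replace = TRUE,
                prob = cfg$lineage_probs)
  frac <- function(class, genome) {
    switch(class,
           conserved_all = 1,
           primate_specific = if (genome == "outgroup") 0 else 1,
           human_specific = 0,
           partial_outgroup = if (genome == "outgroup") 0.5 else 1)
  }
  data.frame(locus_id = sim$loci$locus_id, class = cls,
             outgroup = vapply(cls, frac, 0, genome = "outgroup"),
             sister1 = vapply(cls, frac, 0, genome = "sister1"),
             sister2 = vapply(cls, frac, 0, genome = "sister2"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate genome-alignment chains for the non-focal genomes
#'
#' For each genome label, deletes from a copy of the focal genome the bases
#' each locus is labelled as lacking there (fraction < 1 deletes the leading
#' part of the locus span; fraction 0 deletes it entirely) and emits the
#' forward chain (focal genome as target) plus the reciprocal reverse chain.
#' Conserved loci therefore sit wholly inside aligned blocks, and
#' species-specific loci fall in target gaps (`dt`) of the forward chain.
#'
#' @param sim Output of [simulate_te_genome()].
#' @param labels Label table from [lineage_labels()]; fractions outside
#'   `[0, 1]` are an error.
#' @param genomes Genome label columns of `labels` to build chains for.
#' @return Named list per genome with elements `fwd` and `rev` (lists of
#'   chains), ready for [lineage_calls()].
#' @export
simulate_chains <- function(sim, labels,
                            genomes = c("outgroup", "sister1", "sister2")) {
  G <- nchar(sim$genome[[1]])
  chrom <- names(sim$genome)[1]
  out <- setNames(vector("list", length(genomes)), genomes)
  for (g in genomes) {
    fr <- labels[[g]]
    if (is.null(fr) || any(fr < 0) || any(fr > 1))
      stop("contradictory or missing lineage labels for genome ", g)
    m <- merge(labels[, c("locus_id", g)], sim$loci, by = "locus_id")
    del <- m[m[[g]] < 1, , drop = FALSE]
    del_len <- round((1 - del[[g]]) * (del$end - del$start))
    dels <- data.frame(start = del$start, end = del$start + del_len)
    dels <- dels[dels$end > dels$start, , drop = FALSE]
    dels <- dels[order(dels$start), , drop = FALSE]
    # aligned segments = genome minus deleted spans
    seg_start <- c(0L, dels$end)
    seg_end <- c(dels$start, G)
    keep <- seg_end > seg_start
    seg_start <- seg_start[keep]
    seg_end <- seg_end[keep]
    sizes <- seg_end - seg_start
    dt <- c(seg_start[-1] - seg_end[-length(seg_end)], NA)
    dq <- c(rep(0L, length(sizes) - 1L), NA)
    qsize <- sum(sizes)
    qchrom <- paste0(g, "_chr")
    fwd <- make_chain("1", 1000 * sum(sizes), chrom, G, seg_start[1],
                      seg_end[length(seg_end)], qchrom, qsize, 0L, qsize,
                      data.frame(size = sizes, dt = dt, dq = dq))
    rev <- make_chain("1", 1000 * sum(sizes), qchrom, qsize, 0L, qsize,
                      chrom, G, seg_start[1], seg_end[length(seg_end)],
                      data.frame(size = sizes, dt = dq, dq = dt))
    out[[g]] <- list(fwd = list(fwd), rev = list(rev))
  }
  out
}

#' Simulate gene models, TFBS and TAD annotations around expressed loci
#'
#' Draws a gene-context category per expressed locus from
#' `cfg$annotation_probs` and builds a minimal gene realising it (flanking
#' exons for introns, a covering CDS/UTR/exon otherwise), places TFBS
#' intervals inside a configurable fraction of expressed loci (plus decoys in
#' intergenic gaps), and tiles the genome into TAD windows.
#'
#' @param sim Output of [simulate_te_genome()].
#' @param expressed_ids Locus ids of the expressed loci.
#' @param cfg The [sim_config()].
#' @return List with `genes` (feature table), `tfbs` (BED-style intervals),
#'   `tads`, and `truth` (per expressed locus: drawn `category`,
#'   `tfbs_overlap`).
#' @export
simulate_annotations <- function(sim, expressed_ids, cfg) {
  set.seed(cfg$seed + 3L)
  loci <- sim$loci
  expr <- loci[loci$locus_id %in% expressed_ids, , drop = FALSE]
  expr <- expr[order(expr$start), , drop = FALSE]
  G <- nchar(sim$genome[[1]])
  chrom <- names(sim$genome)[1]
  cats <- sample(names(cfg$annotation_probs), nrow(expr), replace = TRUE,
                 prob = cfg$annotation_probs)
  # margins kept clear of neighbouring loci so each gene tags one locus
  all_pos <- sort(c(0L, loci$start, loci$end, G))
  margin <- vapply(seq_len(nrow(expr)), function(i) {
    lo <- max(all_pos[all_pos < expr$start[i]], 0L)
    hi <- min(all_pos[all_pos > expr$end[i]], G)
    min(150L, (expr$start[i] - lo) %/% 2L, (hi - expr$end[i]) %/% 2L)
  }, 0L)
  genes <- list()
  for (i in seq_len(nrow(expr))) {
    if (cats[i] == "intergenic") next
    m <- max(margin[i], 30L)
    gs <- max(0L, expr$start[i] - m)
    ge <- min(G, expr$end[i] + m)
    gid <- paste0("G", i)
    strand <- sample(c("+", "-"), 1)
    row <- function(feature, s, e, biotype)
      data.frame(gene_id = gid, biotype = biotype, feature = feature,
                 chrom = chrom, start = s, end = e, strand = strand,
                 stringsAsFactors = FALSE)
    feats <- switch(
      cats[i],
      intron = rbind(row("gene", gs, ge, "protein_coding"),
                     row("exon", gs, gs + 15L, "protein_coding"),
                     row("exon", ge - 15L, ge, "protein_coding"),
                     row("CDS", gs, gs + 15L, "protein_coding")),
      exon_noncoding = rbind(row("gene", gs, ge, "lncRNA"),
                             row("exon", gs, ge, "lncRNA")),
      cds = rbind(row("gene", gs, ge, "protein_coding"),
                  row("exon", gs, ge, "protein_coding"),
                  row("CDS", gs, ge, "protein_coding")),
      exon_5utr = rbind(row("gene", gs, ge, "protein_coding"),
                        row("exon", gs, ge, "protein_coding"),
                        row("five_prime_utr", expr$start[i], expr$end[i],
                            "protein_coding"),
                        row("CDS", ge - 10L, ge, "protein_coding")),
      exon_3utr = rbind(row("gene", gs, ge, "protein_coding"),
                        row("exon", gs, ge, "protein_coding"),
                        row("three_prime_utr", expr$start[i], expr$end[i],
                            "protein_coding"),
                        row("CDS", gs, gs + 10L, "protein_coding")))
    genes[[length(genes) + 1L]] <- feats
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), biotype = character(),
               feature = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), stringsAsFactors = FALSE)

  n_tf <- round(cfg$tfbs_overlap_fraction * nrow(expr))
  tf_idx <- sort(sample.int(nrow(expr), n_tf))
  tfbs <- lapply(tf_idx, function(i) {
    len <- min(20L, (expr$end[i] - expr$start[i]) %/% 2L)
    s <- expr$start[i] + (expr$end[i] - expr$start[i] - len) %/% 2L
    data.frame(chrom = chrom, start = s, end = s + len,
               name = paste0("TFBS", i), score = 0, strand = ".",
               stringsAsFactors = FALSE)
  })
  # decoy TFBS in locus-free gaps
  gaps_s <- c(0L, loci$end)
  gaps_e <- c(loci$start, G)
  big <- which(gaps_e - gaps_s > 60L)
  decoys <- lapply(head(big, 10L), function(j) {
    mid <- (gaps_s[j] + gaps_e[j]) %/% 2L
    data.frame(chrom = chrom, start = mid - 10L, end = mid + 10L,
               name = paste0("decoy", j), score = 0, strand = ".",
               stringsAsFactors = FALSE)
  })
  tfbs <- do.call(rbind, c(tfbs, decoys))

  n_tads <- 10L
  bounds <- round(seq(0L, G, length.out = n_tads + 1L))
  tads <- data.frame(chrom = chrom, start = bounds[-(n_tads + 1L)],
                     end = bounds[-1], name = paste0("TAD", seq_len(n_tads)),
                     score = 0, strand = ".", stringsAsFactors = FALSE)

  truth <- data.frame(locus_id = expr$locus_id, category = cats,
                      tfbs_overlap = seq_len(nrow(expr)) %in% tf_idx,
                      stringsAsFactors = FALSE)
  list(genes = genes, tfbs = tfbs, tads = tads, truth = truth)
}
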