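#' Build a canonical k-mer index over locus sequences
#'
#' Maps every canonical k-mer (the lexicographic minimum of a k-mer and its
#' reverse complement) to the loci whose reference sequence contains it. This
#' is the coarse partitioning structure that routes reads and transcripts to
#' candidate loci before any alignment is attempted.
#'
#' @param seqs Character vector of sequences, or a locus table with a
#'   `ref_seq` column.
#' @param ids Sequence identifiers; defaults to `locus_id` when `seqs` is a
#'   locus table.
#' @param k Odd k-mer size between 11 and 31 (default 21).
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(seqs, ids = NULL, k = 21L) {
  k <- as.integer(k)
  stopifnot(k %% 2L == 1L, k >= 11L, k <= 31L)
  if (is.data.frame(seqs)) {
    if (is.null(ids)) ids <- seqs$locus_id
    seqs <- seqs$ref_seq
  }
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  env <- new.env(hash = TRUE, parent = emptyenv())
  n_short <- 0L
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < k) { n_short <- n_short + 1L; next }
    for (km in unique(canonical_kmers(seqs[i], k))) {
      env[[km]] <- c(env[[km]], i)
    }
  }
  if (n_short > 0L)
    warning(n_short, " sequence(s) shorter than k=", k,
            " indexed as zero k-mers")
  structure(list(map = env, k = k, ids = as.character(ids)),
            class = "kmer_index")
}

canonical_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character())
  km <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  rc <- revcomp(km)
  pmin(km, rc)
}

#' Look up candidate loci for a set of sequences
#'
#' @param index A `kmer_index`.
#' @param seqs Character vector of query sequences.
#' @param min_hits Minimum number of shared canonical k-mers for a locus to
#'   become a candidate (default 2).
#' @return List (one element per query) of character vectors of candidate ids.
#' @export
kmer_candidates <- function(index, seqs, min_hits = 2L) {
  lapply(seqs, function(s) {
    kms <- unique(canonical_kmers(s, index$k))
    hits <- unlist(lapply(kms, function(km) index$map[[km]]), use.names = FALSE)
    if (is.null(hits)) return(character())
    tab <- tabulate(hits, nbins = length(index$ids))
    index$ids[tab >= min_hits]
  })
}

#' Partition reads to candidate TE loci by shared k-mers
#'
#' Assigns each read (or read pair: mates vote jointly, their candidate sets
#' are unioned) to every locus sharing at least `min_hits` canonical k-mers.
#' This plays the role of the initial read-to-TE-reference alignment that
#' groups overlapping reads into per-locus clusters prior to assembly.
#'
#' @param reads Read table (post-QC).
#' @param index A `kmer_index` over TE loci.
#' @param min_hits Minimum shared k-mers (default 2).
#' @return List mapping `read_id` to a character vector of candidate locus
#'   ids (possibly empty). The `unassigned` attribute counts empty entries.
#' @export
partition_reads <- function(reads, index, min_hits = 2L) {
  per_read <- kmer_candidates(index, reads$seq, min_hits)
  ids <- unique(reads$read_id)
  out <- lapply(ids, function(id) {
    sort(unique(unlist(per_read[reads$read_id == id], use.names = FALSE)))
  })
  names(out) <- ids
  attr(out, "unassigned") <- sum(lengths(out) == 0L)
  out
}

#' Optimal local alignment of a query against a target sequence
#'
#' Affine-gap local (Smith-Waterman) alignment with default scoring
#' match +1, mismatch -2, gap open -4, gap extend -1 (a gap of length L costs
#' `gap_open + L * gap_extend`). Identity and query coverage are computed
#' from the traceback: identity counts gap columns in its denominator
#' (BLAST-style column identity), so identity 1 means zero mismatches and
#' zero gaps over the aligned region.
#'
#' @param query,target Non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   given as positive `gap_open`/`gap_extend` magnitudes).
#' @return One-row data frame with `matches`, `mismatches`, `gap_columns`,
#'   `aligned_query_bases`, `identity`, `query_coverage`, `score`, and the
#'   0-based half-open `query_start`/`query_end`/`target_start`/`target_end`
#'   of the aligned region.
#' @examples
#' align_pair("ACGTACGT", "ACGTACGT")$identity  # 1
#' @export
align_pair <- function(query, target, match = 1, mismatch = -2,
                       gap_open = 4, gap_extend = 1) {
  align_local_full(query, target, match, mismatch, gap_open, gap_extend)$stats
}

# full local alignment: flat statistics plus the aligned (gapped) strings
align_local_full <- function(query, target, match = 1, mismatch = -2,
                             gap_open = 4, gap_extend = 1) {
  stopifnot(nzchar(query), nzchar(target))
  al <- .cpp_align_local(query, target, match, mismatch, gap_open, gap_extend)
  qa <- strsplit(al$query_aln, "")[[1]]
  ta <- strsplit(al$target_aln, "")[[1]]
  gap_cols <- sum(qa == "-" | ta == "-")
  matches <- sum(qa == ta & qa != "-" & qa != "N")
  mismatches <- length(qa) - gap_cols - matches
  aligned_q <- sum(qa != "-")
  denom <- matches + mismatches + gap_cols
  stats <- data.frame(
    matches = matches, mismatches = mismatches, gap_columns = gap_cols,
    aligned_query_bases = aligned_q,
    identity = if (denom > 0) matches / denom else 0,
    query_coverage = aligned_q / nchar(query),
    score = al$score,
    query_start = al$query_start, query_end = al$query_end,
    target_start = al$target_start, target_end = al$target_end)
  list(stats = stats, query_aln = qa, target_aln = ta)
}

#' Resolve a partition map to best-aligning loci
#'
#' Reads sharing k-mers with several sibling loci are re-placed by alignment:
#' each read unit (pair) keeps only the candidate locus (or loci, when
#' scores tie because the region is identical between copies) with the
#' highest summed alignment score over its mates. This mirrors the
#' primary-alignment placement that precedes per-locus assembly in
#' genome-guided workflows and keeps reads from diverged sibling copies from
#' contaminating a locus pileup.
#'
#' @param reads Read table.
#' @param partition Partition map from [partition_reads()].
#' @param loci TE locus table with `ref_seq`.
#' @return Partition map of the same shape, with candidate sets reduced to
#'   the best-scoring locus (or tied loci).
#' @export
resolve_partition <- function(reads, partition, loci) {
  out <- lapply(names(partition), function(id) {
    cand <- partition[[id]]
    if (length(cand) <= 1L) return(cand)
    mates <- reads$seq[reads$read_id == id]
    scores <- vapply(cand, function(lid) {
      ref <- loci$ref_seq[loci$locus_id == lid]
      sum(vapply(mates, function(s)
        align_best_orientation(s, ref)$stats$score, 0))
    }, 0)
    cand[scores >= max(scores) - 1e-9]
  })
  names(out) <- names(partition)
  attr(out, "unassigned") <- attr(partition, "unassigned")
  out
}

# align query in both orientations, return the better full alignment plus
# the orientation used ("+" = as given, "-" = reverse complement)
align_best_orientation <- function(query, target, ...) {
  fwd <- align_local_full(query, target, ...)
  rev <- align_local_full(revcomp(query), target, ...)
  if (rev$stats$score > fwd$stats$score) {
    rev$orientation <- "-"
    rev
  } else {
    fwd$orientation <- "+"
    fwd
  }
}
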