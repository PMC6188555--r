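#' Count reads per assigned transcript
#'
#' Each read unit (a pair when mates share a `read_id`, otherwise a single
#' read) increments exactly one transcript: the one with the highest
#' alignment identity (mates contribute an aligned-length-weighted mean).
#' Units whose best identity is tied across transcripts are counted to none
#' and tallied as ambiguous; units with no candidate at all are unassigned.
#'
#' @param reads Read table.
#' @param transcripts Data frame with `transcript_id` and `seq` of uniquely
#'   assigned transcripts.
#' @param index Optional `kmer_index` over the transcripts.
#' @param min_hits Minimum shared k-mers to consider a transcript.
#' @param min_identity Alignments below this identity are ignored
#'   (default 0.8).
#' @return List with `counts` (named integer vector over transcripts),
#'   `ambiguous` and `unassigned` unit tallies.
#' @export
count_reads <- function(reads, transcripts, index = NULL, min_hits = 2L,
                        min_identity = 0.8) {
  counts <- setNames(integer(nrow(transcripts)), transcripts$transcript_id)
  ambiguous <- 0L
  unassigned <- 0L
  if (!nrow(reads)) {
    return(list(counts = counts, ambiguous = 0L, unassigned = 0L))
  }
  if (is.null(index))
    index <- build_kmer_index(transcripts$seq, transcripts$transcript_id)
  cand <- kmer_candidates(index, reads$seq, min_hits)
  units <- split(seq_len(nrow(reads)), reads$read_id)
  for (u in units) {
    tids <- unique(unlist(cand[u], use.names = FALSE))
    if (!length(tids)) { unassigned <- unassigned + 1L; next }
    ident <- vapply(tids, function(tid) {
      tseq <- transcripts$seq[transcripts$transcript_id == tid]
      num <- 0; den <- 0
      for (i in u) {
        a <- align_best_orientation(reads$seq[i], tseq)$stats
        num <- num + a$identity * a$aligned_query_bases
        den <- den + a$aligned_query_bases
      }
      if (den > 0) num / den else 0
    }, 0)
    ident[ident < min_identity] <- 0
    if (max(ident) <= 0) { unassigned <- unassigned + 1L; next }
    top <- which(abs(ident - max(ident)) < 1e-9)
    if (length(top) > 1L) { ambiguous <- ambiguous + 1L; next }
    counts[tids[top]] <- counts[tids[top]] + 1L
  }
  list(counts = counts, ambiguous = ambiguous, unassigned = unassigned)
}

#' Transcripts-per-million normalisation
#'
#' `rate_i = count_i / effective_length_i`; `tpm_i = 1e6 * rate_i / sum(rate)`.
#' Effective length defaults to the transcript length (no fragment-length
#' correction). A sample with all-zero counts returns all-zero TPM, the one
#' documented exception to the sum-to-1e6 invariant.
#'
#' @param counts Non-negative count vector.
#' @param lengths Positive effective lengths, same length as `counts`.
#' @return TPM vector summing to 1e6 (or all zero).
#' @examples
#' tpm(c(10, 10), c(100, 200)) # 666666.7, 333333.3
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0)) stop("effective lengths must be > 0")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) return(rate)
  1e6 * rate / tot
}

#' Build a per-sample expression matrix (counts and TPM)
#'
#' @param sample_reads Named list of read tables, one per sample.
#' @param transcripts Data frame with `transcript_id` and `seq`.
#' @param ... Passed to [count_reads()].
#' @return List with integer matrix `counts` (transcripts x samples), matrix
#'   `tpm`, vector `effective_length`, and per-sample `ambiguous` /
#'   `unassigned` tallies.
#' @export
expression_matrix <- function(sample_reads, transcripts, ...) {
  index <- build_kmer_index(transcripts$seq, transcripts$transcript_id)
  per <- lapply(sample_reads, count_reads, transcripts = transcripts,
                index = index, ...)
  counts <- vapply(per, `[[`, numeric(nrow(transcripts)), "counts")
  counts <- matrix(as.integer(counts), nrow = nrow(transcripts),
                   dimnames = list(transcripts$transcript_id,
                                   names(sample_reads)))
  len <- nchar(transcripts$seq)
  tpm_mat <- apply(counts, 2, tpm, lengths = len)
  dimnames(tpm_mat) <- dimnames(counts)
  list(counts = counts, tpm = tpm_mat,
       effective_length = setNames(len, transcripts$transcript_id),
       ambiguous = vapply(per, `[[`, 0L, "ambiguous"),
       unassigned = vapply(per, `[[`, 0L, "unassigned"))
}
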