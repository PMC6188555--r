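#' Filter reads by mean base quality
#'
#' Drops reads whose mean Phred score falls below `threshold` (strictly less
#' than; a read at exactly the threshold is kept). The mean is taken over raw
#' Phred values, the FastQC-style summary. For paired data the filter acts at
#' pair level: if either mate fails, both are dropped, since downstream
#' partitioning assumes intact pairs. Empty reads are dropped and counted
#' separately.
#'
#' @param reads Read table (see [read_fastq()]).
#' @param threshold Minimum mean Phred quality (default 20).
#' @param paired Apply the pair-level drop rule (default TRUE; ignored for
#'   reads with `mate = NA`).
#' @return List with `kept` (read table), `dropped` (count of reads removed
#'   for low quality, including mates removed by the pair rule) and `empty`
#'   (count of zero-length reads).
#' @export
filter_by_mean_quality <- function(reads, threshold = 20, paired = TRUE) {
  n <- nrow(reads)
  if (n == 0L) return(list(kept = reads, dropped = 0L, empty = 0L))
  quals <- phred_decode(reads$qual)
  is_empty <- lengths(quals) == 0L
  meanq <- vapply(quals, function(q) if (length(q)) mean(q) else NA_real_, 0)
  fails <- !is_empty & meanq < threshold
  if (paired) {
    bad_pair <- unique(reads$read_id[(fails | is_empty) & !is.na(reads$mate)])
    fails <- fails | (!is.na(reads$mate) & reads$read_id %in% bad_pair)
    fails <- fails & !is_empty
  }
  kept <- reads[!fails & !is_empty, , drop = FALSE]
  rownames(kept) <- NULL
  out <- list(kept = kept, dropped = sum(fails), empty = sum(is_empty))
  stopifnot(nrow(out$kept) + out$dropped + out$empty == n)
  out
}
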