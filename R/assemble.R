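#' Assemble reads partitioned to one locus into transcript models
#'
#' Reference-placed pileup assembly: each read is aligned to the locus
#' reference sequence (in both orientations; the better one is kept), per-base
#' depth along the locus is accumulated from aligned read bases, and maximal
#' runs with depth `>= min_depth` become segment fragments whose consensus is
#' the per-column majority vote over read bases (ties resolved to the
#' reference base). Fragments are grouped into one transcript model when at
#' least one read or read pair has aligned bases in both fragments; otherwise
#' each fragment becomes its own model.
#'
#' @param reads Read table of the reads partitioned to this locus.
#' @param locus One-row locus table (needs `locus_id` and `ref_seq`).
#' @param min_depth Minimum read depth for an expressed base (default 2,
#'   which rejects singleton sequencing errors).
#' @param min_identity Reads aligning below this identity are ignored
#'   (default 0.8; guards against stray reads from diverged siblings).
#' @return Data frame of transcript models with columns `transcript_id`,
#'   `locus_id`, `n_fragments`, `support_reads`, `spliced`, `seq`, and a
#'   `fragments` list column of per-fragment tables (`start`, `end`,
#'   `consensus`, `mean_depth`; positions are 0-based half-open in locus
#'   space). Zero covered bases yield a zero-row frame.
#' @export
assemble_locus <- function(reads, locus, min_depth = 2L, min_identity = 0.8) {
  ref <- locus$ref_seq
  L <- nchar(ref)
  empty <- data.frame(transcript_id = character(), locus_id = character(),
                      n_fragments = integer(), support_reads = integer(),
                      spliced = logical(), seq = character(),
                      stringsAsFactors = FALSE)
  empty$fragments <- list()
  if (nrow(reads) == 0L || L == 0L) return(empty)

  ref_bases <- strsplit(ref, "")[[1]]
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(bases, NULL))
  depth <- integer(L)
  placements <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    aln <- align_best_orientation(reads$seq[i], ref)
    if (aln$stats$identity < min_identity || aln$stats$matches == 0L) next
    cols <- alignment_columns(aln)
    if (!nrow(cols)) next
    depth[cols$tpos + 1L] <- depth[cols$tpos + 1L] + 1L
    keep <- cols$base %in% bases
    idx <- cbind(match(cols$base[keep], bases), cols$tpos[keep] + 1L)
    votes[idx] <- votes[idx] + 1L
    placements[[i]] <- range(cols$tpos)
  }

  expressed <- depth >= min_depth
  if (!any(expressed)) return(empty)
  runs <- rle(expressed)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  frag <- data.frame(start = starts[runs$values] - 1L, end = ends[runs$values])
  frag$consensus <- vapply(seq_len(nrow(frag)), function(j) {
    pos <- seq(frag$start[j] + 1L, frag$end[j])
    paste(vapply(pos, function(p) {
      v <- votes[, p]
      top <- which(v == max(v))
      if (max(v) == 0L) return(ref_bases[p])
      winners <- bases[top]
      if (length(winners) > 1L && ref_bases[p] %in% winners) ref_bases[p]
      else winners[1]
    }, ""), collapse = "")
  }, "")
  frag$mean_depth <- vapply(seq_len(nrow(frag)), function(j)
    mean(depth[seq(frag$start[j] + 1L, frag$end[j])]), 0)

  # which fragments does each read (pair) touch?
  frag_of <- function(range) {
    if (is.null(range)) return(integer())
    which(frag$start <= range[2] & frag$end > range[1])
  }
  read_frags <- lapply(placements, frag_of)
  names(read_frags) <- reads$read_id
  pair_frags <- lapply(split(read_frags, reads$read_id),
                       function(x) sort(unique(unlist(x))))

  # union-find over fragments linked by a read or pair
  parent <- seq_len(nrow(frag))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (fs in pair_frags) {
    if (length(fs) > 1L)
      for (j in fs[-1]) parent[find(j)] <- find(fs[1])
  }
  comp <- vapply(seq_len(nrow(frag)), find, 0L)
  comp_ids <- unique(comp)

  models <- lapply(seq_along(comp_ids), function(m) {
    fi <- which(comp == comp_ids[m])
    fdf <- frag[fi, , drop = FALSE]
    fdf <- fdf[order(fdf$start), , drop = FALSE]
    rownames(fdf) <- NULL
    support <- sum(vapply(pair_frags, function(fs) any(fs %in% fi), TRUE))
    seq <- paste(fdf$consensus, collapse = "")
    data.frame(transcript_id = paste0(locus$locus_id, ".m", m),
               locus_id = locus$locus_id, n_fragments = nrow(fdf),
               support_reads = support,
               spliced = classify_splicing(nchar(seq), nrow(fdf), L),
               seq = seq, fragments = I(list(fdf)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, models)
  rownames(out) <- NULL
  out
}

# per-column placement of a full local alignment on the target: for every
# aligned column where both sequences carry a base, records the 0-based
# target position and the query base
alignment_columns <- function(aln) {
  qs <- aln$query_aln
  ts <- aln$target_aln
  tpos <- aln$stats$target_start
  out_t <- integer(length(qs))
  out_b <- character(length(qs))
  n <- 0L
  for (i in seq_along(qs)) {
    if (ts[i] != "-") {
      if (qs[i] != "-") {
        n <- n + 1L
        out_t[n] <- tpos
        out_b[n] <- qs[i]
      }
      tpos <- tpos + 1L
    }
  }
  data.frame(tpos = out_t[seq_len(n)], base = out_b[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Classify a transcript model as spliced or unspliced
#'
#' A model is called spliced when it consists of two or more segment
#' fragments, or when its single fragment is shorter than 90% of the genomic
#' length of the reference locus (evidence that part of the nascent RNA was
#' removed).
#'
#' @param model_length Assembled transcript length in bases.
#' @param n_fragments Number of segment fragments in the model.
#' @param locus_length Genomic length of the reference locus.
#' @param max_unspliced_frac Fraction of the locus length below which a
#'   single-fragment model is called spliced (default 0.90).
#' @return Logical: `TRUE` when spliced.
#' @export
classify_splicing <- function(model_length, n_fragments, locus_length,
                              max_unspliced_frac = 0.90) {
  n_fragments >= 2L || model_length < max_unspliced_frac * locus_length
}
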