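#' Fraction of an interval remapped through genome-alignment chains
#'
#' Follows the single best-scoring chain overlapping the interval (the
#' liftOver convention): the fraction is the share of the interval's bases
#' that fall inside that chain's aligned blocks, and the mapped intervals are
#' the query-side images of those block segments, reported in forward query
#' coordinates.
#'
#' @param interval One-row interval data frame (0-based half-open).
#' @param chains List of chains (see [read_chain()]), target side on the
#'   interval's genome.
#' @return List with `fraction` (0 when no chain overlaps) and `mapped`, a
#'   data frame of query-genome intervals with the matching `src_start` /
#'   `src_end` block on the source genome.
#' @export
liftover_fraction <- function(interval, chains) {
  s <- interval$start
  e <- interval$end
  ov <- Filter(function(ch) ch$t_chrom == interval$chrom &&
                 ch$t_start < e && ch$t_end > s, chains)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), src_start = integer(),
                      src_end = integer(), stringsAsFactors = FALSE)
  if (!length(ov)) return(list(fraction = 0, mapped = empty))
  scores <- vapply(ov, `[[`, 0, "score")
  ids <- vapply(ov, `[[`, "", "chain_id")
  best <- ov[[order(-scores, ids)[1]]]

  covered <- 0L
  mapped <- list()
  tpos <- best$t_start
  qpos <- best$q_start
  b <- best$blocks
  for (i in seq_len(nrow(b))) {
    bs <- max(tpos, s)
    be <- min(tpos + b$size[i], e)
    if (be > bs) {
      covered <- covered + (be - bs)
      q1 <- qpos + (bs - tpos)
      q2 <- q1 + (be - bs)
      if (best$q_strand == "-") {
        qf1 <- best$q_size - q2
        qf2 <- best$q_size - q1
      } else {
        qf1 <- q1
        qf2 <- q2
      }
      mapped[[length(mapped) + 1L]] <-
        data.frame(chrom = best$q_chrom, start = qf1, end = qf2,
                   src_start = bs, src_end = be, stringsAsFactors = FALSE)
    }
    tpos <- tpos + b$size[i] + ifelse(is.na(b$dt[i]), 0L, b$dt[i])
    qpos <- qpos + b$size[i] + ifelse(is.na(b$dq[i]), 0L, b$dq[i])
  }
  list(fraction = covered / (e - s),
       mapped = if (length(mapped)) do.call(rbind, mapped) else empty)
}

#' Fraction of an interval surviving direct plus reciprocal remapping
#'
#' Maps the interval forward through `chains_fwd`, maps each image back
#' through `chains_rev`, and reports the fraction of the original bases
#' recovered.
#'
#' @param interval One-row interval data frame.
#' @param chains_fwd Chains from the interval's genome to the other genome.
#' @param chains_rev Chains in the reverse direction.
#' @return Recovered-base fraction in `[0, 1]`.
#' @export
reciprocal_fraction <- function(interval, chains_fwd, chains_rev) {
  fwd <- liftover_fraction(interval, chains_fwd)
  if (!nrow(fwd$mapped)) return(0)
  recovered <- IRanges::IRanges()
  for (i in seq_len(nrow(fwd$mapped))) {
    img <- fwd$mapped[i, ]
    back <- liftover_fraction(
      data.frame(chrom = img$chrom, start = img$start, end = img$end,
                 strand = ".", stringsAsFactors = FALSE), chains_rev)
    if (!nrow(back$mapped)) next
    keep <- back$mapped$chrom == interval$chrom
    if (!any(keep)) next
    recovered <- c(recovered,
                   IRanges::IRanges(start = back$mapped$start[keep] + 1L,
                                    end = back$mapped$end[keep]))
  }
  if (!length(recovered)) return(0)
  orig <- IRanges::IRanges(start = interval$start + 1L, end = interval$end)
  hit <- IRanges::intersect(IRanges::reduce(recovered), orig)
  sum(IRanges::width(hit)) / (interval$end - interval$start)
}

#' Classify one locus by evolutionary lineage
#'
#' Three independent flags computed from remap fractions:
#' `primate_specific` when the direct fraction to the outgroup genome is
#' below `fail_thresh`; `highly_conserved_primates` when both direct and
#' reciprocal fractions reach `conserve_thresh` for every sister genome; and
#' `human_specific` when the direct fraction is below `fail_thresh` for both
#' sisters. The flags are not a partition: a family can harbour loci that are
#' simultaneously conserved and (by the outgroup criterion) primate-specific.
#'
#' @param locus_id Locus identifier.
#' @param direct Named numeric vector of direct remap fractions per genome.
#' @param reciprocal Named numeric vector of reciprocal fractions (needed for
#'   the sister genomes).
#' @param outgroup,sisters Genome labels (defaults `"outgroup"`,
#'   `c("sister1", "sister2")`, the mouse / chimpanzee / bonobo roles).
#' @param fail_thresh Remap fraction below which a conversion counts as
#'   failed (default 0.10).
#' @param conserve_thresh Fraction required for conservation (default 0.95).
#' @return One-row data frame with the fractions used and the three flags.
#' @export
classify_lineage <- function(locus_id, direct, reciprocal,
                             outgroup = "outgroup",
                             sisters = c("sister1", "sister2"),
                             fail_thresh = 0.10, conserve_thresh = 0.95) {
  need <- c(outgroup, sisters)
  if (!all(need %in% names(direct)))
    stop("missing direct remap fraction for genome(s): ",
         paste(setdiff(need, names(direct)), collapse = ", "))
  if (!all(sisters %in% names(reciprocal)))
    stop("missing reciprocal fraction for sister genome(s): ",
         paste(setdiff(sisters, names(reciprocal)), collapse = ", "))
  hc <- all(pmin(direct[sisters], reciprocal[sisters]) >= conserve_thresh)
  data.frame(locus_id = locus_id,
             outgroup_fraction = unname(direct[outgroup]),
             sister_min_fraction = unname(min(direct[sisters])),
             primate_specific = unname(direct[outgroup] < fail_thresh),
             highly_conserved_primates = hc,
             human_specific = all(direct[sisters] < fail_thresh),
             stringsAsFactors = FALSE)
}

#' Lineage calls for a locus table against simulated or real chain sets
#'
#' @param loci TE locus table.
#' @param chain_sets Named list (per genome label) of lists with elements
#'   `fwd` and `rev`, each a list of chains.
#' @param ... Passed to [classify_lineage()].
#' @return Data frame of lineage calls, one row per locus.
#' @export
lineage_calls <- function(loci, chain_sets, ...) {
  out <- lapply(seq_len(nrow(loci)), function(i) {
    iv <- loci[i, c("chrom", "start", "end", "strand")]
    direct <- vapply(chain_sets, function(cs)
      liftover_fraction(iv, cs$fwd)$fraction, 0)
    recip <- vapply(chain_sets, function(cs)
      reciprocal_fraction(iv, cs$fwd, cs$rev), 0)
    classify_lineage(loci$locus_id[i], direct, recip, ...)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signed human-specific to conserved locus ratio
#'
#' The reporting convention for per-family evolutionary balance: the ratio of
#' human-specific to highly-conserved locus counts when human-specific copies
#' predominate, and the negated inverse otherwise, rounded to one decimal.
#' A zero denominator yields a signed infinity sentinel rather than an error.
#'
#' @param n_conserved,n_human_specific Locus counts.
#' @return Signed ratio rounded to one decimal (or `Inf` / `-Inf`).
#' @examples
#' family_ratio(51, 354)  # 6.9
#' family_ratio(140, 10)  # -14
#' @export
family_ratio <- function(n_conserved, n_human_specific) {
  if (n_human_specific >= n_conserved) {
    if (n_conserved == 0) return(Inf)
    round(n_human_specific / n_conserved, 1)
  } else {
    if (n_human_specific == 0) return(-Inf)
    -round(n_conserved / n_human_specific, 1)
  }
}

#' Per-family evolutionary summary
#'
#' @param calls Lineage call table (see [lineage_calls()]).
#' @param loci TE locus table supplying the `family` of each locus.
#' @return Data frame per family: expressed locus count, conserved and
#'   human-specific counts with their percentages, the signed
#'   human/conserved ratio, and the percentage of loci that are conserved or
#'   human-specific.
#' @export
family_summary <- function(calls, loci) {
  m <- merge(calls, loci[, c("locus_id", "family")], by = "locus_id")
  out <- lapply(split(m, m$family), function(g) {
    nc <- sum(g$highly_conserved_primates)
    nh <- sum(g$human_specific)
    data.frame(family = g$family[1], n_expressed_loci = nrow(g),
               n_conserved = nc, pct_conserved = percent_of(nc, nrow(g)),
               n_human_specific = nh,
               pct_human_specific = percent_of(nh, nrow(g)),
               ratio = family_ratio(nc, nh),
               pct_conserved_or_human_specific =
                 percent_of(nc + nh, nrow(g)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
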