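#' Place TE loci in gene context
#'
#' Emits one record per (TE interval, overlapping gene) pair -- so a TE
#' inside two nested genes yields two records -- with the category decided by
#' the highest-precedence gene feature overlapped by at least `min_bp` bases:
#' `CDS > exon_5utr > exon_3utr > exon_noncoding > intron`. A TE overlapping
#' a gene but none of its exonic features is intronic. TEs overlapping no
#' gene get a single `intergenic` record with `gene_id` NA. Antisense
#' overlaps are kept and flagged via `strand_concordant` rather than
#' excluded.
#'
#' @param tes Interval data frame of TE loci/transcripts; needs an id column
#'   (`transcript_id` or `locus_id`) plus `chrom`, `start`, `end`, `strand`.
#' @param genes Gene feature table (see [read_gtf()]).
#' @param min_bp Minimum overlap in bases (default 1).
#' @return Data frame with `id`, `gene_id`, `biotype`, `category`,
#'   `strand_concordant`.
#' @export
annotate_loci <- function(tes, genes, min_bp = 1L) {
  id_col <- intersect(c("transcript_id", "locus_id"), names(tes))[1]
  if (is.na(id_col)) stop("tes needs a transcript_id or locus_id column")
  gene_rows <- genes[genes$feature == "gene", , drop = FALSE]
  precedence <- c(CDS = "CDS", five_prime_utr = "exon_5utr",
                  three_prime_utr = "exon_3utr", exon = "exon_noncoding")
  recs <- lapply(seq_len(nrow(tes)), function(i) {
    te <- tes[i, ]
    ov <- gene_rows$chrom == te$chrom &
      pmin(gene_rows$end, te$end) - pmax(gene_rows$start, te$start) >= min_bp
    if (!any(ov)) {
      return(data.frame(id = te[[id_col]], gene_id = NA_character_,
                        biotype = NA_character_, category = "intergenic",
                        strand_concordant = NA, stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(which(ov), function(g) {
      gid <- gene_rows$gene_id[g]
      feats <- genes[genes$gene_id == gid & genes$feature != "gene" &
                       genes$chrom == te$chrom, , drop = FALSE]
      cat <- "intron"
      for (f in names(precedence)) {
        fi <- feats[feats$feature == f, , drop = FALSE]
        if (nrow(fi) &&
            any(pmin(fi$end, te$end) - pmax(fi$start, te$start) >= min_bp)) {
          cat <- precedence[[f]]
          break
        }
      }
      data.frame(id = te[[id_col]], gene_id = gid,
                 biotype = gene_rows$biotype[g], category = cat,
                 strand_concordant = if (te$strand %in% c("+", "-"))
                   te$strand == gene_rows$strand[g] else NA,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, recs)
  names(out)[names(out) == "id"] <- id_col
  rownames(out) <- NULL
  out
}
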