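#' Read a BED file of intervals
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Columns beyond the first six are ignored; 3-column BED gets name `.`,
#' score 0 and strand `.`.
#'
#' @param path BED file (3 to 6+ columns).
#' @return Interval data frame with extra `name` and `score` columns.
#' @export
read_bed <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#", quote = "")
  if (ncol(raw) < 3L) stop("BED parse error: fewer than 3 columns in ", path)
  df <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]),
                   name = if (ncol(raw) >= 4L) as.character(raw[[4]]) else ".",
                   score = if (ncol(raw) >= 5L) raw[[5]] else 0,
                   strand = if (ncol(raw) >= 6L) as.character(raw[[6]]) else ".",
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Write intervals as BED6
#'
#' @param df Interval data frame; optional `name` and `score` columns are
#'   used when present.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$chrom, df$start, df$end,
                    if (!is.null(df$name)) df$name else ".",
                    if (!is.null(df$score)) df$score else 0,
                    if (!is.null(df$strand)) df$strand else ".")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Returns a flat feature table rather than nested gene objects: one row per
#' `gene`, `exon`, `CDS`, `five_prime_utr` or `three_prime_utr` line, with
#' GTF's 1-based inclusive coordinates shifted to 0-based half-open. Biotype
#' is taken from the `gene_biotype` (or `gene_type`) attribute and collapsed
#' to `protein_coding`, `lncRNA`, `small_ncRNA`, `pseudogene` or `misc`.
#'
#' @param path GTF file.
#' @return Data frame with columns `gene_id`, `biotype`, `feature`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fld <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fld) != 9L)
  if (length(bad))
    stop("GTF parse error at line ", bad[1], ": expected 9 tab-separated ",
         "fields, got ", lengths(fld)[bad[1]])
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  attrs <- vapply(fld, `[`, "", 9)
  biotype <- get_attr(attrs, "gene_biotype")
  alt <- get_attr(attrs, "gene_type")
  biotype[is.na(biotype)] <- alt[is.na(biotype)]
  df <- data.frame(
    gene_id = get_attr(attrs, "gene_id"),
    biotype = normalize_biotype(biotype),
    feature = vapply(fld, `[`, "", 3),
    chrom = vapply(fld, `[`, "", 1),
    start = as.integer(vapply(fld, `[`, "", 4)) - 1L,
    end = as.integer(vapply(fld, `[`, "", 5)),
    strand = vapply(fld, `[`, "", 7),
    stringsAsFactors = FALSE)
  keep <- df$feature %in% c("gene", "exon", "CDS",
                            "five_prime_utr", "three_prime_utr")
  df <- df[keep, , drop = FALSE]
  validate_intervals(df)
  rownames(df) <- NULL
  df
}

normalize_biotype <- function(x) {
  out <- rep("misc", length(x))
  out[x %in% "protein_coding"] <- "protein_coding"
  out[x %in% c("lncRNA", "lincRNA", "antisense")] <- "lncRNA"
  out[x %in% c("miRNA", "snoRNA", "snRNA", "rRNA", "small_ncRNA")] <- "small_ncRNA"
  out[grepl("pseudogene", x)] <- "pseudogene"
  out[is.na(x)] <- "misc"
  out
}

#' Write a gene feature table as GTF
#'
#' @param features Feature table (see [read_gtf()]).
#' @param path Output file.
#' @export
write_gtf <- function(features, path) {
  rows <- sprintf(
    '%s\ttelocus\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    features$chrom, features$feature, features$start + 1L, features$end,
    features$strand, features$gene_id, features$biotype)
  writeLines(rows, path)
  invisible(path)
}
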