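#' Read a RepeatMasker .out annotation into a TE locus table
#'
#' Parses the classic RepeatMasker `.out` dialect: three header lines followed
#' by whitespace-delimited rows with 1-based inclusive genomic coordinates and
#' strand `C` for the minus strand. Coordinates are converted to the package's
#' 0-based half-open convention. When a genome is supplied, the per-locus
#' reference sequence is extracted at parse time (reverse-complemented for
#' minus-strand loci), because downstream assignment aligns transcripts
#' against per-locus sequences rather than family consensi.
#'
#' @param path RepeatMasker `.out` file.
#' @param genome Optional named character vector of chromosome sequences used
#'   to fill the `ref_seq` column.
#' @return Data frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `te_class`, `family`, and (if `genome` given) `ref_seq`.
#' @export
read_repeatmasker_out <- function(path, genome = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("RepeatMasker parse error: expected 3 header lines in ", path)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 11L)
      stop("RepeatMasker parse error at line ", i + 3L, ": expected >= 11 ",
           "columns, got ", length(f))
    begin <- suppressWarnings(as.integer(f[6]))
    end <- suppressWarnings(as.integer(f[7]))
    if (is.na(begin) || is.na(end) || begin < 1L || end < begin)
      stop("RepeatMasker parse error at line ", i + 3L,
           ": bad coordinates '", f[6], "'..'", f[7], "'")
    strand <- f[9]
    if (!strand %in% c("+", "C"))
      stop("RepeatMasker parse error at line ", i + 3L,
           ": strand must be '+' or 'C', got '", strand, "'")
    list(chrom = f[5], start = begin - 1L, end = end,
         strand = if (strand == "C") "-" else "+",
         family = f[10], class_family = f[11],
         id = if (length(f) >= 15L) f[15] else NA_character_)
  })
  df <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    family = vapply(rows, `[[`, "", "family"),
    te_class = te_class_of(vapply(rows, `[[`, "", "class_family")),
    stringsAsFactors = FALSE)
  ids <- vapply(rows, `[[`, "", "id")
  df$locus_id <- ifelse(is.na(ids) | !nzchar(ids),
                        paste0(df$family, ".", df$chrom, ".", df$start),
                        paste0(df$family, ".", ids))
  df <- df[, c("locus_id", "chrom", "start", "end", "strand",
               "te_class", "family")]
  validate_intervals(df)
  if (!is.null(genome)) df$ref_seq <- extract_locus_seq(df, genome)
  df
}

# maps a RepeatMasker class/family string (e.g. "LINE/L1") to the major class
te_class_of <- function(class_family) {
  cls <- sub("/.*$", "", class_family)
  ifelse(cls %in% c("LTR", "LINE", "SINE", "DNA"), cls, "Other")
}

# locus sequences in TE orientation: reverse-complemented for "-" loci
extract_locus_seq <- function(loci, genome) {
  missing <- setdiff(unique(loci$chrom), names(genome))
  if (length(missing))
    stop("genome lacks chromosome(s): ", paste(missing, collapse = ", "))
  s <- substring(genome[loci$chrom], loci$start + 1L, loci$end)
  neg <- loci$strand == "-"
  s[neg] <- revcomp(s[neg])
  unname(s)
}

#' Write a TE locus table in RepeatMasker .out dialect
#'
#' Emits three header lines and one row per locus with 1-based inclusive
#' coordinates and strand `C` for minus-strand loci, so that
#' [read_repeatmasker_out()] round-trips the table.
#'
#' @param loci TE locus table (see [read_repeatmasker_out()]).
#' @param path Output file.
#' @export
write_repeatmasker_out <- function(loci, path) {
  hdr <- c(
    paste("  SW  perc perc perc  query     position in query    matching",
          "      repeat         position in repeat"),
    paste("score  div. del. ins.  sequence  begin end   (left)  repeat",
          "        class/family   begin end    (left)  ID"),
    "")
  cf <- ifelse(loci$te_class == "Other", paste0("Other/", loci$family),
               paste0(loci$te_class, "/", loci$family))
  # preserve a numeric suffix of locus_id in the ID column so that
  # write-then-read reproduces locus ids of the form "<family>.<n>"
  suffix <- sub("^.*\\.", "", loci$locus_id)
  id <- ifelse(grepl("^[0-9]+$", suffix), suffix,
               as.character(seq_len(nrow(loci))))
  rows <- sprintf("%5d %5.1f %4.1f %4.1f  %s %d %d (%d) %s %s %s %d %d (%d) %s",
                  1000L, 0, 0, 0, loci$chrom, loci$start + 1L, loci$end, 0L,
                  ifelse(loci$strand == "-", "C", "+"),
                  loci$family, cf, 1L, loci$end - loci$start, 0L, id)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
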