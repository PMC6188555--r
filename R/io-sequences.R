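#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' Parses Phred+33 FASTQ into a data frame with columns `read_id`, `mate`
#' (1, 2 or `NA`, taken from a trailing `/1` or `/2` in the id), `seq` and
#' `qual` (the raw quality string). Records whose sequence and quality lengths
#' differ are rejected with an error naming the record; malformed files are
#' never silently repaired.
#'
#' @param path FASTQ file (Phred+33).
#' @return Data frame of reads.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error in ", path, ": line count ", length(lines),
         " is not a multiple of 4")
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("FASTQ parse error at record ", bad[1], " (line ",
         idx[bad[1]], "): missing '@' or '+' marker")
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("FASTQ parse error at record ", bad[1], ": sequence length ",
         nchar(seqs[bad[1]]), " != quality length ", nchar(qual[bad[1]]))
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  mate <- rep(NA_integer_, length(ids))
  mate[grepl("/1$", ids)] <- 1L
  mate[grepl("/2$", ids)] <- 2L
  ids <- sub("/[12]$", "", ids)
  data.frame(read_id = ids, mate = mate, seq = toupper(seqs), qual = qual,
             stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#'
#' @param reads Data frame as returned by [read_fastq()].
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  ids <- reads$read_id
  has_mate <- !is.na(reads$mate)
  ids[has_mate] <- paste0(ids[has_mate], "/", reads$mate[has_mate])
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", ids)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual Character vector of quality strings.
#' @return List of integer vectors (one per read).
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) if (nchar(q) == 0L) integer() else utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores to a Phred+33 string
#'
#' @param scores Integer vector of Phred scores (0--93).
#' @return Single quality string.
#' @export
phred_encode <- function(scores) {
  if (!length(scores)) return("")
  stopifnot(all(scores >= 0L), all(scores <= 93L))
  intToUtf8(as.integer(scores) + 33L)
}

#' Write a data frame as a header-row TSV
#'
#' @param df Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a header-row TSV written by [write_tsv()]
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "", quote = "")
}
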