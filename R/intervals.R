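#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand`, using 0-based half-open coordinates throughout the package.
#'
#' @param chrom Character vector of chromosome names (non-empty).
#' @param start,end Integer vectors, 0-based half-open; `0 <= start < end`.
#' @param strand Character vector in `+`, `-`, `.` (recycled).
#' @return A data frame with one row per interval.
#' @examples
#' genomic_intervals("chr1", 10, 20, "+")
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    stop("interval chrom must be non-empty")
  if (anyNA(df$start) || anyNA(df$end))
    stop("interval coordinates must not be NA")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("intervals require 0 <= start < end (0-based half-open)")
  bad <- !df$strand %in% c("+", "-", ".")
  if (any(bad)) stop("unknown strand code: ", df$strand[which(bad)[1]])
  invisible(df)
}

# IRanges view of a 0-based half-open interval table (1-based closed inside).
as_iranges0 <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

#' Count intervals overlapping a feature set
#'
#' Counts how many of `loci` overlap at least one interval in `features` by at
#' least `min_bp` bases, each locus counted once. Used to build the observed
#' margin of enrichment tests.
#'
#' @param loci,features Interval data frames (see [genomic_intervals()]).
#' @param min_bp Minimum overlap in bases (default 1).
#' @return Integer count of overlapping loci.
#' @export
overlap_count <- function(loci, features, min_bp = 1L) {
  sum(overlaps_feature(loci, features, min_bp))
}

#' Flag intervals overlapping a feature set
#'
#' @inheritParams overlap_count
#' @return Logical vector along `loci` rows.
#' @export
overlaps_feature <- function(loci, features, min_bp = 1L) {
  hit <- logical(nrow(loci))
  if (nrow(loci) == 0L || nrow(features) == 0L) return(hit)
  for (chr in unique(loci$chrom)) {
    li <- which(loci$chrom == chr)
    fi <- which(features$chrom == chr)
    if (!length(fi)) next
    ov <- IRanges::countOverlaps(as_iranges0(loci[li, , drop = FALSE]),
                                 as_iranges0(features[fi, , drop = FALSE]),
                                 minoverlap = as.integer(min_bp))
    hit[li] <- ov > 0L
  }
  hit
}

#' Percentage helper used in retention and summary tables
#'
#' @param x Numerator count(s).
#' @param n Denominator count.
#' @param digits Decimal places (default 1, the reporting convention used in
#'   the package's summary tables).
#' @return `100 * x / n` rounded to `digits`.
#' @examples
#' percent_of(654665, 1766735) # 37.1
#' @export
percent_of <- function(x, n, digits = 1) round(100 * x / n, digits)

# reverse complement for plain character vectors (ACGTN)
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}
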