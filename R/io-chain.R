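#' Read a UCSC chain file
#'
#' Parses genome-alignment chains. Each chain is validated against the format
#' invariants: the block sizes plus target gaps (`dt`) must sum to the target
#' span and plus query gaps (`dq`) to the query span, and the last block line
#' carries a size only. Violations are errors, never warnings.
#'
#' @param path Chain file.
#' @return List of chain objects. Each chain is a list with `chain_id`,
#'   `score`, `t_chrom`, `t_size`, `t_strand`, `t_start`, `t_end` (and the
#'   `q_*` equivalents) plus a `blocks` data frame with columns `size`, `dt`,
#'   `dq` (`NA` on the final block). Coordinates are 0-based half-open in
#'   strand-local space, as in the format itself.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  starts <- grep("^chain\\b", lines)
  if (!length(starts)) stop("chain parse error: no 'chain' header in ", path)
  chains <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    if (length(hdr) != 13L)
      stop("chain parse error at line ", starts[i],
           ": header must have 13 fields, got ", length(hdr))
    body <- lines[seq(starts[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    fld <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    nf <- lengths(fld)
    if (!length(fld) || nf[length(fld)] != 1L || any(nf[-length(fld)] != 3L))
      stop("chain parse error in chain at line ", starts[i],
           ": expected 'size dt dq' rows ending in a bare size")
    blocks <- data.frame(
      size = vapply(fld, `[`, 0, 1),
      dt = c(vapply(fld[-length(fld)], `[`, 0, 2), NA_real_),
      dq = c(vapply(fld[-length(fld)], `[`, 0, 3), NA_real_))
    ch <- list(score = as.numeric(hdr[2]),
               t_chrom = hdr[3], t_size = as.integer(hdr[4]),
               t_strand = hdr[5], t_start = as.integer(hdr[6]),
               t_end = as.integer(hdr[7]),
               q_chrom = hdr[8], q_size = as.integer(hdr[9]),
               q_strand = hdr[10], q_start = as.integer(hdr[11]),
               q_end = as.integer(hdr[12]),
               chain_id = hdr[13], blocks = blocks)
    validate_chain(ch, line = starts[i])
    chains[[i]] <- ch
  }
  chains
}

validate_chain <- function(ch, line = NA) {
  where <- if (is.na(line)) paste0(" '", ch$chain_id, "'")
           else paste0(" at line ", line)
  b <- ch$blocks
  t_span <- sum(b$size) + sum(b$dt, na.rm = TRUE)
  q_span <- sum(b$size) + sum(b$dq, na.rm = TRUE)
  if (t_span != ch$t_end - ch$t_start)
    stop("chain format error", where, ": blocks cover ", t_span,
         " target bases but header span is ", ch$t_end - ch$t_start)
  if (q_span != ch$q_end - ch$q_start)
    stop("chain format error", where, ": blocks cover ", q_span,
         " query bases but header span is ", ch$q_end - ch$q_start)
  if (ch$t_strand != "+")
    stop("chain format error", where, ": target strand must be '+'")
  if (!ch$q_strand %in% c("+", "-"))
    stop("chain format error", where, ": bad query strand")
  invisible(ch)
}

#' Write chains to a UCSC chain file
#'
#' @param chains List of chain objects (see [read_chain()]).
#' @param path Output file.
#' @export
write_chain <- function(chains, path) {
  out <- unlist(lapply(chains, function(ch) {
    validate_chain(ch)
    hdr <- paste("chain", format(ch$score, scientific = FALSE), ch$t_chrom,
                 ch$t_size, ch$t_strand, ch$t_start, ch$t_end, ch$q_chrom,
                 ch$q_size, ch$q_strand, ch$q_start, ch$q_end, ch$chain_id)
    b <- ch$blocks
    n <- nrow(b)
    body <- if (n > 1L)
      c(paste(b$size[-n], b$dt[-n], b$dq[-n]), as.character(b$size[n]))
    else as.character(b$size[n])
    c(hdr, body, "")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Construct a validated chain object
#'
#' @param chain_id,score Chain identifier and alignment score.
#' @param t_chrom,t_size,t_start,t_end Target side (strand always `+`).
#' @param q_chrom,q_size,q_start,q_end,q_strand Query side; coordinates are
#'   strand-local as in the chain format.
#' @param blocks Data frame with `size`, `dt`, `dq` (`NA` on the last row).
#' @return A chain object (see [read_chain()]); invalid block sums error.
#' @export
make_chain <- function(chain_id, score, t_chrom, t_size, t_start, t_end,
                       q_chrom, q_size, q_start, q_end, blocks,
                       q_strand = "+") {
  ch <- list(score = score, t_chrom = t_chrom, t_size = as.integer(t_size),
             t_strand = "+", t_start = as.integer(t_start),
             t_end = as.integer(t_end), q_chrom = q_chrom,
             q_size = as.integer(q_size), q_strand = q_strand,
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             chain_id = as.character(chain_id), blocks = blocks)
  validate_chain(ch)
  ch
}
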