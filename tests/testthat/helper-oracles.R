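# Independent oracles the implementation is checked against. These are
# deliberately naive (full matrices, per-base loops, exhaustive sums) and
# share no code with the package internals.

# Full-matrix affine-gap local alignment score (Gotoh, pure R).
# A gap of length L costs gap_open + L * gap_extend.
oracle_local_score <- function(q, t, match = 1, mismatch = -2,
                               gap_open = 4, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc)
  n <- length(tc)
  NEG <- -Inf
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      s <- if (qc[i - 1] == tc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Per-base chain mapping: walks every base of the target genome through the
# chain blocks and returns, for each base of the interval, its query-genome
# forward coordinate or NA.
oracle_map_bases <- function(interval, chain) {
  pos <- seq(interval$start, interval$end - 1L)
  out <- rep(NA_integer_, length(pos))
  if (chain$t_chrom != interval$chrom) return(out)
  tpos <- chain$t_start
  qpos <- chain$q_start
  b <- chain$blocks
  for (k in seq_len(nrow(b))) {
    for (off in seq_len(b$size[k]) - 1L) {
      tb <- tpos + off
      qb <- qpos + off
      hit <- which(pos == tb)
      if (length(hit)) {
        out[hit] <- if (chain$q_strand == "-") chain$q_size - 1L - qb else qb
      }
    }
    tpos <- tpos + b$size[k] + ifelse(is.na(b$dt[k]), 0L, b$dt[k])
    qpos <- qpos + b$size[k] + ifelse(is.na(b$dq[k]), 0L, b$dq[k])
  }
  out
}

# best-scoring overlapping chain, as the liftover contract defines it
oracle_liftover_fraction <- function(interval, chains) {
  ov <- Filter(function(ch) ch$t_chrom == interval$chrom &&
                 ch$t_start < interval$end && ch$t_end > interval$start,
               chains)
  if (!length(ov)) return(0)
  scores <- vapply(ov, `[[`, 0, "score")
  ids <- vapply(ov, `[[`, "", "chain_id")
  best <- ov[[order(-scores, ids)[1]]]
  mapped <- oracle_map_bases(interval, best)
  mean(!is.na(mapped))
}

# exhaustive upper-tail hypergeometric via binomial coefficients
oracle_hyper_upper <- function(N, K, n, x) {
  xs <- x:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# exhaustive two-sided Fisher p: sum point probabilities <= observed
oracle_fisher_two <- function(a, b, c, d) {
  rs <- a + b
  cs <- a + c
  N <- a + b + c + d
  lo <- max(0, cs - (N - rs))
  hi <- min(rs, cs)
  probs <- vapply(lo:hi, function(x)
    choose(rs, x) * choose(N - rs, cs - x) / choose(N, cs), 0)
  obs <- choose(rs, a) * choose(N - rs, cs - a) / choose(N, cs)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# random valid chain on chrT/chrQ for liftover property tests
make_chain_test <- function(sizes, dt, dq, q_strand = "+") {
  t_span <- sum(sizes) + sum(dt, na.rm = TRUE)
  q_span <- sum(sizes) + sum(dq, na.rm = TRUE)
  t_start <- sample(0:50, 1)
  q_start <- sample(0:50, 1)
  make_chain("1", 1000, "chrT", t_start + t_span + 50L, t_start,
             t_start + t_span, "chrQ", q_start + q_span + 50L, q_start,
             q_start + q_span, data.frame(size = sizes, dt = dt, dq = dq),
             q_strand = q_strand)
}

# simple reverse complement, independent of the package's own helper
revcomp_test <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# tiled error-free reads covering [0, L); each start is emitted twice so
# every base reaches depth >= 2 even at the interval edges
tiled_reads <- function(seq, read_len = 60L, step = 20L, prefix = "r") {
  L <- nchar(seq)
  starts <- unique(c(seq(0L, max(0L, L - read_len), by = step),
                     L - read_len))
  starts <- rep(starts[starts >= 0L], each = 2L)
  data.frame(read_id = paste0(prefix, seq_along(starts)),
             mate = NA_integer_,
             seq = substring(seq, starts + 1L, starts + read_len),
             qual = strrep("I", read_len), stringsAsFactors = FALSE)
}
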