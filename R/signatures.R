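#' Counts-per-million normalisation
#'
#' @param counts Transcript x sample count matrix.
#' @return CPM matrix; all-zero samples stay zero.
#' @export
cpm <- function(counts) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  t(t(counts) / lib) * 1e6
}

#' Detection prefilter for differential-expression testing
#'
#' Two sequential filters: keep transcripts with CPM at or above `cpm_thresh`
#' in at least `min_samples` samples (both boundaries inclusive), then keep
#' transcripts detected (count > 0) in at least `detect_frac` of all samples.
#'
#' @param counts Transcript x sample count matrix.
#' @param cpm_thresh CPM threshold (default 1).
#' @param min_samples Minimum samples at or above `cpm_thresh` (default 2).
#' @param detect_frac Minimum detected fraction of samples (default 0.5).
#' @return Character vector of retained transcript ids (rownames).
#' @export
prefilter <- function(counts, cpm_thresh = 1, min_samples = 2L,
                      detect_frac = 0.5) {
  cm <- cpm(counts)
  keep1 <- rowSums(cm >= cpm_thresh) >= min_samples
  keep2 <- rowMeans(counts > 0) >= detect_frac
  rownames(counts)[keep1 & keep2]
}

#' Case/control differential-expression test
#'
#' Transparent stand-ins for a full count-model analysis, acting on CPM:
#' `log2fc = log2((mean case CPM + pseudocount) / (mean control CPM +
#' pseudocount))` for every method. P-values come from a seeded label
#' permutation test of the CPM mean difference (`method = "permutation"`,
#' default, with `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`), from Welch's
#' t-test on `log2(CPM + pseudocount)` (`"welch_logcpm"`), or from a
#' precomputed `external` table with columns `transcript_id`, `p`, `log2fc`
#' (the route for results of a dedicated count-model package).
#'
#' @param counts Transcript x sample count matrix (rownames required).
#' @param groups Vector along columns with values `"case"` / `"control"`;
#'   each group needs at least 2 samples.
#' @param method `"permutation"`, `"welch_logcpm"` or `"external"`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed for the permutation draw (default 1).
#' @param pseudocount Added to mean CPM before the log ratio (default 0.5).
#' @param external Precomputed results table for `method = "external"`.
#' @return Data frame with `transcript_id`, `log2fc`, `p`,
#'   `detected_fraction_cases`, `detected_fraction_controls`.
#' @export
de_test <- function(counts, groups,
                    method = c("permutation", "welch_logcpm", "external"),
                    n_perm = 10000L, seed = 1L, pseudocount = 0.5,
                    external = NULL) {
  method <- match.arg(method)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts),
            all(groups %in% c("case", "control")))
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L)
    stop("each group needs at least 2 samples")
  is_case <- groups == "case"
  cm <- cpm(counts)
  mean_case <- rowMeans(cm[, is_case, drop = FALSE])
  mean_ctrl <- rowMeans(cm[, !is_case, drop = FALSE])
  log2fc <- log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))
  det_case <- rowMeans(counts[, is_case, drop = FALSE] > 0)
  det_ctrl <- rowMeans(counts[, !is_case, drop = FALSE] > 0)

  if (method == "external") {
    stopifnot(!is.null(external),
              all(c("transcript_id", "p", "log2fc") %in% names(external)))
    idx <- match(rownames(counts), external$transcript_id)
    p <- external$p[idx]
    log2fc <- external$log2fc[idx]
  } else if (method == "welch_logcpm") {
    lg <- log2(cm + pseudocount)
    p <- apply(lg, 1, function(v) {
      if (stats::sd(v[is_case]) == 0 && stats::sd(v[!is_case]) == 0) {
        if (mean(v[is_case]) == mean(v[!is_case])) 1 else 0
      } else stats::t.test(v[is_case], v[!is_case])$p.value
    })
  } else {
    obs <- mean_case - mean_ctrl
    n <- ncol(cm)
    k <- sum(is_case)
    withr_seed <- function(expr) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      expr
    }
    perm <- withr_seed(replicate(n_perm, sample.int(n, k)))
    # indicator matrix (samples x permutations) for vectorised null stats
    ind <- matrix(0, nrow = n, ncol = n_perm)
    ind[cbind(as.vector(perm), rep(seq_len(n_perm), each = k))] <- 1
    null_case <- (cm %*% ind) / k
    null_ctrl <- (cm %*% (1 - ind)) / (n - k)
    null_diff <- null_case - null_ctrl
    exceed <- rowSums(abs(null_diff) >= abs(obs) - 1e-12)
    p <- (1 + exceed) / (n_perm + 1)
  }
  data.frame(transcript_id = rownames(counts), log2fc = log2fc, p = p,
             detected_fraction_cases = det_case,
             detected_fraction_controls = det_ctrl,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratify differential-expression results into signatures
#'
#' A transcript is `up` when `p < p_thresh`, `log2fc > lfc_thresh` and it is
#' detected in at least `detect_thresh` of cases; `down` symmetrically with
#' `log2fc < -lfc_thresh` and detection in controls; otherwise `none`.
#'
#' @param results Data frame from [de_test()].
#' @param p_thresh Nominal p-value threshold (default 0.05).
#' @param lfc_thresh Absolute log2 fold-change threshold (default 1, i.e. a
#'   2-fold change; configurable because reporting conventions vary).
#' @param detect_thresh Detection fraction gate (default 0.5).
#' @return `results` with an added `signature` column (`up`/`down`/`none`).
#' @export
stratify <- function(results, p_thresh = 0.05, lfc_thresh = 1,
                     detect_thresh = 0.5) {
  up <- results$p < p_thresh & results$log2fc > lfc_thresh &
    results$detected_fraction_cases >= detect_thresh
  down <- results$p < p_thresh & results$log2fc < -lfc_thresh &
    results$detected_fraction_controls >= detect_thresh
  results$signature <- ifelse(up, "up", ifelse(down, "down", "none"))
  results
}
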