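#' TPM normalisation
#'
#' Transcripts-per-million: each count is divided by the gene's effective
#' length in kb, and the resulting rates are rescaled so every sample column
#' sums to one million. An all-zero sample yields an all-zero column with a
#' warning.
#'
#' @param dex a [DoseExperiment-class] (counts + effective lengths).
#' @return numeric matrix of TPM values, same dimnames as the counts; every
#'   non-degenerate column sums to 1e6 (relative tolerance 1e-9).
#' @examples
#' dsn <- pipelineDesign(n_rep = 2)
#' cnt <- matrix(c(10L, 20L), 2, 8, dimnames = list(c("a", "b"), dsn$sample_id))
#' dex <- DoseExperiment(cnt, lengths = c(a = 1000, b = 2000), design = dsn)
#' computeTpm(dex)[, 1]
#' @export
computeTpm <- function(dex) {
  stopifnot(is(dex, "DoseExperiment"))
  cnt <- doseCounts(dex)
  len_kb <- effectiveLengths(dex) / 1000
  if (anyNA(len_kb)) {
    stopf("missing effective length for gene(s): %s",
          paste(rownames(cnt)[is.na(len_kb)], collapse = ", "))
  }
  rate <- cnt / len_kb
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warnf("sample(s) with zero total counts: %s (TPM set to 0)",
          paste(colnames(cnt)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  txInfo("TPM: %d genes x %d samples", nrow(tpm), ncol(tpm))
  tpm
}

#' Low-expression filter
#'
#' Deterministic re-expression of the usual count-based prefilter: a gene is
#' retained iff its CPM reaches the CPM equivalent of 10 reads in the median
#' library (`10 / median(lib) * 1e6`) in at least `k` samples, where `k` is
#' the size of the smallest design group, AND its total count across samples
#' is at least 15.
#'
#' @param dex a [DoseExperiment-class].
#' @return character vector of retained gene ids, in input order.
#' @export
filterLowExpressed <- function(dex) {
  stopifnot(is(dex, "DoseExperiment"))
  design <- doseDesign(dex)
  checkDesign(design)
  cnt <- doseCounts(dex)
  lib <- colSums(cnt)
  if (all(lib == 0)) stopf("all libraries are empty")
  cpm <- sweep(cnt, 2, pmax(lib, 1), "/") * 1e6
  cpm_cut <- 10 / stats::median(lib) * 1e6
  k <- min(table(factor(design$group, levels = unique(design$group))))
  keep <- rowSums(cpm >= cpm_cut) >= k & rowSums(cnt) >= 15
  txInfo("low-expression filter: kept %d / %d genes (CPM cut %.3g in >= %d samples, total >= 15)",
         sum(keep), nrow(cnt), cpm_cut, k)
  rownames(cnt)[keep]
}

#' Two-group differential expression
#'
#' Tests each gene between two treatment groups. The default method is a
#' Welch t-test on `log2(CPM + 0.5)`; the alternative `"exact"` method is an
#' exact conditional binomial test on pooled, library-size-normalised counts.
#' P-values are Benjamini-Hochberg adjusted across the tested genes and a
#' gene is flagged differentially expressed iff its FDR falls below
#' `fdr_deg`.
#'
#' @param dex a [DoseExperiment-class]; restrict rows beforehand to apply a
#'   prefilter (see [filterLowExpressed()]).
#' @param groupA,groupB group labels (each with >= 2 replicates); the fold
#'   change is reported as B over A.
#' @param method `"welch"` (default) or `"exact"`.
#' @param fdr_deg FDR threshold (default 0.1).
#' @return `DataFrame` with columns `gene_id`, `log2fc`, `p`, `fdr`,
#'   `is_deg`.
#' @export
differentialExpression <- function(dex, groupA = "L0", groupB = "N0",
                                   method = c("welch", "exact"),
                                   fdr_deg = 0.1) {
  stopifnot(is(dex, "DoseExperiment"))
  method <- match.arg(method)
  grp <- as.character(sampleGroups(dex))
  ia <- which(grp == groupA)
  ib <- which(grp == groupB)
  if (length(ia) < 2 || length(ib) < 2) {
    stopf("both groups need >= 2 replicates (%s: %d, %s: %d)",
          groupA, length(ia), groupB, length(ib))
  }
  cnt <- doseCounts(dex)
  lib <- pmax(colSums(cnt), 1)
  logcpm <- log2(sweep(cnt, 2, lib, "/") * 1e6 + 0.5)
  l2fc <- rowMeans(logcpm[, ib, drop = FALSE]) - rowMeans(logcpm[, ia, drop = FALSE])
  if (method == "welch") {
    p <- welchRows(logcpm[, ia, drop = FALSE], logcpm[, ib, drop = FALSE])
  } else {
    sa <- rowSums(cnt[, ia, drop = FALSE])
    sb <- rowSums(cnt[, ib, drop = FALSE])
    pb <- sum(lib[ib]) / (sum(lib[ia]) + sum(lib[ib]))
    p <- vapply(seq_along(sa), function(i) {
      tot <- sa[i] + sb[i]
      if (tot == 0) return(1)
      binom.test(sb[i], tot, p = pb)$p.value
    }, numeric(1))
  }
  fdr <- p.adjust(p, method = "BH")
  res <- S4Vectors::DataFrame(
    gene_id = rownames(cnt), log2fc = unname(l2fc), p = unname(p),
    fdr = unname(fdr), is_deg = unname(fdr < fdr_deg)
  )
  txInfo("differential expression %s vs %s (%s): %d / %d genes at FDR < %g",
         groupB, groupA, method, sum(res$is_deg), nrow(res), fdr_deg)
  res
}

## Row-wise Welch t-test (two-sided) on a pair of sample blocks.
welchRows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # identical, constant groups carry no evidence
  p
}

#' Per-group base means
#'
#' Arithmetic mean of each gene's TPM over the biological replicates of each
#' treatment group ("base mean"), columns ordered L0, L4, L8, N0.
#'
#' @param tpm TPM matrix from [computeTpm()] (or any genes x samples matrix).
#' @param design sample design matching the TPM columns.
#' @return genes x 4 numeric matrix with columns `L0`, `L4`, `L8`, `N0`.
#' @export
groupBaseMeans <- function(tpm, design) {
  checkDesign(design)
  design <- design[match(colnames(tpm), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stopf("TPM columns missing from design")
  grp <- factor(as.character(design$group), levels = GROUP_LEVELS)
  out <- vapply(GROUP_LEVELS, function(g) {
    idx <- which(grp == g)
    if (length(idx) == 0) return(rep(NA_real_, nrow(tpm)))
    rowMeans(tpm[, idx, drop = FALSE])
  }, numeric(nrow(tpm)))
  matrix(out, nrow = nrow(tpm),
         dimnames = list(rownames(tpm), GROUP_LEVELS))
}
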