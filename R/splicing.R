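#' Percent spliced in (PSI)
#'
#' PSI of an event in a sample is the inclusion junction count divided by
#' the total junction count: `inc / (inc + exc)`. A sample with zero total
#' coverage has undefined PSI (`NA`) and is excluded from group means.
#'
#' `computePsi()` is a generic: given two numeric vectors it evaluates the
#' formula element-wise; given a [SpliceEventExperiment-class] it returns
#' the events x samples PSI matrix.
#'
#' @param x inclusion counts (numeric) or a [SpliceEventExperiment-class].
#' @param exc exclusion counts (numeric method only).
#' @param ... unused.
#' @return numeric vector or matrix of PSI values in \[0, 1\].
#' @examples
#' computePsi(3, 1)   # 0.75
#' @export
setGeneric("computePsi", function(x, ...) standardGeneric("computePsi"))

#' @rdname computePsi
#' @export
setMethod("computePsi", "numeric", function(x, exc, ...) {
  if (any(x < 0) || any(exc < 0)) stopf("junction counts must be non-negative")
  tot <- x + exc
  psi <- ifelse(tot == 0, NA_real_, x / tot)
  if (anyNA(psi)) warnf("%d observation(s) with zero coverage: PSI undefined", sum(is.na(psi)))
  psi
})

#' @rdname computePsi
#' @export
setMethod("computePsi", "SpliceEventExperiment", function(x, ...) {
  inc <- inclusionCounts(x)
  exc <- exclusionCounts(x)
  tot <- inc + exc
  psi <- inc / tot
  psi[tot == 0] <- NA_real_
  if (anyNA(psi)) {
    warnf("%d event/sample cell(s) with zero coverage: PSI undefined", sum(is.na(psi)))
  }
  psi
})

#' Differential alternative-splicing events
#'
#' Compares each event between the control group (L0) and a comparison
#' group. The default test is a two-sided Fisher's exact test on the 2x2
#' table of inclusion/exclusion junction counts pooled within each group;
#' the `"ttest"` option applies a Welch t-test to the per-sample PSI values
#' instead. Delta PSI is the difference of per-sample PSI group means
#' (comparison minus control). P-values are Benjamini-Hochberg adjusted
#' jointly across all event types in the comparison, and an event is flagged
#' differential iff `fdr < fdr_splice` AND `|delta_psi| >= dpsi_min`.
#'
#' @param events a [SpliceEventExperiment-class].
#' @param design sample design matching the event columns.
#' @param control control group label (default `"L0"`).
#' @param comparison comparison group label.
#' @param method `"fisher"` (pooled counts, default) or `"ttest"`
#'   (per-replicate PSI).
#' @param fdr_splice FDR threshold (default 0.1).
#' @param dpsi_min minimum |delta PSI| (default 0.05).
#' @return `DataFrame` with `event_id`, `type`, `gene_id`, per-group mean
#'   PSI, `delta_psi`, `p`, `fdr`, `is_differential`. Events whose PSI is
#'   undefined in every sample of a group are excluded with a warning.
#' @export
differentialEvents <- function(events, design, control = "L0", comparison,
                               method = c("fisher", "ttest"),
                               fdr_splice = 0.1, dpsi_min = 0.05) {
  stopifnot(is(events, "SpliceEventExperiment"))
  method <- match.arg(method)
  checkDesign(design)
  grp <- as.character(design$group[match(colnames(events), design$sample_id)])
  ic <- which(grp == control)
  ix <- which(grp == comparison)
  if (length(ic) < 2 || length(ix) < 2) {
    stopf("both groups need >= 2 samples (%s: %d, %s: %d)", control,
          length(ic), comparison, length(ix))
  }
  inc <- inclusionCounts(events)
  exc <- exclusionCounts(events)
  psi <- suppressWarnings(computePsi(events))
  mean_c <- rowMeans(psi[, ic, drop = FALSE], na.rm = TRUE)
  mean_x <- rowMeans(psi[, ix, drop = FALSE], na.rm = TRUE)
  undef <- is.nan(mean_c) | is.nan(mean_x)
  if (any(undef)) {
    warnf("excluding %d event(s) with all-missing PSI in a group", sum(undef))
  }
  keep <- which(!undef)
  p <- vapply(keep, function(i) {
    if (method == "fisher") {
      tab <- matrix(c(sum(inc[i, ic]), sum(exc[i, ic]),
                      sum(inc[i, ix]), sum(exc[i, ix])), 2, 2, byrow = TRUE)
      if (sum(tab) == 0) return(1)
      fisher.test(tab, alternative = "two.sided")$p.value
    } else {
      a <- psi[i, ic]; b <- psi[i, ix]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      if (sd(a) == 0 && sd(b) == 0) return(if (mean(a) == mean(b)) 1 else 0)
      stats::t.test(a, b)$p.value
    }
  }, numeric(1))
  fdr <- p.adjust(p, method = "BH")
  dpsi <- mean_x[keep] - mean_c[keep]
  res <- S4Vectors::DataFrame(
    event_id = rownames(events)[keep],
    type = eventType(events)[keep],
    gene_id = as.character(SummarizedExperiment::rowData(events)$gene_id)[keep],
    mean_psi_control = unname(mean_c[keep]),
    mean_psi_comparison = unname(mean_x[keep]),
    delta_psi = unname(dpsi),
    p = unname(p), fdr = unname(fdr),
    is_differential = unname(fdr < fdr_splice & abs(dpsi) >= dpsi_min)
  )
  txInfo("differential splicing %s vs %s (%s): %d / %d events at FDR < %g, |dPSI| >= %g",
         comparison, control, method, sum(res$is_differential), nrow(res),
         fdr_splice, dpsi_min)
  res
}

#' Tally flagged splicing events by type
#'
#' @param results a `DataFrame` from [differentialEvents()] (or a list of
#'   them, summed).
#' @return named integer vector over `SE`, `A5SS`, `A3SS`, `MXE`, `RI`.
#' @export
tallyEventTypes <- function(results) {
  if (is.list(results) && !is.data.frame(results) && !is(results, "DataFrame")) {
    tallies <- vapply(results, tallyEventTypes, integer(length(EVENT_TYPES)))
    return(setNames(as.integer(rowSums(tallies)), EVENT_TYPES))
  }
  flagged <- results[results$is_differential, , drop = FALSE]
  tab <- table(factor(flagged$type, levels = EVENT_TYPES))
  setNames(as.integer(tab), EVENT_TYPES)
}
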