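#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAString DNAStringSet
NULL

#' DoseExperiment: read counts for the four-group dose series
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding the
#' gene x sample read-count matrix for the tryptophan dose series. The
#' `counts` assay stores non-negative integers; `rowData(x)$effective_length`
#' carries the per-gene union-exon length in bp used by TPM normalisation;
#' `colData(x)` carries the sample design (`group`, `dose_pct`,
#' `is_reference`, `replicate`).
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [DoseExperiment()] for the constructor, [computeTpm()],
#'   [differentialExpression()].
#' @export
setClass("DoseExperiment", contains = "SummarizedExperiment")

setValidity("DoseExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cnt))) msg <- c(msg, "counts must not contain NA")
    else {
      if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"effective_length" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'effective_length' is required")
  } else if (any(is.na(rd$effective_length)) || any(rd$effective_length <= 0)) {
    msg <- c(msg, "effective_length must be positive for every gene")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "dose_pct", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("colData missing column(s): ", paste(miss, collapse = ", ")))
  } else if (!all(as.character(cd$group) %in% GROUP_LEVELS)) {
    msg <- c(msg, paste0("group labels must be among ", paste(GROUP_LEVELS, collapse = "/")))
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseExperiment
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param lengths numeric vector of per-gene effective lengths (bp), named by
#'   gene or in row order.
#' @param design a sample design `data.frame` as returned by
#'   [pipelineDesign()], rows matching `colnames(counts)`.
#' @return A [DoseExperiment-class] object.
#' @examples
#' dsn <- pipelineDesign(n_rep = 2)
#' cnt <- matrix(5L, 3, nrow(dsn), dimnames = list(paste0("g", 1:3), dsn$sample_id))
#' dex <- DoseExperiment(cnt, lengths = c(1000, 1500, 2000), design = dsn)
#' dex
#' @export
DoseExperiment <- function(counts, lengths, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("count matrix must carry gene row names and sample column names")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss)) {
      stopf("missing effective length for gene(s): %s",
            paste(head(miss, 5), collapse = ", "))
    }
    lengths <- lengths[rownames(counts)]
  } else if (length(lengths) != nrow(counts)) {
    stopf("lengths must match the number of genes")
  }
  design <- as.data.frame(design)
  if (!all(colnames(counts) %in% design$sample_id)) {
    stopf("every count column must appear in design$sample_id")
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(design, row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(effective_length = as.numeric(lengths),
                                   row.names = rownames(counts)),
    colData = cd
  )
  new("DoseExperiment", se)
}

#' Accessors for DoseExperiment
#'
#' `doseCounts()` returns the integer count assay, `effectiveLengths()` the
#' per-gene union-exon lengths (bp), `sampleGroups()` the ordered factor of
#' treatment groups and `doseDesign()` the sample design as a `data.frame`.
#'
#' @param x a [DoseExperiment-class].
#' @return matrix / numeric vector / factor / data.frame respectively.
#' @name DoseExperiment-accessors
#' @export
doseCounts <- function(x) {
  stopifnot(is(x, "DoseExperiment"))
  SummarizedExperiment::assay(x, "counts")
}

#' @rdname DoseExperiment-accessors
#' @export
effectiveLengths <- function(x) {
  stopifnot(is(x, "DoseExperiment"))
  setNames(SummarizedExperiment::rowData(x)$effective_length, rownames(x))
}

#' @rdname DoseExperiment-accessors
#' @export
sampleGroups <- function(x) {
  stopifnot(is(x, "DoseExperiment"))
  factor(as.character(SummarizedExperiment::colData(x)$group), levels = GROUP_LEVELS)
}

#' @rdname DoseExperiment-accessors
#' @export
doseDesign <- function(x) {
  stopifnot(is(x, "DoseExperiment"))
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "DoseExperiment", function(object) {
  callNextMethod()
  grp <- table(sampleGroups(object))
  cat("groups:", paste(sprintf("%s(%d)", names(grp), grp), collapse = " "), "\n")
})

#' SpliceEventExperiment: junction counts for alternative-splicing events
#'
#' Extends `RangedSummarizedExperiment` with two integer assays, `inclusion`
#' and `exclusion`, one row per alternative-splicing event. `rowRanges` holds
#' the event body (the alternatively spliced exon for SE/MXE, the alternative
#' segment for A5SS/A3SS, the retained intron for RI); `rowData` carries
#' `type` (SE/A5SS/A3SS/MXE/RI), `gene_id`, and for MXE the second exclusive
#' exon as `body2_start`/`body2_end` (1-based closed).
#'
#' @seealso [SpliceEventExperiment()], [computePsi()], [differentialEvents()].
#' @export
setClass("SpliceEventExperiment", contains = "RangedSummarizedExperiment")

setValidity("SpliceEventExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("inclusion", "exclusion") %in% an)) {
    msg <- c(msg, "assays 'inclusion' and 'exclusion' are required")
  } else {
    inc <- SummarizedExperiment::assay(object, "inclusion")
    exc <- SummarizedExperiment::assay(object, "exclusion")
    if (any(inc < 0, na.rm = TRUE) || any(exc < 0, na.rm = TRUE)) {
      msg <- c(msg, "junction counts must be non-negative")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("type", "gene_id") %in% colnames(rd))) {
    msg <- c(msg, "rowData must carry 'type' and 'gene_id'")
  } else {
    if (!all(as.character(rd$type) %in% EVENT_TYPES)) {
      msg <- c(msg, paste0("event type must be one of ", paste(EVENT_TYPES, collapse = "/")))
    }
    mxe <- as.character(rd$type) == "MXE"
    if (any(mxe)) {
      if (!all(c("body2_start", "body2_end") %in% colnames(rd)) ||
          any(is.na(rd$body2_start[mxe])) || any(is.na(rd$body2_end[mxe]))) {
        msg <- c(msg, "MXE events must carry second-exon coordinates")
      }
    }
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "event ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SpliceEventExperiment
#'
#' @param body a `GRanges` of event bodies (one per event), named by event id,
#'   with strand set.
#' @param type character vector of event types (`SE`, `A5SS`, `A3SS`, `MXE`,
#'   `RI`).
#' @param gene_id character vector of host gene ids.
#' @param inclusion,exclusion integer matrices (events x samples) of junction
#'   read counts supporting inclusion / exclusion of the event body.
#' @param body2_start,body2_end integer vectors (1-based closed) giving the
#'   MXE second exclusive exon; `NA` for other event types.
#' @return A [SpliceEventExperiment-class].
#' @export
SpliceEventExperiment <- function(body, type, gene_id, inclusion, exclusion,
                                  body2_start = NA_integer_,
                                  body2_end = NA_integer_) {
  inclusion <- as.matrix(inclusion); storage.mode(inclusion) <- "integer"
  exclusion <- as.matrix(exclusion); storage.mode(exclusion) <- "integer"
  if (!identical(dim(inclusion), dim(exclusion))) {
    stopf("inclusion and exclusion matrices must have identical dimensions")
  }
  rd <- S4Vectors::DataFrame(type = as.character(type), gene_id = as.character(gene_id))
  rd$body2_start <- as.integer(rep_len(body2_start, length(body)))
  rd$body2_end <- as.integer(rep_len(body2_end, length(body)))
  S4Vectors::mcols(body) <- rd
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(inclusion = inclusion, exclusion = exclusion),
    rowRanges = body
  )
  rownames(se) <- names(body)
  new("SpliceEventExperiment", se)
}

#' Accessors for SpliceEventExperiment
#'
#' @param x a [SpliceEventExperiment-class].
#' @return `inclusionCounts()`/`exclusionCounts()` return integer matrices;
#'   `eventType()` a character vector; `eventBody()` the body `GRanges`.
#' @name SpliceEventExperiment-accessors
#' @export
inclusionCounts <- function(x) SummarizedExperiment::assay(x, "inclusion")

#' @rdname SpliceEventExperiment-accessors
#' @export
exclusionCounts <- function(x) SummarizedExperiment::assay(x, "exclusion")

#' @rdname SpliceEventExperiment-accessors
#' @export
eventType <- function(x) as.character(SummarizedExperiment::rowData(x)$type)

#' @rdname SpliceEventExperiment-accessors
#' @export
eventBody <- function(x) SummarizedExperiment::rowRanges(x)

setMethod("show", "SpliceEventExperiment", function(object) {
  callNextMethod()
  tt <- table(factor(eventType(object), levels = EVENT_TYPES))
  cat("event types:", paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
})

#' RBPMotif: one RNA-binding-protein motif
#'
#' Represents a single RBP motif either as an IUPAC consensus (stored in the
#' DNA alphabet, U mapped to T) or as a position-frequency matrix with rows
#' A/C/G/T. PFM scanning calls a hit where the log-odds score against a
#' uniform background reaches `scoreThreshold` times the maximum attainable
#' score.
#'
#' @slot rbp RBP (protein) name.
#' @slot motifId motif identifier, unique within the RBP.
#' @slot kind `"iupac"` or `"pfm"`.
#' @slot consensus IUPAC consensus string (DNA alphabet) for `kind = "iupac"`.
#' @slot pfm 4 x width numeric matrix (rows A,C,G,T) for `kind = "pfm"`.
#' @slot scoreThreshold fraction of the maximum log-odds score required for a
#'   PFM hit (default 0.8).
#' @export
setClass("RBPMotif", representation(
  rbp = "character", motifId = "character", kind = "character",
  consensus = "character", pfm = "matrix", scoreThreshold = "numeric"
))

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

setValidity("RBPMotif", function(object) {
  msg <- character()
  if (!object@kind %in% c("iupac", "pfm")) msg <- c(msg, "kind must be 'iupac' or 'pfm'")
  if (object@kind == "iupac") {
    chars <- strsplit(object@consensus, "")[[1]]
    if (length(chars) < 4) msg <- c(msg, "motif width must be >= 4")
    bad <- setdiff(chars, IUPAC_CHARS)
    if (length(bad)) {
      msg <- c(msg, paste0("illegal IUPAC character(s): ", paste(bad, collapse = "")))
    }
  } else {
    if (nrow(object@pfm) != 4) msg <- c(msg, "PFM must have 4 rows (A,C,G,T)")
    if (ncol(object@pfm) < 4) msg <- c(msg, "motif width must be >= 4")
    cs <- colSums(object@pfm)
    if (any(abs(cs - cs[1]) > 0.01 * cs[1])) {
      msg <- c(msg, "PFM column sums must agree within 1%")
    }
    if (object@scoreThreshold <= 0 || object@scoreThreshold > 1) {
      msg <- c(msg, "scoreThreshold must lie in (0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct RBP motifs
#'
#' `iupacMotif()` builds a consensus motif (U is normalised to T);
#' `pfmMotif()` builds a position-frequency-matrix motif.
#'
#' @param rbp RBP name.
#' @param motif_id motif identifier.
#' @param consensus IUPAC string (RNA or DNA alphabet).
#' @param pfm 4 x width matrix, rows in order A,C,G,T (or A,C,G,U).
#' @param score_threshold PFM hit threshold as a fraction of the maximum
#'   log-odds score.
#' @return An [RBPMotif-class].
#' @examples
#' iupacMotif("SRSF1", "m1", "GGAGGA")
#' @export
iupacMotif <- function(rbp, motif_id, consensus) {
  consensus <- toupper(gsub("U", "T", toupper(consensus)))
  new("RBPMotif", rbp = rbp, motifId = motif_id, kind = "iupac",
      consensus = consensus, pfm = matrix(numeric(), 4, 0), scoreThreshold = 0.8)
}

#' @rdname iupacMotif
#' @export
pfmMotif <- function(rbp, motif_id, pfm, score_threshold = 0.8) {
  pfm <- as.matrix(pfm)
  rownames(pfm) <- c("A", "C", "G", "T")
  new("RBPMotif", rbp = rbp, motifId = motif_id, kind = "pfm",
      consensus = "", pfm = pfm, scoreThreshold = score_threshold)
}

#' Width of a motif in bases
#' @param x an [RBPMotif-class].
#' @return integer width.
#' @export
motifWidth <- function(x) {
  stopifnot(is(x, "RBPMotif"))
  if (x@kind == "iupac") nchar(x@consensus) else ncol(x@pfm)
}

setMethod("show", "RBPMotif", function(object) {
  if (object@kind == "iupac") {
    cat(sprintf("RBPMotif %s/%s IUPAC %s\n", object@rbp, object@motifId,
                object@consensus))
  } else {
    cat(sprintf("RBPMotif %s/%s PFM width %d (threshold %.2f x max score)\n",
                object@rbp, object@motifId, ncol(object@pfm),
                object@scoreThreshold))
  }
})

#' CoexpressionNetwork: thresholded Pearson co-expression graph
#'
#' Undirected graph over genes whose four-group base-mean profiles correlate
#' beyond the threshold (\code{r > r_threshold} or \code{r < -r_threshold},
#' strict).
#'
#' @slot nodes `DataFrame` with columns `gene_id`, `degree`, `highlighted`
#'   (degree above the hub-degree cut), `hub` (top-fraction by degree rank)
#'   and optionally `direction` (up/down in N0).
#' @slot edges `DataFrame` with columns `gene_a`, `gene_b`, `r`, `sign`.
#' @slot rThreshold the correlation threshold used.
#' @seealso [correlationNetwork()], [detectHubs()].
#' @export
setClass("CoexpressionNetwork", representation(
  nodes = "DataFrame", edges = "DataFrame", rThreshold = "numeric"
))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  if (!all(c("gene_id", "degree") %in% colnames(object@nodes))) {
    msg <- c(msg, "nodes need 'gene_id' and 'degree' columns")
  }
  if (nrow(object@edges) > 0) {
    if (!all(c("gene_a", "gene_b", "r") %in% colnames(object@edges))) {
      msg <- c(msg, "edges need 'gene_a', 'gene_b', 'r' columns")
    } else if (any(abs(object@edges$r) <= object@rThreshold)) {
      msg <- c(msg, "every edge must exceed the correlation threshold")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Accessors for CoexpressionNetwork
#' @param x a [CoexpressionNetwork-class].
#' @return `networkNodes()` and `networkEdges()` return `DataFrame`s;
#'   `networkDegree()` a named integer vector.
#' @name CoexpressionNetwork-accessors
#' @export
networkNodes <- function(x) x@nodes

#' @rdname CoexpressionNetwork-accessors
#' @export
networkEdges <- function(x) x@edges

#' @rdname CoexpressionNetwork-accessors
#' @export
networkDegree <- function(x) setNames(x@nodes$degree, x@nodes$gene_id)

setMethod("show", "CoexpressionNetwork", function(object) {
  cat(sprintf("CoexpressionNetwork: %d nodes, %d edges (|r| > %g)\n",
              nrow(object@nodes), nrow(object@edges), object@rThreshold))
  if ("hub" %in% colnames(object@nodes)) {
    cat(sprintf("  highlighted: %d, hubs: %d\n",
                sum(object@nodes$highlighted), sum(object@nodes$hub)))
  }
})
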