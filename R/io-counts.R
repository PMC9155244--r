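#' Read / write a gene x sample read-count table
#'
#' The canonical dialect is a UTF-8 TSV whose first column (`gene_id`) holds
#' gene identifiers and whose remaining columns hold non-negative integer
#' read counts, one column per sample. `read_count_matrix`-style validation
#' is applied: negative, non-integer or missing cells are rejected with the
#' offending row/column named, as are duplicated gene ids.
#'
#' @param path TSV file path.
#' @param lengths per-gene effective lengths (bp) used to build a
#'   [DoseExperiment-class]; named by gene id.
#' @param design sample design (see [pipelineDesign()]); defaults to the
#'   standard 4 x 6 design inferred from the column names.
#' @return `readCountMatrix()` returns a [DoseExperiment-class];
#'   `writeCountMatrix()` writes the canonical dialect and returns the path
#'   invisibly. A write/read cycle is lossless, and a read/write cycle is
#'   byte-identical for files already in the canonical dialect.
#' @examples
#' dsn <- pipelineDesign(n_rep = 2)
#' cnt <- matrix(1:16, 2, 8, dimnames = list(c("g1", "g2"), dsn$sample_id))
#' f <- tempfile(fileext = ".tsv")
#' writeCountMatrix(cnt, f)
#' dex <- readCountMatrix(f, lengths = c(g1 = 500, g2 = 800), design = dsn)
#' dim(dex)
#' @export
readCountMatrix <- function(path, lengths, design = NULL) {
  tab <- readCanonicalTsv(path, colClasses = "character")
  if (ncol(tab) < 2) stopf("count table needs a gene_id column plus >= 1 sample column")
  gene_id <- tab[[1]]
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) stopf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  samples <- colnames(tab)[-1]
  mat <- matrix(NA_integer_, nrow(tab), length(samples),
                dimnames = list(gene_id, samples))
  for (j in seq_along(samples)) {
    cell <- tab[[j + 1L]]
    bad <- which(is.na(cell) | !grepl("^[0-9]+$", cell))
    if (length(bad)) {
      stopf("non-integer or negative count '%s' at gene '%s', sample '%s'",
            cell[bad[1]], gene_id[bad[1]], samples[j])
    }
    mat[, j] <- as.integer(cell)
  }
  if (is.null(design)) {
    grp <- sub("_r[0-9]+$", "", samples)
    n_rep <- length(samples) / length(unique(grp))
    design <- pipelineDesign(n_rep = max(2, ceiling(n_rep)))
    design <- design[design$sample_id %in% samples, , drop = FALSE]
    if (!all(samples %in% design$sample_id)) {
      stopf("cannot infer design from sample names; pass 'design' explicitly")
    }
  }
  checkDesign(design)
  txInfo("read count matrix: %d genes x %d samples from %s", nrow(mat),
         ncol(mat), path)
  DoseExperiment(mat, lengths = lengths, design = design)
}

#' @param x a [DoseExperiment-class] or an integer matrix with dimnames.
#' @rdname readCountMatrix
#' @export
writeCountMatrix <- function(x, path) {
  mat <- if (is(x, "DoseExperiment")) doseCounts(x) else as.matrix(x)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeCanonicalTsv(df, path)
}
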