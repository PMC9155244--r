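#' Read / write splicing-event junction-count tables
#'
#' The canonical dialect is an rMATS-style TSV with columns `event_id`,
#' `type` (SE/A5SS/A3SS/MXE/RI), `gene_id`, `chrom`, `strand`, the event
#' body as 0-based half-open `body_start`/`body_end`, the MXE second
#' exclusive exon as `body2_start`/`body2_end` (`NA` otherwise), then one
#' `inc_<sample>` and one `exc_<sample>` integer column per sample.
#' Coordinates are converted to 1-based closed `GRanges` on read and back on
#' write, so a write/read cycle is lossless.
#'
#' @param path TSV file path.
#' @param design optional sample design; when given, the count columns must
#'   match its `sample_id`s exactly.
#' @return `readEventCounts()` returns a [SpliceEventExperiment-class];
#'   `writeEventCounts()` returns the path invisibly.
#' @export
readEventCounts <- function(path, design = NULL) {
  tab <- readCanonicalTsv(path)
  fixed <- c("event_id", "type", "gene_id", "chrom", "strand",
             "body_start", "body_end", "body2_start", "body2_end")
  miss <- setdiff(fixed, colnames(tab))
  if (length(miss)) stopf("event table missing column(s): %s", paste(miss, collapse = ", "))
  badType <- setdiff(unique(tab$type), EVENT_TYPES)
  if (length(badType)) stopf("unknown event type code(s): %s", paste(badType, collapse = ", "))
  mxe <- tab$type == "MXE"
  if (any(mxe & (is.na(tab$body2_start) | is.na(tab$body2_end)))) {
    stopf("MXE event(s) missing second-exon coordinates: %s",
          paste(tab$event_id[mxe & is.na(tab$body2_start)], collapse = ", "))
  }
  inc_cols <- grep("^inc_", colnames(tab), value = TRUE)
  exc_cols <- grep("^exc_", colnames(tab), value = TRUE)
  if (length(inc_cols) == 0 || !identical(sub("^inc_", "", inc_cols),
                                          sub("^exc_", "", exc_cols))) {
    stopf("event table needs matching inc_<sample>/exc_<sample> column pairs")
  }
  samples <- sub("^inc_", "", inc_cols)
  if (!is.null(design)) {
    checkDesign(design)
    if (!setequal(samples, design$sample_id)) {
      stopf("event count columns do not match the sample design (extra: %s; missing: %s)",
            paste(setdiff(samples, design$sample_id), collapse = ","),
            paste(setdiff(design$sample_id, samples), collapse = ","))
    }
    samples <- design$sample_id
  }
  inc <- as.matrix(tab[, paste0("inc_", samples), drop = FALSE])
  exc <- as.matrix(tab[, paste0("exc_", samples), drop = FALSE])
  colnames(inc) <- colnames(exc) <- samples
  if (any(inc < 0, na.rm = TRUE) || any(exc < 0, na.rm = TRUE)) {
    stopf("negative junction counts in '%s'", path)
  }
  ## disk dialect is 0-based half-open; GRanges is 1-based closed
  body <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$body_start + 1L, end = tab$body_end),
    strand = tab$strand
  )
  names(body) <- tab$event_id
  b2s <- ifelse(is.na(tab$body2_start), NA_integer_, tab$body2_start + 1L)
  ses <- SpliceEventExperiment(body, tab$type, tab$gene_id, inc, exc,
                               body2_start = as.integer(b2s),
                               body2_end = as.integer(tab$body2_end))
  txInfo("read %d splicing event(s) x %d sample(s) from %s", nrow(ses),
         ncol(ses), path)
  ses
}

#' @param events a [SpliceEventExperiment-class].
#' @rdname readEventCounts
#' @export
writeEventCounts <- function(events, path) {
  body <- eventBody(events)
  rd <- SummarizedExperiment::rowData(events)
  inc <- inclusionCounts(events)
  exc <- exclusionCounts(events)
  df <- data.frame(
    event_id = rownames(events),
    type = as.character(rd$type),
    gene_id = as.character(rd$gene_id),
    chrom = as.character(GenomicRanges::seqnames(body)),
    strand = as.character(GenomicRanges::strand(body)),
    body_start = GenomicRanges::start(body) - 1L,
    body_end = GenomicRanges::end(body),
    body2_start = ifelse(is.na(rd$body2_start), NA_integer_, rd$body2_start - 1L),
    body2_end = rd$body2_end,
    stringsAsFactors = FALSE
  )
  colnames(inc) <- paste0("inc_", colnames(inc))
  colnames(exc) <- paste0("exc_", colnames(exc))
  writeCanonicalTsv(cbind(df, inc, exc), path)
}

#' Read / write the per-sample trait table
#'
#' Two-column TSV `sample_id`, `tg_mg_dl` (postprandial plasma triglycerides,
#' mg/dL).
#'
#' @param path TSV file path.
#' @param trait data.frame with columns `sample_id` and `tg_mg_dl`.
#' @return `readTraitTable()` returns the data.frame; `writeTraitTable()` the
#'   path, invisibly.
#' @export
readTraitTable <- function(path) {
  tab <- readCanonicalTsv(path)
  if (!all(c("sample_id", "tg_mg_dl") %in% colnames(tab))) {
    stopf("trait table needs columns sample_id, tg_mg_dl")
  }
  if (any(is.na(tab$tg_mg_dl))) stopf("missing trait value(s) in '%s'", path)
  tab
}

#' @rdname readTraitTable
#' @export
writeTraitTable <- function(trait, path) {
  stopifnot(all(c("sample_id", "tg_mg_dl") %in% colnames(trait)))
  writeCanonicalTsv(trait[, c("sample_id", "tg_mg_dl")], path)
}
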