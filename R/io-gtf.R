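#' Read gene models from a GTF file
#'
#' Imports exon features via `rtracklayer`, groups them by `gene_id`, and
#' computes each gene's effective length as the length of the union of its
#' exon intervals (the length TPM normalisation divides by). GTF coordinates
#' are 1-based inclusive; they are kept in `GRanges` convention internally.
#'
#' @param path GTF file path.
#' @return A named list with `exons` (a `GRangesList`, one element per gene)
#'   and `lengths` (named numeric vector of union-exon lengths in bp). An
#'   empty file yields empty containers with a warning.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1\tsrc\texon\t1\t100\t.\t+\t.",
#'                  'gene_id "g1"; transcript_id "g1.t1";'), gtf)
#' readGtfGeneModels(gtf)$lengths
#' @export
readGtfGeneModels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warnf("GTF file '%s' contains no features; returning empty gene models", path)
    return(list(exons = GenomicRanges::GRangesList(), lengths = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) stopf("malformed GTF line %d: fewer than 9 fields", which(nf < 9)[1])
  starts <- as.integer(vapply(fields, `[[`, "", 4L))
  ends <- as.integer(vapply(fields, `[[`, "", 5L))
  bad <- which(ends < starts)
  if (length(bad)) {
    stopf("GTF line %d: end (%d) < start (%d)", bad[1], ends[bad[1]], starts[bad[1]])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    warnf("GTF file '%s' has no exon features; returning empty gene models", path)
    return(list(exons = GenomicRanges::GRangesList(), lengths = numeric()))
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stopf("exon feature without a gene_id attribute in '%s'", path)
  }
  exons <- GenomicRanges::split(gr, gr$gene_id)
  lens <- sum(GenomicRanges::width(GenomicRanges::reduce(exons)))
  txInfo("read %d gene model(s) (%d exons) from %s", length(exons), length(gr), path)
  list(exons = exons, lengths = lens)
}

#' Write gene models as GTF
#'
#' Emits one `exon` feature per interval with `gene_id`/`transcript_id`
#' attributes (transcript id is `<gene_id>.t1`): enough structure for
#' [readGtfGeneModels()] to round-trip the models.
#'
#' @param exons a `GRangesList` named by gene id.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGtfGeneModels <- function(exons, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (g in names(exons)) {
    e <- exons[[g]]
    strand <- as.character(GenomicRanges::strand(e))
    strand[strand == "*"] <- "+"
    lines <- sprintf(
      "%s\tdoseTx\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
      as.character(GenomicRanges::seqnames(e)), GenomicRanges::start(e),
      GenomicRanges::end(e), strand, g, g)
    writeLines(lines, con)
  }
  invisible(path)
}
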