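#' Read / write RBP motif definitions
#'
#' Two plain-text dialects are supported and auto-detected:
#' \describe{
#'   \item{consensus (dialect A)}{one motif per line,
#'     `RBP_NAME<TAB>MOTIF_ID<TAB>IUPAC_STRING`; RNA alphabets are accepted
#'     (U and T are equivalent, stored as T).}
#'   \item{PFM (dialect B)}{blocks starting with a header
#'     `>RBP_NAME<TAB>MOTIF_ID` followed by four rows `A:`, `C:`, `G:`,
#'     `T:`/`U:` of per-position counts; all columns must sum to a common
#'     total within 1%.}
#' }
#' Lines beginning with `#` and blank lines are ignored.
#'
#' @param path motif file path.
#' @return `readMotifs()` returns a list of [RBPMotif-class] objects;
#'   `writeMotifs()` writes dialect A/B as appropriate and returns the path.
#' @examples
#' f <- tempfile()
#' writeLines("SRSF1\tm1\tGGAGGA", f)
#' readMotifs(f)[[1]]
#' @export
readMotifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warnf("motif file '%s' is empty", path)
    return(list())
  }
  if (any(startsWith(lines, ">"))) {
    motifs <- parsePfmBlocks(lines)
  } else {
    motifs <- lapply(lines, function(ln) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 3) {
        stopf("malformed consensus motif line (expect RBP<TAB>ID<TAB>IUPAC): '%s'", ln)
      }
      iupacMotif(parts[1], parts[2], parts[3])
    })
  }
  for (m in motifs) validObject(m)
  key <- vapply(motifs, function(m) paste(m@rbp, m@motifId, sep = "/"), "")
  if (anyDuplicated(key)) {
    stopf("duplicate (rbp, motif_id) pair(s): %s", paste(unique(key[duplicated(key)]),
                                                         collapse = ", "))
  }
  txInfo("read %d motif(s) for %d RBP(s) from %s", length(motifs),
         length(unique(vapply(motifs, function(m) m@rbp, ""))), path)
  motifs
}

parsePfmBlocks <- function(lines) {
  heads <- which(startsWith(lines, ">"))
  motifs <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    ids <- strsplit(hdr, "[\t ]+")[[1]]
    if (length(ids) < 2) stopf("PFM header needs RBP and motif id: '%s'", lines[heads[i]])
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) != 4) {
      stopf("PFM block '%s' must have exactly 4 base rows (got %d)", hdr, length(body))
    }
    rows <- lapply(body, function(ln) {
      parts <- strsplit(trimws(ln), "[:\t ]+")[[1]]
      list(base = toupper(parts[1]), vals = as.numeric(parts[-1]))
    })
    bases <- vapply(rows, `[[`, "", "base")
    bases[bases == "U"] <- "T"
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      stopf("PFM block '%s' rows must be A/C/G/T (or U)", hdr)
    }
    wid <- unique(lengths(lapply(rows, `[[`, "vals")))
    if (length(wid) != 1) stopf("PFM block '%s' has ragged rows", hdr)
    pfm <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(pfm) <- bases
    pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
    cs <- colSums(pfm)
    if (any(abs(cs - cs[1]) > 0.01 * cs[1])) {
      stopf("PFM block '%s': column sums differ by more than 1%% (%s)", hdr,
            paste(signif(cs, 4), collapse = ", "))
    }
    motifs[[i]] <- pfmMotif(ids[1], ids[2], pfm)
  }
  motifs
}

#' @param motifs list of [RBPMotif-class] objects.
#' @rdname readMotifs
#' @export
writeMotifs <- function(motifs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (m in motifs) {
    if (m@kind == "iupac") {
      writeLines(sprintf("%s\t%s\t%s", m@rbp, m@motifId, m@consensus), con)
    } else {
      writeLines(sprintf(">%s\t%s", m@rbp, m@motifId), con)
      for (b in c("A", "C", "G", "T")) {
        writeLines(paste0(b, ": ", paste(m@pfm[b, ], collapse = " ")), con)
      }
    }
  }
  invisible(path)
}
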