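#' Build RBP binding regions around spliced exons
#'
#' For each event the scanned region is the alternatively spliced exon body
#' plus 250 bp flanks either side, with the `trim_bp` (10 bp) intronic bases
#' adjacent to each splice junction excluded — these carry the core
#' spliceosomal signal and would otherwise dominate any motif test. With the
#' body at 1-based \[s, e\] the three genomic pieces are
#' `[s - flank_bp, s - trim_bp - 1]`, `[s, e]`, and
#' `[e + trim_bp + 1, e + flank_bp]`. Flanks are clipped at chromosome ends
#' (with a warning), never an error. Geometry per event type: SE and
#' A5SS/A3SS use the stored alternative segment as the body; RI uses the
#' retained intron (flanks extend into the adjacent exons); MXE yields one
#' region per exclusive exon, named `<event_id>#1` / `<event_id>#2`.
#'
#' On the minus strand the genomic intervals are identical; sequences are
#' reverse-complemented and pieces re-ordered 5' to 3' in transcript sense
#' by [regionSequences()].
#'
#' @param events a [SpliceEventExperiment-class].
#' @param genome a `DNAStringSet` named by chromosome (used for end
#'   clipping; may be omitted if `seqlengths` are unneeded).
#' @param which event ids to build regions for (default all).
#' @param flank_bp flank length (default 250).
#' @param trim_bp splice-site exclusion (default 10).
#' @return a `GRangesList`, one element per region, each a piece-`GRanges`
#'   (mcols `piece` in `flank_up`/`body`/`flank_down`) with `event_id` in
#'   the list's metadata columns.
#' @export
buildBindingRegions <- function(events, genome = NULL, which = rownames(events),
                                flank_bp = 250, trim_bp = 10) {
  stopifnot(is(events, "SpliceEventExperiment"))
  if (trim_bp > flank_bp) stopf("trim_bp cannot exceed flank_bp")
  body <- eventBody(events)
  rd <- SummarizedExperiment::rowData(events)
  which <- intersect(which, rownames(events))
  i <- match(which, rownames(events))

  ## one row per region body (MXE contributes two)
  reg <- data.frame(
    event_id = which,
    name = which,
    chrom = as.character(GenomicRanges::seqnames(body))[i],
    strand = as.character(GenomicRanges::strand(body))[i],
    start = GenomicRanges::start(body)[i],
    end = GenomicRanges::end(body)[i],
    stringsAsFactors = FALSE
  )
  mxe <- which(as.character(rd$type)[i] == "MXE")
  if (length(mxe)) {
    reg2 <- reg[mxe, , drop = FALSE]
    reg2$start <- rd$body2_start[i][mxe]
    reg2$end <- rd$body2_end[i][mxe]
    reg$name[mxe] <- paste0(reg$name[mxe], "#1")
    reg2$name <- paste0(reg2$event_id, "#2")
    ord <- order(c(seq_len(nrow(reg)), mxe + 0.5))
    reg <- rbind(reg, reg2)[ord, , drop = FALSE]
  }

  chrlen <- if (!is.null(genome)) {
    setNames(BiocGenerics::width(genome), names(genome))[reg$chrom]
  } else {
    rep(NA_real_, nrow(reg))
  }
  too_long <- !is.na(chrlen) & (reg$end - reg$start + 1) > chrlen
  if (any(too_long)) {
    stopf("event '%s': exon longer than chromosome '%s'",
          reg$event_id[too_long][1], reg$chrom[too_long][1])
  }

  ## pieces: trimmed upstream flank, body, trimmed downstream flank
  n <- nrow(reg)
  pstart <- c(reg$start - flank_bp, reg$start, reg$end + trim_bp + 1)
  pend <- c(reg$start - trim_bp - 1, reg$end, reg$end + flank_bp)
  pname <- rep(c("flank_up", "body", "flank_down"), each = n)
  owner <- rep(seq_len(n), 3)
  plen <- rep(chrlen, 3)

  clip_lo <- pstart < 1
  if (any(clip_lo)) {
    warnf("event(s) %s: flank clipped at chromosome start",
          paste(unique(reg$name[owner[clip_lo]]), collapse = ", "))
    pstart[clip_lo] <- 1L
  }
  clip_hi <- !is.na(plen) & pend > plen
  if (any(clip_hi)) {
    warnf("event(s) %s: flank clipped at chromosome end",
          paste(unique(reg$name[owner[clip_hi]]), collapse = ", "))
    pend[clip_hi] <- plen[clip_hi]
  }
  keep <- pend >= pstart
  ## genomic order within each region: flank_up, body, flank_down
  ord <- order(owner[keep], pstart[keep])
  idx <- which(keep)[ord]

  gr <- GenomicRanges::GRanges(
    seqnames = reg$chrom[owner[idx]],
    ranges = IRanges::IRanges(start = pstart[idx], end = pend[idx]),
    strand = reg$strand[owner[idx]],
    piece = pname[idx]
  )
  grl <- GenomicRanges::split(gr, factor(reg$name[owner[idx]], levels = reg$name))
  S4Vectors::mcols(grl)$event_id <- reg$event_id
  grl
}

#' Extract binding-region sequences in transcript sense
#'
#' @param regions `GRangesList` from [buildBindingRegions()].
#' @param genome `DNAStringSet` named by chromosome.
#' @return a named `DNAStringSetList`, one element per region; each element
#'   holds the region's pieces ordered 5' to 3' in transcript sense
#'   (minus-strand regions are reverse-complemented and piece order
#'   reversed).
#' @export
regionSequences <- function(regions, genome) {
  stopifnot(is(genome, "DNAStringSet"))
  flat <- unlist(regions, use.names = FALSE)
  owner <- rep(seq_along(regions), lengths(regions))
  chrom <- as.character(GenomicRanges::seqnames(flat))
  seqs <- Biostrings::DNAStringSet(rep("", length(flat)))
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    seqs[j] <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(GenomicRanges::start(flat)[j],
                       GenomicRanges::end(flat)[j]))
  }
  names(seqs) <- S4Vectors::mcols(flat)$piece
  minus <- as.character(GenomicRanges::strand(flat)) == "-"
  if (any(minus)) {
    ## transcript sense: reverse-complement and reverse piece order
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    pos <- sequence(lengths(regions))
    ord <- order(owner, ifelse(minus, -pos, pos))
    seqs <- seqs[ord]
    owner <- owner[ord]
  }
  out <- S4Vectors::split(seqs, factor(owner, levels = seq_along(regions)))
  names(out) <- names(regions)
  out
}

#' Scan a motif over a binding region
#'
#' IUPAC mode reports every offset where the consensus matches under IUPAC
#' degeneracy (U and T equivalent); PFM mode reports offsets whose log-odds
#' score against a uniform background reaches `scoreThreshold` times the
#' maximum attainable score. Scanning is on the sense-strand sequence only,
#' piece by piece, so a match never spans the genomic gap between
#' non-adjacent pieces. A motif wider than the sequence yields zero hits.
#'
#' @param x region sequence: a character string, `DNAString`, or a
#'   `DNAStringSet` of pieces (as from [regionSequences()]).
#' @param motif an [RBPMotif-class].
#' @return integer vector of 1-based hit offsets in the concatenated
#'   piece sequence.
#' @examples
#' scanMotif("AAGGAGGAAA", iupacMotif("SRSF1", "m1", "GGAGGA"))  # 3
#' @export
scanMotif <- function(x, motif) {
  stopifnot(is(motif, "RBPMotif"))
  if (is.character(x) || is(x, "DNAString")) {
    x <- Biostrings::DNAStringSet(as.character(x))
  }
  offset <- 0L
  hits <- integer()
  for (j in seq_along(x)) {
    s <- x[[j]]
    h <- if (motif@kind == "iupac") scanIupac(s, motif) else scanPfm(s, motif)
    hits <- c(hits, h + offset)
    offset <- offset + length(s)
  }
  hits
}

scanIupac <- function(s, motif) {
  w <- nchar(motif@consensus)
  if (length(s) < w) return(integer())
  m <- Biostrings::matchPattern(motif@consensus, s, fixed = "subject")
  BiocGenerics::start(m)
}

scanPfm <- function(s, motif) {
  w <- ncol(motif@pfm)
  if (length(s) < w) return(integer())
  ## log-odds vs uniform background with 0.5 pseudocount per cell
  tot <- colSums(motif@pfm)
  lo <- log2(sweep(motif@pfm + 0.5, 2, tot + 2, "/") / 0.25)
  max_score <- sum(apply(lo, 2, max))
  thr <- motif@scoreThreshold * max_score
  chars <- strsplit(as.character(s), "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  n_pos <- length(chars) - w + 1L
  scores <- vapply(seq_len(n_pos), function(p) {
    ix <- idx[p:(p + w - 1L)]
    if (anyNA(ix)) return(-Inf)
    sum(lo[cbind(ix, seq_len(w))])
  }, numeric(1))
  which(scores >= thr)
}

#' Sample background events
#'
#' Uniform sample without replacement from the non-differential event ids,
#' used as the control arm of the enrichment test. Deterministic given the
#' seed.
#'
#' @param non_differential character vector of candidate event ids.
#' @param n_background how many to draw (default: supply the differential
#'   region count).
#' @param seed RNG seed.
#' @return character vector of sampled event ids.
#' @export
sampleBackground <- function(non_differential, n_background, seed = NULL) {
  if (n_background > length(non_differential)) {
    stopf(paste0("requested %d background events but only %d non-differential ",
                 "events are available; lower the background multiplier"),
          n_background, length(non_differential))
  }
  withSeed(seed, sample(non_differential, n_background))
}

## Vectorised region-level containment: one vcountPattern call over all
## pieces instead of one matchPattern call per piece.
regionsContainMotif <- function(seqs, motif) {
  if (is(seqs, "DNAStringSetList")) {
    idx <- rep(seq_along(seqs), lengths(seqs))
    flat <- unlist(seqs, use.names = FALSE)
    n_regions <- length(seqs)
  } else {
    pieces <- lapply(seqs, function(s) {
      if (is.character(s) || is(s, "DNAString")) {
        Biostrings::DNAStringSet(as.character(s))
      } else {
        s
      }
    })
    idx <- rep(seq_along(pieces), lengths(pieces))
    flat <- do.call(c, unname(pieces))
    n_regions <- length(pieces)
  }
  hit <- if (motif@kind == "iupac") {
    Biostrings::vcountPattern(motif@consensus, flat, fixed = "subject") > 0
  } else {
    vapply(seq_along(flat), function(i) length(scanPfm(flat[[i]], motif)) > 0,
           logical(1))
  }
  as.logical(tapply(hit, factor(idx, levels = seq_len(n_regions)), any))
}

#' One-sided Fisher exact P for 2x2 tables
#'
#' Upper-tail probability of the `a` cell under the hypergeometric null with
#' the table margins fixed — the one-sided ("greater") Fisher exact test
#' used by [enrichMotifs()]. Vectorised over tables.
#'
#' @param a,b,c,d the 2x2 cell counts: differential regions with / without
#'   the motif, background regions with / without.
#' @return P(X >= a) under the hypergeometric null.
#' @examples
#' fisherOneSided(10, 0, 0, 10)  # 1 / choose(20, 10)
#' @export
fisherOneSided <- function(a, b, c, d) {
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' RBP motif enrichment in differential binding regions
#'
#' For every motif, each region either contains the motif (>= 1 scan hit) or
#' not; the 2x2 table (differential vs background regions, with vs without
#' the motif) is tested with a one-sided Fisher's exact test (alternative:
#' differential regions enriched). Within each RBP only the motif with the
#' smallest P is kept (`selected`), and an RBP is `significant` iff its
#' selected P <= `alpha_enrich`.
#'
#' @param differential_seqs,background_seqs named lists of region piece
#'   `DNAStringSet`s (see [regionSequences()]), or character vectors of
#'   plain sequences.
#' @param motifs list of [RBPMotif-class] objects (unique (rbp, motif_id)).
#' @param alpha_enrich significance level (default 0.05).
#' @return `DataFrame` with one row per motif: `rbp`, `motif_id`, counts
#'   `a`,`b`,`c`,`d` (`a+b` = differential regions, `c+d` = background
#'   regions), `odds_ratio` (sample odds ratio, `(a*d)/(b*c)`), `p`
#'   (one-sided), `selected`, `significant`.
#' @export
enrichMotifs <- function(differential_seqs, background_seqs, motifs,
                         alpha_enrich = 0.05) {
  if (length(differential_seqs) == 0 || length(background_seqs) == 0) {
    stopf("both region sets must be non-empty")
  }
  if (length(motifs) == 0) stopf("need at least one motif")
  key <- vapply(motifs, function(m) paste(m@rbp, m@motifId, sep = "/"), "")
  if (anyDuplicated(key)) {
    stopf("duplicate (rbp, motif_id): %s", paste(key[duplicated(key)], collapse = ", "))
  }
  rows <- lapply(motifs, function(m) {
    a <- sum(regionsContainMotif(differential_seqs, m))
    b <- length(differential_seqs) - a
    cc <- sum(regionsContainMotif(background_seqs, m))
    d <- length(background_seqs) - cc
    p <- fisherOneSided(a, b, cc, d)
    S4Vectors::DataFrame(rbp = m@rbp, motif_id = m@motifId,
                         a = a, b = b, c = cc, d = d,
                         odds_ratio = (a * d) / (b * cc),
                         p = p)
  })
  res <- do.call(rbind, rows)
  res$selected <- FALSE
  for (r in unique(res$rbp)) {
    i <- which(res$rbp == r)
    best <- i[order(res$p[i], res$motif_id[i])[1]]
    res$selected[best] <- TRUE
  }
  res$significant <- res$selected & res$p <= alpha_enrich
  txInfo("RBP enrichment: %d motif(s), %d RBP(s), %d significant at P <= %g",
         nrow(res), length(unique(res$rbp)), sum(res$significant), alpha_enrich)
  res
}
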