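#' Pairwise percent identity against the pig sequence
#'
#' Identity is the number of matching aligned positions divided by the
#' ungapped pig sequence length, times 100 — so in `"align"` mode the
#' measure is asymmetric (the pig sequence is always the denominator), and
#' in `"prealigned"` mode (equal-length sequences compared position by
#' position) it is symmetric.
#'
#' `"align"` mode performs a global Needleman-Wunsch alignment with match
#' +1, mismatch -1, gap -2 (linear), breaking traceback ties
#' deterministically: diagonal, then up (gap in the other sequence), then
#' left.
#'
#' @param pig_seq,other_seq nucleotide strings (character, `DNAString`).
#' @param mode `"prealigned"` (default) or `"align"`.
#' @return list with `identity` (percent, 0-100), `matches`, and for
#'   `"align"` mode the alignment `score`.
#' @examples
#' pairwiseIdentity("ACGT", "ACGA")$identity  # 75
#' @export
pairwiseIdentity <- function(pig_seq, other_seq, mode = c("prealigned", "align")) {
  mode <- match.arg(mode)
  a <- toupper(as.character(pig_seq))
  b <- toupper(as.character(other_seq))
  if (nchar(a) == 0 || nchar(b) == 0) stopf("sequences must be non-empty")
  if (mode == "prealigned") {
    if (nchar(a) != nchar(b)) {
      stopf("prealigned mode needs equal-length sequences (%d vs %d)",
            nchar(a), nchar(b))
    }
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    matches <- sum(ca == cb)
    return(list(identity = matches / nchar(a) * 100, matches = matches,
                score = NA_real_))
  }
  nw <- needlemanWunsch(a, b)
  list(identity = nw$matches / nchar(a) * 100, matches = nw$matches,
       score = nw$score)
}

## Global alignment, match +1 / mismatch -1 / gap -2 (linear). Traceback
## prefers diagonal, then up (consume a), then left (consume b).
needlemanWunsch <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  sub <- outer(ca, cb, function(x, y) ifelse(x == y, match, mismatch))
  for (i in seq_len(n)) {
    diag_row <- S[i, 1:m] + sub[i, ]
    up_row <- S[i, 2:(m + 1)] + gap
    ## left-gap dependency forces a sequential pass within the row
    prev <- S[i + 1, 1]
    row <- numeric(m)
    for (j in seq_len(m)) {
      best <- max(diag_row[j], up_row[j], prev + gap)
      row[j] <- best
      prev <- best
    }
    S[i + 1, 2:(m + 1)] <- row
  }
  ## traceback with the fixed tie order
  i <- n; j <- m; matches <- 0L
  while (i > 0 && j > 0) {
    here <- S[i + 1, j + 1]
    if (here == S[i, j] + sub[i, j]) {
      if (ca[i] == cb[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (here == S[i, j + 1] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = S[n + 1, m + 1], matches = matches)
}

#' Gene conservation score
#'
#' Arithmetic mean of the per-species percent identities of a pig gene
#' against its orthologs in the seven reference mammals (human, mouse, blue
#' whale, dog, horse, sheep, cow). Missing species are excluded from the
#' mean with a warning.
#'
#' @param identities named numeric vector of percent identities (0-100).
#' @param gene_id optional gene id carried through to the result.
#' @return list with `gene_id`, `per_species_identity`, `gene_score`.
#' @examples
#' ids <- setNames(c(95, 90, 85, 80, 75, 70, 65),
#'                 c("human", "mouse", "blue_whale", "dog", "horse", "sheep", "cow"))
#' geneConservationScore(ids)$gene_score  # 80
#' @export
geneConservationScore <- function(identities, gene_id = NA_character_) {
  if (any(identities < 0 | identities > 100, na.rm = TRUE)) {
    stopf("identities must lie in [0, 100]")
  }
  miss <- setdiff(CONSERVATION_SPECIES, names(identities))
  ok <- !is.na(identities)
  if (length(miss) || any(!ok)) {
    warnf("species missing for gene %s: %s (score uses the remaining %d)",
          gene_id, paste(c(miss, names(identities)[!ok]), collapse = ", "),
          sum(ok))
  }
  list(gene_id = gene_id, per_species_identity = identities,
       gene_score = mean(identities[ok]))
}

#' Species tree from per-species conservation of one gene
#'
#' Single-linkage agglomerative clustering on the one-dimensional distance
#' `|identity_i - identity_j|`, rendered as a Newick string via `ape`.
#' Branch lengths are merge heights (each terminal branch is half the merge
#' distance, the ultrametric convention); label-order ties are broken
#' deterministically by sorting species names first.
#'
#' @param per_species_identity named numeric vector (>= 2 species).
#' @return Newick text with terminal semicolon; parses with any standard
#'   Newick reader.
#' @export
buildSpeciesTree <- function(per_species_identity) {
  x <- per_species_identity[order(names(per_species_identity))]
  if (length(x) < 2) stopf("need at least two species to build a tree")
  hc <- hclust(dist(x, method = "euclidean"), method = "single")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}

#' Conservation scores for a set of ortholog sequences
#'
#' Convenience wrapper: given one pig sequence and one ortholog per species,
#' computes per-species identity ([pairwiseIdentity()]) and the gene score
#' ([geneConservationScore()]).
#'
#' @param orthologs a `DNAStringSet` containing a `sus_scrofa` record plus
#'   one record per species.
#' @param mode passed to [pairwiseIdentity()]; `"prealigned"` requires all
#'   sequences to share the pig sequence's length.
#' @param gene_id carried through to the result.
#' @return as [geneConservationScore()], plus `newick` from
#'   [buildSpeciesTree()].
#' @export
conservationFromOrthologs <- function(orthologs, mode = c("prealigned", "align"),
                                      gene_id = NA_character_) {
  mode <- match.arg(mode)
  if (!"sus_scrofa" %in% names(orthologs)) {
    stopf("ortholog set must contain a 'sus_scrofa' record")
  }
  pig <- orthologs[["sus_scrofa"]]
  species <- setdiff(names(orthologs), "sus_scrofa")
  ids <- vapply(species, function(sp) {
    pairwiseIdentity(pig, orthologs[[sp]], mode = mode)$identity
  }, numeric(1))
  res <- geneConservationScore(ids, gene_id = gene_id)
  res$newick <- buildSpeciesTree(ids)
  res
}
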