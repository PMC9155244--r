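## Shared fixture builders. Everything is generated in code; no binary data.

## Small DoseExperiment with the given per-group count rows.
makeDex <- function(counts, lengths = NULL, n_rep = NULL) {
  if (is.null(n_rep)) n_rep <- ncol(counts) / 4
  dsn <- pipelineDesign(n_rep = n_rep)
  colnames(counts) <- dsn$sample_id
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  DoseExperiment(counts, lengths = setNames(lengths, rownames(counts)),
                 design = dsn)
}

## SpliceEventExperiment from inclusion/exclusion matrices (events x samples).
makeEvents <- function(inc, exc, type = NULL, strand = "+", n_rep = NULL) {
  if (is.null(n_rep)) n_rep <- ncol(inc) / 4
  dsn <- pipelineDesign(n_rep = n_rep)
  n <- nrow(inc)
  ids <- sprintf("ev%02d", seq_len(n))
  dimnames(inc) <- dimnames(exc) <- list(ids, dsn$sample_id)
  if (is.null(type)) type <- rep("SE", n)
  body <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = 1000 + (seq_len(n) - 1) * 2000, width = 100),
    strand = strand)
  names(body) <- ids
  SpliceEventExperiment(body, type, sprintf("sg%02d", seq_len(n)), inc, exc)
}

## A single-event experiment with an SE body at a chosen locus.
makeSingleEvent <- function(start, end, strand = "+", chrom = "chrS",
                            type = "SE", body2_start = NA, body2_end = NA) {
  dsn <- pipelineDesign(n_rep = 2)
  body <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start, end = end), strand = strand)
  names(body) <- "ev01"
  inc <- matrix(5L, 1, nrow(dsn), dimnames = list("ev01", dsn$sample_id))
  SpliceEventExperiment(body, type, "sg01", inc, inc,
                        body2_start = as.integer(body2_start),
                        body2_end = as.integer(body2_end))
}

## Random DNA string.
randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Independent one-sided hypergeometric tail by explicit enumeration with
## binomial coefficients (oracle; kept free of phyper/fisher.test).
enumFisherOneSided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- a:min(r1, c1)
  sum(exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)))
}

## Archetype group-mean shapes used in planted-profile tests (L0, L4, L8, N0).
archetypeShapes <- function(m0 = 100, eff = 50) {
  list(
    increased_dose_effect = c(m0, m0 + eff / 2, m0 + eff, m0 + eff),
    sensitive_dose = c(m0, m0 + eff, m0 + eff, m0 + eff),
    counter_effect = c(m0, m0 + eff / 2, m0 + eff, m0 - eff)
  )
}

## Per-sample matrix of planted archetype profiles plus replicate noise.
plantedProfileTpm <- function(n_per = 20, m0 = 100, eff = 50, noise_sd = 0.5 * eff,
                              design = pipelineDesign()) {
  shapes <- archetypeShapes(m0, eff)
  arch <- rep(names(shapes), each = n_per)
  genes <- sprintf("p%03d", seq_along(arch))
  grp_idx <- match(as.character(design$group), c("L0", "L4", "L8", "N0"))
  tpm <- t(vapply(seq_along(genes), function(i) {
    shapes[[arch[i]]][grp_idx] + rnorm(nrow(design), 0, noise_sd)
  }, numeric(nrow(design))))
  dimnames(tpm) <- list(genes, design$sample_id)
  list(tpm = tpm, archetype = setNames(arch, genes))
}
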