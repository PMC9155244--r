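test_that("SE binding region matches the 250/10 interval arithmetic", {
  ## exon [1000, 1100) zero-based = [1001, 1100] one-based
  genome <- Biostrings::DNAStringSet(setNames(randomDna(10000, seed = 1), "chrS"))
  ev <- makeSingleEvent(1001, 1100)
  reg <- buildBindingRegions(ev, genome)[[1]]
  expect_equal(GenomicRanges::start(reg), c(751, 1001, 1111))
  expect_equal(GenomicRanges::end(reg), c(990, 1100, 1350))
  expect_equal(sum(GenomicRanges::width(reg)), 580)
  expect_equal(S4Vectors::mcols(reg)$piece, c("flank_up", "body", "flank_down"))
  ## no scanned base lies within 10 bp of a splice junction on the intron side
  trimmed <- c(991:1000, 1101:1110)
  covered <- unlist(lapply(seq_along(reg), function(i) {
    GenomicRanges::start(reg)[i]:GenomicRanges::end(reg)[i]
  }))
  expect_length(intersect(trimmed, covered), 0)
})

test_that("degenerate flank/trim settings reduce to the exon body", {
  genome <- Biostrings::DNAStringSet(setNames(randomDna(5000, seed = 2), "chrS"))
  ev <- makeSingleEvent(2001, 2100)
  reg <- buildBindingRegions(ev, genome, flank_bp = 0, trim_bp = 0)[[1]]
  expect_length(reg, 1)
  expect_equal(GenomicRanges::start(reg), 2001)
  expect_equal(GenomicRanges::end(reg), 2100)
})

test_that("minus-strand sequences are reverse-complemented with reversed pieces", {
  genome <- Biostrings::DNAStringSet(setNames(randomDna(5000, seed = 3), "chrS"))
  plus <- makeSingleEvent(2001, 2100, strand = "+")
  minus <- makeSingleEvent(2001, 2100, strand = "-")
  sp <- regionSequences(buildBindingRegions(plus, genome), genome)[[1]]
  sm <- regionSequences(buildBindingRegions(minus, genome), genome)[[1]]
  ## same genomic intervals; minus concatenation is the reverse complement
  ## of the plus concatenation
  plus_cat <- paste(as.character(sp), collapse = "")
  minus_cat <- paste(as.character(sm), collapse = "")
  expect_identical(minus_cat,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(plus_cat))))
  expect_equal(names(sm), c("flank_down", "body", "flank_up"))
})

test_that("flanks clip at chromosome boundaries with a warning", {
  genome <- Biostrings::DNAStringSet(setNames(randomDna(1200, seed = 4), "chrS"))
  ev <- makeSingleEvent(100, 199)
  expect_warning(reg <- buildBindingRegions(ev, genome), "clipped")
  expect_gte(min(GenomicRanges::start(reg[[1]])), 1)
  ev2 <- makeSingleEvent(1000, 1099)
  expect_warning(reg2 <- buildBindingRegions(ev2, genome), "clipped")
  expect_lte(max(GenomicRanges::end(reg2[[1]])), 1200)
})

test_that("MXE events yield one region per exclusive exon", {
  genome <- Biostrings::DNAStringSet(setNames(randomDna(8000, seed = 5), "chrS"))
  ev <- makeSingleEvent(2001, 2100, type = "MXE", body2_start = 3001,
                        body2_end = 3080)
  regs <- buildBindingRegions(ev, genome)
  expect_length(regs, 2)
  expect_equal(names(regs), c("ev01#1", "ev01#2"))
  expect_equal(unique(S4Vectors::mcols(regs)$event_id), "ev01")
  expect_equal(GenomicRanges::start(regs[[2]])[2], 3001)
})

test_that("IUPAC scanning finds exact and degenerate matches piece-wise", {
  m <- iupacMotif("SRSF1", "m1", "GGAGGA")
  expect_equal(scanMotif("AAGGAGGAAA", m), 3)
  ## full degeneracy: every offset matches
  n4 <- iupacMotif("X", "n", "NNNN")
  expect_equal(scanMotif("ACGTACGTAC", n4), 1:7)
  ## U in motif matches T in sequence
  mu <- iupacMotif("PUM2", "m1", "UGUAAAUA")
  expect_equal(scanMotif("CCTGTAAATACC", mu), 3)
  ## motif wider than sequence: zero hits, no error
  expect_length(scanMotif("ACG", m), 0)
  ## matches never span the gap between pieces
  pieces <- Biostrings::DNAStringSet(c("AAAGGA", "GGAAAA"))
  expect_length(scanMotif(pieces, m), 0)
  whole <- Biostrings::DNAStringSet("AAAGGAGGAAAA")
  expect_equal(scanMotif(whole, m), 4)
})

test_that("PFM scanning at threshold 1 hits only the single best word", {
  pfm <- matrix(c(9, 0, 0, 0,   0, 9, 0, 0,   0, 0, 9, 0,   0, 0, 0, 9),
                4, 4)  # best word ACGT
  m <- pfmMotif("RBPX", "p1", pfm, score_threshold = 1)
  expect_equal(scanMotif("TTACGTTTACGA", m), 3)
  ## lower threshold admits the one-mismatch word ACGA (score ratio ~0.41)
  m2 <- pfmMotif("RBPX", "p1", pfm, score_threshold = 0.4)
  expect_equal(scanMotif("TTACGATTT", m2), 3)
  m3 <- pfmMotif("RBPX", "p1", pfm, score_threshold = 0.45)
  expect_length(scanMotif("TTACGATTT", m3), 0)
})

test_that("background sampling is seeded, bounded and varied", {
  cand <- sprintf("ev%03d", 1:100)
  s1 <- sampleBackground(cand, 5, seed = 7)
  s2 <- sampleBackground(cand, 5, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  expect_error(sampleBackground(cand[1:50], 100), "background")
  s3 <- sampleBackground(cand, 5, seed = 8)
  expect_false(identical(s1, s3))
})

test_that("Fisher enrichment matches closed forms and selects min-P per RBP", {
  ## a=10,b=0,c=0,d=10 -> p = 1/choose(20,10)
  expect_equal(fisherOneSided(10, 0, 0, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
  ## balanced table is not significant
  expect_gt(fisherOneSided(5, 5, 5, 5), 0.5)

  ## region-level containment and min-P selection
  diff_seqs <- c(replicate(10, paste0(randomDna(20), "GGAGGA", randomDna(20))))
  bg_seqs <- replicate(10, gsub("GGAGGA", "ACACAC",
                                paste0(randomDna(20), "TTTTTT", randomDna(20))))
  motifs <- list(iupacMotif("SRSF1", "m1", "GGAGGA"),
                 iupacMotif("SRSF1", "m2", "GGAGGAGG"),
                 iupacMotif("PUM2", "m1", "TGTAAATA"))
  res <- enrichMotifs(as.list(diff_seqs), as.list(bg_seqs), motifs)
  df <- as.data.frame(res)
  srsf1 <- df[df$rbp == "SRSF1", ]
  expect_equal(sum(srsf1$selected), 1)
  expect_equal(srsf1$motif_id[srsf1$selected],
               srsf1$motif_id[which.min(srsf1$p)])
  best <- df[df$rbp == "SRSF1" & df$selected, ]
  expect_equal(best$a, 10)
  expect_equal(best$c, 0)
  expect_equal(best$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_true(best$significant)
  ## duplicate (rbp, motif) pairs are rejected
  expect_error(enrichMotifs(as.list(diff_seqs), as.list(bg_seqs),
                            motifs[c(1, 1)]), "duplicate")
  expect_error(enrichMotifs(list(), as.list(bg_seqs), motifs), "non-empty")
})

test_that("one-sided P agrees with stats::fisher.test on random tables", {
  set.seed(12)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2, 2)
    p_pkg <- fisherOneSided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    p_ft <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p_pkg, p_ft, tolerance = 1e-12)
  }
})
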