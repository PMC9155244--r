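#' Simulate the dose-series count matrix with planted truth
#'
#' Draws negative-binomial read counts (`Var = mu + phi * mu^2`) for the
#' 4-group x n-replicate design, with per-sample library sizes log-normal
#' (sigma 0.2) around 20 million reads. A subset of genes is planted with
#' one of three dose-response archetypes describing how the group mean moves
#' between the L0 level `m0` and the N0 level `m1`:
#' \describe{
#'   \item{increased_dose_effect}{linear movement toward N0 with dose:
#'     `(m0, m0 + g/2, m0 + g, m1)` with `g = m1 - m0`.}
#'   \item{sensitive_dose}{jumps to the N0 level at the 0.4% dose already:
#'     `(m0, m1, m1, m1)`.}
#'   \item{counter_effect}{moves away from the N0 level with dose:
#'     `(m0, m0 + d/2, m0 + d, m1)` with `d = m0 - m1 > 0` (N0 below L0 so
#'     all means stay positive).}
#' }
#' Null genes share one mean across all groups. Archetype genes differ
#' between L0 and N0 by `effect_fold` and are therefore the planted DEG set.
#' All genes of one archetype and direction share an affinely equivalent
#' trajectory, so each correlates perfectly with the others at the
#' group-mean level; the first increased-dose-effect gene is designated the
#' planted hub.
#'
#' @param design sample design ([pipelineDesign()]).
#' @param n_genes total genes (>= 50).
#' @param phi NB dispersion (>= 0; 0 gives the Poisson limit).
#' @param base_mean_range range of baseline expected counts, sampled
#'   log-uniformly.
#' @param effect_fold N0-over-L0 fold change planted in archetype genes.
#' @param n_per_archetype archetype genes per category (default 20).
#' @param lib_size_mean,lib_size_sdlog library-size log-normal parameters.
#' @param gene_length_range range of simulated union-exon gene lengths (bp).
#' @param seed RNG seed.
#' @return list with `experiment` (a [DoseExperiment-class]), `exons`
#'   (a `GRangesList` of two-exon gene models matching the effective
#'   lengths) and `truth` (planted group means, DEG set, archetype map,
#'   hub gene, fold change).
#' @export
simulateCounts <- function(design = pipelineDesign(), n_genes = 2000,
                           phi = 0.1, base_mean_range = c(20, 2000),
                           effect_fold = 3, n_per_archetype = 20,
                           lib_size_mean = 2e7, lib_size_sdlog = 0.2,
                           gene_length_range = c(500, 5000), seed = NULL) {
  checkDesign(design)
  if (n_genes < 50) stopf("n_genes must be >= 50 (got %d)", n_genes)
  if (phi < 0) stopf("dispersion phi must be >= 0")
  if (effect_fold <= 0) stopf("effect_fold must be > 0")
  if (3 * n_per_archetype > n_genes) stopf("too many archetype genes for n_genes")
  withSeed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    m0 <- 10^runif(n_genes, log10(base_mean_range[1]), log10(base_mean_range[2]))
    archetype <- setNames(rep("null", n_genes), genes)
    planted <- sample(genes, 3 * n_per_archetype)
    archetype[planted] <- rep(PROFILE_CATEGORIES, each = n_per_archetype)
    ## direction of the N0 shift; counter-effect genes always shift N0 down
    ## so the away-from-N0 trajectory keeps positive means
    dir_up <- setNames(rep(NA, n_genes), genes)
    for (cat in c("increased_dose_effect", "sensitive_dose")) {
      idx <- which(archetype == cat)
      dir_up[idx] <- rep(c(TRUE, FALSE), length.out = length(idx))
    }
    dir_up[archetype == "counter_effect"] <- FALSE

    mu <- matrix(rep(m0, length(GROUP_LEVELS)), n_genes, length(GROUP_LEVELS),
                 dimnames = list(genes, GROUP_LEVELS))
    for (i in which(archetype != "null")) {
      f <- if (dir_up[i]) effect_fold else 1 / effect_fold
      m1 <- m0[i] * f
      g <- m1 - m0[i]
      mu[i, ] <- switch(archetype[i],
        increased_dose_effect = c(m0[i], m0[i] + g / 2, m0[i] + g, m1),
        sensitive_dose = c(m0[i], m1, m1, m1),
        counter_effect = c(m0[i], m0[i] - g / 2, m0[i] - g, m1)
      )
    }
    if (any(mu <= 0)) {
      stopf("planted effect drives a group mean non-positive (fold %g)", effect_fold)
    }
    hub_gene <- genes[which(archetype == "increased_dose_effect")[1]]

    lib <- stats::rlnorm(nrow(design), log(lib_size_mean), lib_size_sdlog)
    grp <- as.character(design$group)
    counts <- matrix(0L, n_genes, nrow(design),
                     dimnames = list(genes, design$sample_id))
    for (s in seq_len(nrow(design))) {
      mus <- mu[, grp[s]] * lib[s] / lib_size_mean
      counts[, s] <- if (phi == 0) {
        stats::rpois(n_genes, mus)
      } else {
        rnbinom(n_genes, mu = mus, size = 1 / phi)
      }
    }
    lens <- round(runif(n_genes, gene_length_range[1], gene_length_range[2]))
    exons <- simulateGeneModels(genes, lens)
    dex <- DoseExperiment(counts, lengths = setNames(lens, genes), design = design)
    truth <- list(
      group_means = mu,
      deg_genes = genes[archetype != "null"],
      profile_archetype = archetype,
      direction_up_in_N0 = dir_up,
      hub_gene = hub_gene,
      effect_fold = effect_fold,
      library_sizes = setNames(lib, design$sample_id)
    )
    txInfo("simulated counts: %d genes x %d samples (%d archetype genes, hub %s)",
           n_genes, nrow(design), sum(archetype != "null"), hub_gene)
    list(experiment = dex, exons = exons, truth = truth)
  })
}

## Two-exon gene models laid head-to-tail on a synthetic chromosome, with
## union-exon length equal to the requested effective length.
simulateGeneModels <- function(genes, lens, chrom = "chrE", gap = 1000L) {
  l1 <- pmax(1L, lens %/% 2L)
  l2 <- lens - l1
  span <- l1 + 200L + pmax(l2, 1L) + gap
  gstart <- cumsum(c(1L, span[-length(span)]))
  two <- l2 > 0
  starts <- c(gstart, gstart[two] + l1[two] + 200L)
  widths <- c(l1, l2[two])
  owner <- c(genes, genes[two])
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts, width = widths),
    strand = "+"
  )
  GenomicRanges::split(gr, factor(owner, levels = genes))
}

#' Simulate splicing events with binomial junction counts
#'
#' Inclusion counts are drawn `Binomial(coverage, PSI_group)` per sample,
#' exclusion counts are `coverage - inclusion`. `n_diff` events receive a
#' group-specific PSI (the control group L0 keeps the base PSI, all other
#' groups are shifted by `dpsi` in whichever direction stays inside
#' \[0, 1\]); the remaining events share one PSI across groups. Event bodies
#' are laid out on a synthetic chromosome `chrS`, one 2 kb slot per event,
#' with random strand and event types drawn with skipped exons predominant.
#'
#' @param design sample design.
#' @param n_events number of events.
#' @param coverage junction-read coverage per event and sample (>= 10).
#' @param n_diff number of planted differential events.
#' @param dpsi planted PSI shift for differential events.
#' @param type_probs sampling weights over SE/A5SS/A3SS/MXE/RI.
#' @param seed RNG seed.
#' @return list with `events` (a [SpliceEventExperiment-class]) and `truth`
#'   (differential ids and the true per-group PSI matrix).
#' @export
simulateEvents <- function(design = pipelineDesign(), n_events = 200,
                           coverage = 50, n_diff = 30, dpsi = 0.3,
                           type_probs = c(SE = 0.6, A5SS = 0.1, A3SS = 0.1,
                                          MXE = 0.1, RI = 0.1),
                           seed = NULL) {
  checkDesign(design)
  if (coverage < 10) stopf("coverage must be >= 10 (got %g)", coverage)
  if (n_diff > n_events) stopf("n_diff cannot exceed n_events")
  if (dpsi < 0 || dpsi > 1) stopf("dpsi must lie in [0, 1]")
  withSeed(seed, {
    ids <- sprintf("ev%04d", seq_len(n_events))
    type <- sample(EVENT_TYPES, n_events, replace = TRUE,
                   prob = type_probs[EVENT_TYPES])
    strand <- sample(c("+", "-"), n_events, replace = TRUE)
    slot <- 2000L
    body_len <- sample(60:150, n_events, replace = TRUE)
    body_start <- 1000L + (seq_len(n_events) - 1L) * slot
    body <- GenomicRanges::GRanges(
      seqnames = "chrS",
      ranges = IRanges::IRanges(start = body_start, width = body_len),
      strand = strand
    )
    names(body) <- ids
    b2 <- rep(NA_integer_, n_events)
    b2e <- rep(NA_integer_, n_events)
    mxe <- type == "MXE"
    b2[mxe] <- body_start[mxe] + body_len[mxe] + 300L
    b2e[mxe] <- b2[mxe] + sample(60:150, sum(mxe), replace = TRUE) - 1L

    base_psi <- runif(n_events, 0.2, 0.8)
    diff_ids <- sort(sample(ids, n_diff))
    psi <- matrix(rep(base_psi, length(GROUP_LEVELS)), n_events,
                  length(GROUP_LEVELS), dimnames = list(ids, GROUP_LEVELS))
    for (id in diff_ids) {
      i <- match(id, ids)
      shift <- if (base_psi[i] + dpsi <= 1) dpsi else -dpsi
      psi[i, setdiff(GROUP_LEVELS, "L0")] <- base_psi[i] + shift
    }
    grp <- as.character(design$group)
    inc <- matrix(0L, n_events, nrow(design), dimnames = list(ids, design$sample_id))
    for (s in seq_len(nrow(design))) {
      inc[, s] <- rbinom(n_events, coverage, psi[, grp[s]])
    }
    exc <- coverage - inc
    ses <- SpliceEventExperiment(body, type, sprintf("sg%04d", seq_len(n_events)),
                                 inc, exc, body2_start = b2, body2_end = b2e)
    txInfo("simulated %d events (%d differential, coverage %d)", n_events,
           n_diff, coverage)
    list(events = ses, truth = list(diff_events = diff_ids, psi = psi,
                                    coverage = coverage, dpsi = dpsi))
  })
}

## Draw one concrete word compatible with an IUPAC consensus.
IUPAC_EXPAND <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

sampleIupacWord <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_EXPAND[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, ""), collapse = "")
}

#' Simulate a genome with motifs planted in binding regions
#'
#' Generates an i.i.d. uniform background sequence covering all event
#' coordinates, then writes a word matching the motif consensus at a random
#' position inside the exon body of each differential event with probability
#' `p_diff`, and of each non-differential event with probability `p_bg`.
#' The body lies wholly inside the binding region, so plants never touch the
#' `trim_bp` splice-site exclusion zones. For minus-strand events the
#' reverse complement is written so the transcript-sense scan sees the
#' consensus.
#'
#' @param events a [SpliceEventExperiment-class] with bodies on one
#'   chromosome.
#' @param motif an IUPAC [RBPMotif-class] to plant.
#' @param diff_ids ids of the differential events.
#' @param p_diff,p_bg plant probabilities in differential / background
#'   event bodies.
#' @param seed RNG seed.
#' @return list with `genome` (a `DNAStringSet`) and `truth` (planted event
#'   ids and positions).
#' @export
simulateGenomeWithMotifs <- function(events, motif, diff_ids, p_diff = 0.8,
                                     p_bg = 0.1, seed = NULL) {
  stopifnot(is(events, "SpliceEventExperiment"), is(motif, "RBPMotif"))
  if (motif@kind != "iupac") stopf("motif planting requires an IUPAC consensus motif")
  if (p_diff < 0 || p_diff > 1 || p_bg < 0 || p_bg > 1) {
    stopf("plant probabilities must lie in [0, 1]")
  }
  body <- eventBody(events)
  chrom <- unique(as.character(GenomicRanges::seqnames(body)))
  if (length(chrom) != 1) stopf("all events must lie on one chromosome")
  rd <- SummarizedExperiment::rowData(events)
  glen <- max(GenomicRanges::end(body), rd$body2_end, na.rm = TRUE) + 500L
  withSeed(seed, {
    bases <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    w <- motifWidth(motif)
    planted <- character()
    positions <- integer()
    for (i in seq_len(nrow(events))) {
      id <- rownames(events)[i]
      p <- if (id %in% diff_ids) p_diff else p_bg
      if (runif(1) >= p) next
      s <- GenomicRanges::start(body)[i]
      e <- GenomicRanges::end(body)[i]
      if (e - s + 1 < w) next
      pos <- sample(s:(e - w + 1L), 1)
      word <- sampleIupacWord(motif@consensus)
      if (as.character(GenomicRanges::strand(body))[i] == "-") {
        word <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(word)))
      }
      bases[pos:(pos + w - 1L)] <- strsplit(word, "")[[1]]
      planted <- c(planted, id)
      positions <- c(positions, pos)
    }
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- chrom
    txInfo("simulated genome %s (%d bp), motif %s planted in %d event bodies",
           chrom, glen, motif@motifId, length(planted))
    list(genome = genome,
         truth = list(planted_events = planted, positions = positions,
                      p_diff = p_diff, p_bg = p_bg, motif_id = motif@motifId))
  })
}

#' Simulate the plasma-triglyceride trait
#'
#' Per-sample postprandial plasma TG (mg/dL) linearly coupled to the planted
#' hub gene's expression: `TG = intercept + slope * TPM + N(0, noise_sd)`.
#' The default negative slope mirrors expression rising as TG falls.
#'
#' @param design sample design.
#' @param hub_tpm named per-sample TPM of the hub gene.
#' @param intercept,slope,noise_sd linear-model parameters (mg/dL units).
#' @param seed RNG seed.
#' @return data.frame `sample_id`, `tg_mg_dl`.
#' @export
simulateTrait <- function(design, hub_tpm, intercept = 120, slope = -0.3,
                          noise_sd = 5, seed = NULL) {
  checkDesign(design)
  if (!all(design$sample_id %in% names(hub_tpm))) {
    stopf("hub_tpm must be named by every design sample")
  }
  withSeed(seed, {
    tg <- intercept + slope * unname(hub_tpm[design$sample_id]) +
      rnorm(nrow(design), 0, noise_sd)
    data.frame(sample_id = design$sample_id, tg_mg_dl = tg,
               stringsAsFactors = FALSE)
  })
}

#' Simulate ortholog sequences at controlled identity
#'
#' Copies the pig sequence for each species and mutates a `(1 - identity)`
#' fraction of positions to a different base (no indels by default), so the
#' realised prealigned identity equals the planted fraction up to rounding.
#' With `indels = TRUE` a small number of single-base insertions/deletions
#' are added, exercising the alignment path of the conservation module.
#'
#' @param pig_seq pig sequence (character/`DNAString`) or NULL to draw a
#'   random one of length `pig_length`.
#' @param pig_length length of the random pig sequence.
#' @param species_identities named identity fractions in \[0, 1\] (defaults
#'   to the seven reference mammals at 0.95 down to 0.65).
#' @param indels add indels (default FALSE).
#' @param seed RNG seed.
#' @return list with `sequences` (a `DNAStringSet`: `sus_scrofa` plus one
#'   record per species) and `truth` (the planted identities).
#' @export
simulateOrthologs <- function(pig_seq = NULL, pig_length = 1000,
                              species_identities = setNames(
                                c(0.95, 0.90, 0.85, 0.80, 0.75, 0.70, 0.65),
                                CONSERVATION_SPECIES),
                              indels = FALSE, seed = NULL) {
  if (any(species_identities < 0 | species_identities > 1)) {
    stopf("species identities must lie in [0, 1]")
  }
  withSeed(seed, {
    if (is.null(pig_seq)) {
      pig_seq <- paste(sample(c("A", "C", "G", "T"), pig_length, replace = TRUE),
                       collapse = "")
    }
    pig_seq <- toupper(as.character(pig_seq))
    n <- nchar(pig_seq)
    seqs <- c(sus_scrofa = pig_seq)
    for (sp in names(species_identities)) {
      chars <- strsplit(pig_seq, "")[[1]]
      k <- round((1 - species_identities[[sp]]) * n)
      if (k > 0) {
        pos <- sample(n, k)
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
      }
      if (indels) {
        n_ind <- max(1L, round(n / 500))
        for (z in seq_len(n_ind)) {
          at <- sample(length(chars), 1)
          if (runif(1) < 0.5) {
            chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = at)
          } else {
            chars <- chars[-at]
          }
        }
      }
      seqs[[sp]] <- paste(chars, collapse = "")
    }
    out <- Biostrings::DNAStringSet(seqs)
    list(sequences = out,
         truth = list(species_identities = species_identities, indels = indels))
  })
}

#' Simulate every pipeline input and write it to disk
#'
#' Generates the full synthetic dataset — counts, design, gene models,
#' splicing events, genome with planted motifs, motif file, trait table and
#' ortholog FASTAs — together with `truth.json` recording all planted
#' ground truth. Every file format round-trips through the package readers.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipelineConfig()]; its `seed` drives all randomness.
#' @param n_genes,n_events,coverage,n_diff,effect_fold,n_per_archetype,phi
#'   passed to the generators.
#' @param planted_motif IUPAC motif planted in differential event bodies.
#' @param decoy_motifs additional motifs written to the motif file but not
#'   planted.
#' @param p_diff,p_bg motif plant rates.
#' @return (invisibly) a list of the in-memory objects and the truth record.
#' @export
simulateAll <- function(out_dir, config = pipelineConfig(), n_genes = 2000,
                        n_events = 200, coverage = 50, n_diff = 30,
                        effect_fold = 3, n_per_archetype = 20, phi = 0.1,
                        planted_motif = iupacMotif("SRSF1", "m1", "GGAGGA"),
                        decoy_motifs = list(
                          iupacMotif("PUM2", "m1", "TGTANATA"),
                          iupacMotif("PCBP3", "m1", "CCTTCCTT")),
                        p_diff = 0.8, p_bg = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  design <- pipelineDesign()
  sim_c <- simulateCounts(design, n_genes = n_genes, phi = phi,
                          effect_fold = effect_fold,
                          n_per_archetype = n_per_archetype,
                          seed = childSeed(seed, 1))
  sim_e <- simulateEvents(design, n_events = n_events, coverage = coverage,
                          n_diff = n_diff, seed = childSeed(seed, 2))
  sim_g <- simulateGenomeWithMotifs(sim_e$events, planted_motif,
                                    sim_e$truth$diff_events,
                                    p_diff = p_diff, p_bg = p_bg,
                                    seed = childSeed(seed, 3))
  tpm <- computeTpm(sim_c$experiment)
  trait <- simulateTrait(design, tpm[sim_c$truth$hub_gene, ],
                         seed = childSeed(seed, 4))
  sim_o <- simulateOrthologs(seed = childSeed(seed, 5))

  writeCountMatrix(sim_c$experiment, file.path(out_dir, "counts.tsv"))
  writeCanonicalTsv(design, file.path(out_dir, "design.tsv"))
  writeGtfGeneModels(sim_c$exons, file.path(out_dir, "genes.gtf"))
  writeEventCounts(sim_e$events, file.path(out_dir, "events.tsv"))
  Biostrings::writeXStringSet(sim_g$genome, file.path(out_dir, "genome.fa"))
  writeMotifs(c(list(planted_motif), decoy_motifs),
              file.path(out_dir, "motifs.txt"))
  writeTraitTable(trait, file.path(out_dir, "trait.tsv"))
  orth_dir <- file.path(out_dir, "orthologs")
  dir.create(orth_dir, showWarnings = FALSE)
  for (nm in names(sim_o$sequences)) {
    Biostrings::writeXStringSet(sim_o$sequences[nm],
                                file.path(orth_dir, paste0(nm, ".fa")))
  }
  truth <- list(
    seed = seed,
    deg_genes = sim_c$truth$deg_genes,
    profile_archetype = as.list(sim_c$truth$profile_archetype[
      sim_c$truth$profile_archetype != "null"]),
    hub_gene = sim_c$truth$hub_gene,
    effect_fold = effect_fold,
    diff_events = sim_e$truth$diff_events,
    planted_motif = list(rbp = planted_motif@rbp, motif_id = planted_motif@motifId,
                         p_diff = p_diff, p_bg = p_bg),
    species_identities = as.list(sim_o$truth$species_identities)
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txInfo("synthetic dataset written to %s", out_dir)
  invisible(list(counts = sim_c, events = sim_e, genome = sim_g,
                 trait = trait, orthologs = sim_o, truth = truth))
}
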