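#' Run the full pipeline end to end
#'
#' Simulates the default synthetic dataset (unless `data_dir` points at an
#' existing one), then runs every stage in order — TPM normalisation,
#' low-expression filtering, L0-vs-N0 / L0-vs-L4 / L0-vs-L8 differential
#' expression, dose-profile clustering and classification of the L0-vs-N0
#' DEG set, co-expression network with hub detection and trait correlation,
#' differential splicing per comparison with event-type tallies, binding
#' -region construction with RBP motif enrichment, and ortholog conservation
#' scoring with the species tree — writing one canonical TSV (or FASTA /
#' Newick / JSON) per stage under `out_dir`. All randomness flows from
#' `config$seed`, so two runs with the same configuration are
#' byte-identical.
#'
#' @param out_dir output directory.
#' @param config a [pipelineConfig()].
#' @param n_genes,n_events synthetic dataset size.
#' @param data_dir optional directory holding a dataset previously written
#'   by [simulateAll()]; when NULL the dataset is simulated into
#'   `file.path(out_dir, "data")`.
#' @return (invisibly) a named list of stage results.
#' @export
runAll <- function(out_dir, config = pipelineConfig(), n_genes = 2000,
                   n_events = 200, data_dir = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data_dir)) {
    data_dir <- file.path(out_dir, "data")
    sim <- simulateAll(data_dir, config = config, n_genes = n_genes,
                       n_events = n_events)
  }
  design <- readCanonicalTsv(file.path(data_dir, "design.tsv"))
  design$group <- factor(design$group, levels = GROUP_LEVELS)
  models <- readGtfGeneModels(file.path(data_dir, "genes.gtf"))
  dex <- readCountMatrix(file.path(data_dir, "counts.tsv"),
                         lengths = models$lengths, design = design)
  genome <- Biostrings::readDNAStringSet(file.path(data_dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  events <- readEventCounts(file.path(data_dir, "events.tsv"), design = design)
  motifs <- readMotifs(file.path(data_dir, "motifs.txt"))
  trait <- readTraitTable(file.path(data_dir, "trait.tsv"))

  ## expression
  tpm <- computeTpm(dex)
  keep <- filterLowExpressed(dex)
  deg <- list()
  for (g in c("N0", "L4", "L8")) {
    deg[[g]] <- differentialExpression(dex[keep, ], groupA = "L0", groupB = g,
                                       fdr_deg = config$fdr_deg)
    writeCanonicalTsv(as.data.frame(deg[[g]]),
                      file.path(out_dir, sprintf("deg_L0_vs_%s.tsv", g)))
  }
  base_means <- groupBaseMeans(tpm, design)
  writeCanonicalTsv(
    data.frame(gene_id = rownames(base_means), base_means, check.names = FALSE),
    file.path(out_dir, "base_means.tsv"))

  ## dose profiles over the L0-vs-N0 DEG set
  deg_n0 <- deg$N0$gene_id[deg$N0$is_deg]
  profiles <- NULL
  if (length(deg_n0) >= config$n_clusters) {
    centred <- centerProfiles(base_means, deg_n0)
    clustering <- clusterProfiles(centred, k = config$n_clusters,
                                  minkowski_order = config$minkowski_order)
    classes <- classifyProfiles(clustering, centred,
                                gamma = config$gamma_sensitive)
    profiles <- list(centred = centred, clustering = clustering,
                     classes = classes)
    writeCanonicalTsv(
      data.frame(gene_id = names(clustering$cluster),
                 cluster = unname(clustering$cluster),
                 category = unname(classes$gene_category)),
      file.path(out_dir, "profiles.tsv"))
    writeCanonicalTsv(
      data.frame(cluster = rownames(clustering$centroids),
                 clustering$centroids,
                 category = unname(classes$cluster_category),
                 check.names = FALSE),
      file.path(out_dir, "profile_centroids.tsv"))
  } else {
    warnf("fewer than %d L0-vs-N0 DEG (%d); skipping profile clustering",
          config$n_clusters, length(deg_n0))
  }

  ## co-expression network + trait correlation
  network <- NULL
  trait_cor <- NULL
  if (length(deg_n0) >= 2) {
    dir_vec <- setNames(ifelse(deg$N0$log2fc > 0, "up", "down"), deg$N0$gene_id)
    network <- correlationNetwork(base_means, deg_n0,
                                  r_threshold = config$r_threshold,
                                  direction = dir_vec)
    network <- detectHubs(network, hub_degree_min = config$hub_degree_min,
                          hub_top_frac = config$hub_top_frac)
    writeCanonicalTsv(as.data.frame(networkEdges(network)),
                      file.path(out_dir, "network_edges.tsv"))
    writeCanonicalTsv(as.data.frame(networkNodes(network)),
                      file.path(out_dir, "network_nodes.tsv"))
    trait_cor <- traitCorrelation(base_means, trait, design, deg_n0)
    writeCanonicalTsv(as.data.frame(trait_cor),
                      file.path(out_dir, "trait_correlation.tsv"))
  }

  ## differential splicing + tallies
  splice <- list()
  tallies <- list()
  for (g in c("L4", "L8", "N0")) {
    splice[[g]] <- differentialEvents(events, design, control = "L0",
                                      comparison = g,
                                      fdr_splice = config$fdr_splice,
                                      dpsi_min = config$dpsi_min)
    tallies[[g]] <- tallyEventTypes(splice[[g]])
    writeCanonicalTsv(as.data.frame(splice[[g]]),
                      file.path(out_dir, sprintf("splicing_L0_vs_%s.tsv", g)))
  }
  tally_df <- data.frame(comparison = names(tallies),
                         do.call(rbind, tallies), check.names = FALSE)
  writeCanonicalTsv(tally_df, file.path(out_dir, "splicing_tallies.tsv"))

  ## RBP enrichment: differential events (union over comparisons) vs sampled
  ## non-differential background
  diff_ids <- sort(unique(unlist(lapply(splice, function(s) {
    s$event_id[s$is_differential]
  }))))
  enrichment <- NULL
  if (length(diff_ids) >= 2) {
    non_diff <- setdiff(rownames(events), diff_ids)
    diff_regions <- buildBindingRegions(events, genome, which = diff_ids,
                                        flank_bp = config$flank_bp,
                                        trim_bp = config$trim_bp)
    bg_ids <- sampleBackground(sort(non_diff),
                               min(length(non_diff), length(diff_regions)),
                               seed = childSeed(config$seed, 6))
    bg_regions <- buildBindingRegions(events, genome, which = sort(bg_ids),
                                      flank_bp = config$flank_bp,
                                      trim_bp = config$trim_bp)
    enrichment <- enrichMotifs(regionSequences(diff_regions, genome),
                               regionSequences(bg_regions, genome),
                               motifs, alpha_enrich = config$alpha_enrich)
    writeCanonicalTsv(as.data.frame(enrichment),
                      file.path(out_dir, "rbp_enrichment.tsv"))
  } else {
    warnf("fewer than 2 differential events; skipping RBP enrichment")
  }

  ## conservation of the planted orthologs
  orth_dir <- file.path(data_dir, "orthologs")
  orth_files <- list.files(orth_dir, pattern = "\\.fa$", full.names = TRUE)
  orth <- do.call(c, lapply(orth_files, Biostrings::readDNAStringSet))
  names(orth) <- sub("\\s.*$", "", names(orth))
  conservation <- conservationFromOrthologs(orth, mode = "prealigned",
                                            gene_id = "hub")
  writeCanonicalTsv(
    data.frame(species = names(conservation$per_species_identity),
               identity_pct = unname(conservation$per_species_identity)),
    file.path(out_dir, "conservation.tsv"))
  writeLines(c(sprintf("gene_score\t%s", conservation$gene_score)),
             file.path(out_dir, "conservation_score.tsv"))
  writeLines(conservation$newick, file.path(out_dir, "species_tree.nwk"))

  txInfo("pipeline complete: results under %s", out_dir)
  invisible(list(tpm = tpm, retained = keep, deg = deg,
                 base_means = base_means, profiles = profiles,
                 network = network, trait_correlation = trait_cor,
                 splicing = splice, tallies = tallies,
                 enrichment = enrichment, conservation = conservation))
}
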