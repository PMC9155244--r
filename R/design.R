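#' Sample design for the dose series
#'
#' Builds the standard design: low-birth-weight piglets at 0%, 0.4% and 0.8%
#' dietary tryptophan (groups L0, L4, L8) plus the normal-birth-weight
#' reference N0, with `n_rep` biological replicates per group (six in the
#' study design).
#'
#' @param n_rep replicates per group (>= 2 for any statistical operation).
#' @return `data.frame` with columns `sample_id`, `group` (ordered factor
#'   L0 < L4 < L8 < N0 in level order), `dose_pct` (percent tryptophan in the
#'   diet; N0 carries 0 plus `is_reference = TRUE`), `replicate`.
#' @examples
#' head(pipelineDesign())
#' @export
pipelineDesign <- function(n_rep = 6) {
  if (n_rep < 2) stopf("every group needs at least 2 replicates (got %d)", n_rep)
  grp <- rep(GROUP_LEVELS, each = n_rep)
  rep_i <- rep(seq_len(n_rep), times = length(GROUP_LEVELS))
  data.frame(
    sample_id = sprintf("%s_r%d", grp, rep_i),
    group = factor(grp, levels = GROUP_LEVELS),
    dose_pct = unname(GROUP_DOSES[grp]),
    is_reference = grp == "N0",
    replicate = rep_i,
    stringsAsFactors = FALSE
  )
}

checkDesign <- function(design) {
  if (is.null(design) || nrow(design) == 0) stopf("empty sample design")
  need <- c("sample_id", "group")
  miss <- setdiff(need, colnames(design))
  if (length(miss)) stopf("design missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stopf("duplicate sample ids in design")
  bad <- setdiff(as.character(design$group), GROUP_LEVELS)
  if (length(bad)) stopf("unknown group label(s): %s", paste(unique(bad), collapse = ", "))
  invisible(design)
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the defaults used
#' throughout: DEG and splicing FDR cut 0.1, minimum |delta PSI| 0.05,
#' co-expression |r| threshold 0.9 with hub highlighting above degree 15 and
#' a top-20% hub fraction, six profile clusters under Minkowski order-2
#' (Euclidean) distance, 250 bp binding-region flanks with 10 bp splice-site
#' exclusion zones, and enrichment alpha 0.05.
#'
#' @param fdr_deg FDR threshold below which a gene is differentially expressed.
#' @param fdr_splice FDR threshold for differential splicing events.
#' @param dpsi_min minimum absolute difference in percent-spliced-in.
#' @param r_threshold Pearson correlation magnitude required for a network
#'   edge (strict inequality).
#' @param hub_degree_min nodes with degree strictly above this are highlighted.
#' @param hub_top_frac fraction of nodes (by degree rank) called hubs.
#' @param n_clusters number of profile clusters cut from the dendrogram.
#' @param minkowski_order order `p` of the Minkowski profile distance.
#' @param gamma_sensitive gap-closure fraction at the 0.4% dose above which a
#'   cluster is called sensitive-dose rather than increased-dose-effect.
#' @param flank_bp binding-region flank length either side of the spliced exon.
#' @param trim_bp intronic bases adjacent to each splice junction excluded
#'   from the flanks.
#' @param alpha_enrich one-sided Fisher significance level for RBP enrichment.
#' @param seed master seed; every source of randomness in the pipeline flows
#'   from it.
#' @return a validated named list of class `doseTxConfig`.
#' @examples
#' cfg <- pipelineConfig(seed = 7)
#' cfg$r_threshold
#' @export
pipelineConfig <- function(fdr_deg = 0.1, fdr_splice = 0.1, dpsi_min = 0.05,
                           r_threshold = 0.9, hub_degree_min = 15,
                           hub_top_frac = 0.2, n_clusters = 6,
                           minkowski_order = 2, gamma_sensitive = 0.67,
                           flank_bp = 250, trim_bp = 10, alpha_enrich = 0.05,
                           seed = 1L) {
  cfg <- list(
    fdr_deg = fdr_deg, fdr_splice = fdr_splice, dpsi_min = dpsi_min,
    r_threshold = r_threshold, hub_degree_min = hub_degree_min,
    hub_top_frac = hub_top_frac, n_clusters = n_clusters,
    minkowski_order = minkowski_order, gamma_sensitive = gamma_sensitive,
    flank_bp = flank_bp, trim_bp = trim_bp, alpha_enrich = alpha_enrich,
    seed = as.integer(seed)
  )
  fracs <- c("fdr_deg", "fdr_splice", "hub_top_frac", "alpha_enrich")
  for (nm in fracs) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) stopf("%s must lie in (0, 1]", nm)
  }
  if (cfg$dpsi_min < 0 || cfg$dpsi_min > 1) stopf("dpsi_min must lie in [0, 1]")
  if (cfg$r_threshold <= 0 || cfg$r_threshold >= 1) stopf("r_threshold must lie in (0, 1)")
  if (cfg$hub_degree_min < 0) stopf("hub_degree_min must be >= 0")
  if (cfg$n_clusters < 1) stopf("n_clusters must be >= 1")
  if (cfg$minkowski_order <= 0) stopf("minkowski_order must be > 0")
  if (cfg$flank_bp < 0 || cfg$trim_bp < 0) stopf("flank_bp/trim_bp must be >= 0")
  if (cfg$trim_bp > cfg$flank_bp) stopf("trim_bp cannot exceed flank_bp")
  class(cfg) <- "doseTxConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' Only keys known to [pipelineConfig()] are accepted; unknown keys raise an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @param config a `doseTxConfig` list.
#' @return `readConfig()` returns a `doseTxConfig`; `writeConfig()` the path,
#'   invisibly.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipelineConfig, raw)
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "doseTxConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
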