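#' Thresholded Pearson co-expression network
#'
#' Computes the Pearson correlation of every gene pair over the four ordered
#' group base means (L0, L4, L8, N0) and keeps an edge iff
#' \code{r > r_threshold} or \code{r < -r_threshold} (strict). Genes with zero variance across groups are
#' excluded with a warning. With only four points per profile, high |r|
#' arises by chance in roughly 10-15% of independent pairs; interpret edge
#' counts accordingly.
#'
#' @param groupMeans genes x 4 base-mean matrix ([groupBaseMeans()]).
#' @param gene_subset genes to include (typically the L0-vs-N0 DEG set).
#' @param r_threshold correlation magnitude threshold (default 0.9).
#' @param direction optional named character/numeric vector marking each
#'   gene up- or down-regulated in N0 (stored on the nodes for plotting).
#' @return a [CoexpressionNetwork-class]; hub/highlight flags are filled in
#'   by [detectHubs()].
#' @export
correlationNetwork <- function(groupMeans, gene_subset = rownames(groupMeans),
                               r_threshold = 0.9, direction = NULL) {
  miss <- setdiff(gene_subset, rownames(groupMeans))
  if (length(miss)) {
    stopf("gene(s) absent from the base-mean matrix: %s",
          paste(head(miss, 5), collapse = ", "))
  }
  m <- groupMeans[gene_subset, GROUP_LEVELS, drop = FALSE]
  if (ncol(m) < 3) stopf("need at least 3 conditions to correlate")
  sds <- apply(m, 1, sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warnf("excluding %d zero-variance gene(s) from the network: %s", sum(flat),
          paste(head(rownames(m)[flat], 5), collapse = ", "))
    m <- m[!flat, , drop = FALSE]
  }
  genes <- rownames(m)
  n <- length(genes)
  edges <- S4Vectors::DataFrame(gene_a = character(), gene_b = character(),
                                r = numeric(), sign = character())
  if (n >= 2) {
    cc <- cor(t(m))
    idx <- which(upper.tri(cc) & (cc > r_threshold | cc < -r_threshold),
                 arr.ind = TRUE)
    if (nrow(idx)) {
      ord <- order(idx[, 1], idx[, 2])
      idx <- idx[ord, , drop = FALSE]
      rv <- cc[idx]
      edges <- S4Vectors::DataFrame(
        gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
        r = rv, sign = ifelse(rv > 0, "positive", "negative")
      )
    }
  }
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  nodes <- S4Vectors::DataFrame(
    gene_id = genes,
    degree = as.integer(deg),
    highlighted = FALSE,
    hub = FALSE
  )
  if (!is.null(direction)) {
    nodes$direction <- unname(direction[genes])
  }
  net <- new("CoexpressionNetwork", nodes = nodes, edges = edges,
             rThreshold = r_threshold)
  txInfo("co-expression network: %d nodes, %d edges at |r| > %g", n,
         nrow(edges), r_threshold)
  net
}

#' Rank hub genes in a co-expression network
#'
#' Nodes are ranked by degree (number of |r|-thresholded partners), ties
#' broken lexicographically by gene id. A node is `highlighted` when its
#' degree strictly exceeds `hub_degree_min` (more than 15 highly correlated
#' partners in the default configuration); the `hub` set is the top
#' `ceiling(hub_top_frac * n_nodes)` nodes by rank.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param hub_degree_min highlight threshold (strict; default 15).
#' @param hub_top_frac hub fraction (default 0.2).
#' @return the network with `highlighted`/`hub` flags set and nodes ordered
#'   by rank.
#' @export
detectHubs <- function(network, hub_degree_min = 15, hub_top_frac = 0.2) {
  stopifnot(is(network, "CoexpressionNetwork"))
  nodes <- network@nodes
  if (nrow(nodes) == 0) return(network)
  ord <- order(-nodes$degree, nodes$gene_id)
  nodes <- nodes[ord, , drop = FALSE]
  nodes$highlighted <- nodes$degree > hub_degree_min
  n_hub <- min(nrow(nodes), ceiling(hub_top_frac * nrow(nodes)))
  nodes$hub <- seq_len(nrow(nodes)) <= n_hub
  network@nodes <- nodes
  txInfo("hub detection: %d highlighted (degree > %d), %d hubs (top %g%%)",
         sum(nodes$highlighted), hub_degree_min, sum(nodes$hub),
         100 * hub_top_frac)
  network
}

#' Gene-trait correlation against plasma triglycerides
#'
#' Pearson correlation between each gene's four group-mean TPM values and
#' the group-mean postprandial plasma TG (mg/dL). Negative r means
#' expression rises as TG falls. A constant trait leaves r undefined; such
#' genes are reported as `NA` with a warning.
#'
#' @param groupMeans genes x 4 base-mean matrix.
#' @param trait per-sample trait table (`sample_id`, `tg_mg_dl`).
#' @param design sample design mapping samples to groups.
#' @param gene_subset genes to correlate.
#' @return `DataFrame` with `gene_id`, `r`, `n_points` (= 4).
#' @export
traitCorrelation <- function(groupMeans, trait, design,
                             gene_subset = rownames(groupMeans)) {
  checkDesign(design)
  if (!all(trait$sample_id %in% design$sample_id)) {
    stopf("trait samples absent from design: %s",
          paste(setdiff(trait$sample_id, design$sample_id), collapse = ", "))
  }
  grp <- as.character(design$group[match(trait$sample_id, design$sample_id)])
  tg_group <- tapply(trait$tg_mg_dl, factor(grp, levels = GROUP_LEVELS), mean)
  if (anyNA(tg_group)) stopf("trait table must cover all four groups")
  m <- groupMeans[gene_subset, GROUP_LEVELS, drop = FALSE]
  if (sd(tg_group) == 0) {
    warnf("trait is constant across groups; correlations undefined")
    r <- rep(NA_real_, nrow(m))
  } else {
    r <- apply(m, 1, function(x) {
      if (sd(x) == 0) NA_real_ else cor(x, tg_group)
    })
    if (anyNA(r)) warnf("undefined correlation for %d constant gene(s)", sum(is.na(r)))
  }
  S4Vectors::DataFrame(gene_id = rownames(m), r = unname(r),
                       n_points = length(GROUP_LEVELS))
}
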