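#' Centre dose-series expression profiles
#'
#' For each gene the four group base means (L0, L4, L8, N0) are z-scaled
#' (mean 0, SD 1 across the four values) and then shifted so the L0 value is
#' exactly 0, making trajectories comparable across expression magnitudes.
#' Genes with zero variance across groups carry no trajectory and are dropped
#' with a warning. The transform is invariant to affine rescaling of a
#' gene's raw means.
#'
#' @param groupMeans genes x 4 base-mean matrix from [groupBaseMeans()].
#' @param gene_subset genes to profile (typically the L0-vs-N0 DEG set).
#' @return genes x 4 matrix of centred profiles; every L0 entry is 0.
#' @export
centerProfiles <- function(groupMeans, gene_subset = rownames(groupMeans)) {
  if (length(gene_subset) == 0) stopf("gene_subset must be non-empty")
  miss <- setdiff(gene_subset, rownames(groupMeans))
  if (length(miss)) {
    stopf("gene(s) absent from the base-mean matrix: %s",
          paste(head(miss, 5), collapse = ", "))
  }
  m <- groupMeans[gene_subset, GROUP_LEVELS, drop = FALSE]
  sds <- apply(m, 1, sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warnf("dropping %d gene(s) with zero variance across groups: %s", sum(flat),
          paste(head(rownames(m)[flat], 5), collapse = ", "))
    m <- m[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  z <- (m - rowMeans(m)) / sds
  z - z[, "L0"]
}

#' Cluster dose-response profiles
#'
#' Agglomerative complete-linkage clustering of the centred 4-point
#' trajectories under the Minkowski distance of order `minkowski_order`
#' (order 2 = Euclidean), cut at `k` clusters. Genes are processed in
#' lexicographic id order so ties in the linkage are broken
#' deterministically and the result is invariant to input row order.
#'
#' @param profiles centred profile matrix from [centerProfiles()].
#' @param k number of clusters (default 6).
#' @param minkowski_order Minkowski order p (default 2).
#' @return list with `cluster` (named integer vector, clusters numbered by
#'   first gene occurrence), `centroids` (k x 4 matrix of cluster means) and
#'   `tree` (the `hclust` object).
#' @export
clusterProfiles <- function(profiles, k = 6, minkowski_order = 2) {
  if (nrow(profiles) < k) {
    stopf("need at least k = %d genes to cut %d clusters (got %d)", k, k,
          nrow(profiles))
  }
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- dist(profiles, method = "minkowski", p = minkowski_order)
  tree <- hclust(d, method = "complete")
  raw <- cutree(tree, k = k)
  ## renumber clusters by first appearance for label stability
  relab <- match(raw, unique(raw))
  cluster <- setNames(relab, rownames(profiles))
  centroids <- t(vapply(seq_len(k), function(ci) {
    colMeans(profiles[names(cluster)[cluster == ci], , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(centroids) <- seq_len(k)
  txInfo("profile clustering: %d genes into %d clusters (complete linkage, Minkowski p=%g)",
         nrow(profiles), k, minkowski_order)
  list(cluster = cluster, centroids = centroids, tree = tree)
}

#' Classify profile clusters into dose-response categories
#'
#' Each cluster centroid `c` is compared against its N0 (normal-birth-weight)
#' coordinate through the gap `g(x) = |x - c_N0|`:
#' \itemize{
#'   \item `counter_effect` if `g(c_L8) >= g(c_L0)` — the trajectory moves
#'     away from (or fails to approach) the N0 level with dose;
#'   \item otherwise `sensitive_dose` if the gap already closed at the 0.4%
#'     dose: `g(c_L0) - g(c_L4) >= gamma * (g(c_L0) - g(c_L8))` with
#'     `gamma = 0.67`;
#'   \item otherwise `increased_dose_effect` — gradual, dose-proportional
#'     movement toward N0.
#' }
#' The rule is total and mutually exclusive.
#'
#' @param clustering result of [clusterProfiles()].
#' @param profiles the centred profile matrix (used only via the stored
#'   centroids; accepted for recomputation if centroids are absent).
#' @param gamma gap-closure fraction for the sensitive-dose call.
#' @return list with `cluster_category` (named character per cluster) and
#'   `gene_category` (named character per gene).
#' @export
classifyProfiles <- function(clustering, profiles = NULL, gamma = 0.67) {
  centroids <- clustering$centroids
  if (is.null(centroids)) {
    stopifnot(!is.null(profiles))
    ks <- sort(unique(clustering$cluster))
    centroids <- t(vapply(ks, function(ci) {
      colMeans(profiles[names(clustering$cluster)[clustering$cluster == ci], ,
                        drop = FALSE])
    }, numeric(4)))
    rownames(centroids) <- ks
  }
  cat_of <- apply(centroids, 1, function(cc) {
    g <- abs(cc[c("L0", "L4", "L8")] - cc[["N0"]])
    if (g[["L8"]] >= g[["L0"]]) {
      "counter_effect"
    } else if ((g[["L0"]] - g[["L4"]]) >= gamma * (g[["L0"]] - g[["L8"]])) {
      "sensitive_dose"
    } else {
      "increased_dose_effect"
    }
  })
  gene_category <- setNames(cat_of[as.character(clustering$cluster)],
                            names(clustering$cluster))
  list(cluster_category = cat_of, gene_category = gene_category)
}
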