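#' Pearson correlation matrix of a variable matrix
#'
#' Linear-dependence baseline: symmetric with unit diagonal, entries in
#' \[-1, 1\]. Misses purely nonlinear dependence (e.g. a variable and its
#' square under a symmetric distribution are uncorrelated).
#'
#' @param data samples-by-variables matrix with nonconstant columns.
#' @return `N x N` correlation matrix.
#' @export
pearson_matrix <- function(data) {
  data <- as_variable_matrix(data)
  stats::cor(data)
}

#' Correlation-based dissimilarity
#'
#' Maps a correlation matrix to dissimilarities: `1 - |rho|` by default,
#' so strong dependence of either sign counts as similarity; `absolute =
#' FALSE` gives `1 - rho`. Diagonal forced to zero.
#'
#' @param rho correlation matrix.
#' @param absolute use `|rho|` (default `TRUE`).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
cor_dissimilarity <- function(rho, absolute = TRUE) {
  d <- if (absolute) 1 - abs(rho) else 1 - rho
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering with group-average linkage
#'
#' The comparison baseline: starting from singleton clusters, repeatedly
#' merges the two clusters with the smallest group-average dissimilarity
#' `d_GA(C_m, C_n) = (1 / (|C_m||C_n|)) sum_{i in C_m} sum_{j in C_n}
#' d_ij`, then cuts the tree at `K` clusters.
#'
#' @param delta `midp_dissim` or symmetric dissimilarity matrix.
#' @param K target number of clusters (1..N).
#' @return list with `partition` ([partition()]), `dendrogram` (an
#'   `hclust` object) and `merges` (merge table with heights).
#' @export
hc_cluster <- function(delta, K) {
  d <- dissim_matrix(delta)
  n <- nrow(d)
  if (K < 1 || K > n) stop("`K` must be in 1..", n)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(hc, k = K)
  list(partition = partition(labels),
       dendrogram = hc,
       merges = data.frame(a = hc$merge[, 1L], b = hc$merge[, 2L],
                           height = hc$height))
}

#' Export a dendrogram as Newick
#'
#' @param hc `hclust` object (e.g. from [hc_cluster()]).
#' @param path output file.
#' @export
export_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("package 'ape' is required for Newick export")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
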