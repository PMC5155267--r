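#' Gram-Schmidt orthonormalization of a block of variables
#'
#' Classical Gram-Schmidt in the given column order: the first column is
#' normalized, each subsequent column has its projections onto the already
#' accepted directions removed and is then normalized. A column whose
#' residual norm after projection falls below `tol` times its original
#' norm carries (numerically) no new information and is dropped.
#'
#' @param V numeric matrix (samples x block variables).
#' @param tol relative rank tolerance (default 1e-8).
#' @return list with `W` (orthonormal columns), `kept` and `dropped`
#'   (column indices of `V`).
#' @export
gram_schmidt_block <- function(V, tol = 1e-8) {
  if (!is.matrix(V)) V <- as.matrix(V)
  if (ncol(V) < 1L) stop("empty block")
  kept <- integer(0)
  w <- matrix(0, nrow(V), 0L)
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    orig <- sqrt(sum(v^2))
    if (orig == 0) stop("all-zero column ", j, " in block")
    if (ncol(w) > 0L) v <- v - w %*% crossprod(w, v)
    res <- sqrt(sum(v^2))
    if (res < tol * orig) next
    w <- cbind(w, v / res)
    kept <- c(kept, j)
  }
  list(W = w, kept = kept, dropped = setdiff(seq_len(ncol(V)), kept))
}

#' Orthonormalize variables within each cluster
#'
#' Removes within-cluster redundancy before predictive modeling: for each
#' cluster of the partition, the member columns are (optionally
#' mean-centered and) orthonormalized by [gram_schmidt_block()],
#' independently of the other clusters. The blocks are concatenated into a
#' single design matrix whose columns are named `c{k}_w{m}` and carry a
#' group index aligned to the clusters.
#'
#' @param data samples-by-variables matrix.
#' @param part [partition()] over the columns of `data` (or a label
#'   vector).
#' @param tol relative rank tolerance (default 1e-8).
#' @param center mean-center columns first (default `TRUE`; the regression
#'   intercept absorbs the means).
#' @param order `"given"` (original column order, default) or
#'   `"variance"` (decreasing sample variance within each cluster).
#' @return object of class `midp_blocks`: `W` (design matrix),
#'   `group_index` (integer cluster id per design column), `blocks` (per
#'   cluster: member names in processing order, kept/dropped, the block
#'   matrix).
#' @export
orthonormalize_clusters <- function(data, part, tol = 1e-8, center = TRUE,
                                    order = c("given", "variance")) {
  order <- match.arg(order)
  data <- as_variable_matrix(data)
  if (is.list(part)) part <- part$labels
  if (length(part) != ncol(data))
    stop("partition length does not match number of variables")
  part <- partition(part)
  x <- if (center) sweep(data, 2L, colMeans(data)) else data
  w_all <- matrix(0, nrow(x), 0L)
  group_index <- integer(0)
  blocks <- vector("list", part$K)
  for (k in seq_len(part$K)) {
    members <- which(part$labels == k)
    if (order == "variance") {
      members <- members[base::order(apply(x[, members, drop = FALSE], 2L,
                                           stats::var),
                                     decreasing = TRUE)]
    }
    gs <- gram_schmidt_block(x[, members, drop = FALSE], tol = tol)
    if (ncol(gs$W) > 0L)
      colnames(gs$W) <- paste0("c", k, "_w", seq_len(ncol(gs$W)))
    ## V_kept = W R with R upper triangular, so W = V_kept solve(R);
    ## the map lets the same basis be applied to new samples
    r <- crossprod(gs$W, x[, members[gs$kept], drop = FALSE])
    blocks[[k]] <- list(cluster = k,
                        members = colnames(data)[members],
                        kept = colnames(data)[members][gs$kept],
                        dropped = colnames(data)[members][gs$dropped],
                        W = gs$W,
                        transform = if (length(gs$kept)) solve(r) else r)
    w_all <- cbind(w_all, gs$W)
    group_index <- c(group_index, rep(k, ncol(gs$W)))
  }
  structure(list(W = w_all, group_index = group_index, blocks = blocks,
                 tol = tol, center = center,
                 train_means = if (center) colMeans(data) else NULL),
            class = "midp_blocks")
}

#' Apply fitted orthonormal blocks to new samples
#'
#' Maps a new samples-by-variables matrix (same variables as the training
#' data) into the design-matrix coordinates learned by
#' [orthonormalize_clusters()]: columns are centered with the training
#' means and projected through each block's Gram-Schmidt transform, so a
#' model fitted on the training design applies directly.
#'
#' @param blocks `midp_blocks` from [orthonormalize_clusters()].
#' @param newdata matrix with the same column names as the training data.
#' @return design matrix aligned with `blocks$W`.
#' @export
apply_blocks <- function(blocks, newdata) {
  if (!inherits(blocks, "midp_blocks")) stop("`blocks` must be midp_blocks")
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  x <- newdata
  if (!is.null(blocks$train_means)) {
    if (is.null(colnames(x))) stop("`newdata` must carry variable names")
    x <- sweep(x, 2L, blocks$train_means[colnames(x)])
  }
  out <- matrix(0, nrow(x), 0L)
  for (b in blocks$blocks) {
    if (length(b$kept) == 0L) next
    w_new <- x[, b$kept, drop = FALSE] %*% b$transform
    colnames(w_new) <- colnames(b$W)
    out <- cbind(out, w_new)
  }
  out
}

#' @export
print.midp_blocks <- function(x, ...) {
  cat("Orthonormalized cluster blocks:", length(x$blocks), "cluster(s),",
      ncol(x$W), "design column(s)\n")
  for (b in x$blocks) {
    cat(sprintf("  cluster %d: %d member(s), %d kept\n",
                b$cluster, length(b$members), length(b$kept)))
  }
  invisible(x)
}
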