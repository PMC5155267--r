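#' Double-centered Gram matrix from a dissimilarity matrix
#'
#' Computes `B = -1/2 H D^(2) H` where `H = I - N^-1 11'` is the centering
#' matrix and `D^(2)` is the elementwise-squared dissimilarity matrix. When
#' the dissimilarities are Euclidean distances of some configuration, `B`
#' is the Gram matrix of the centered configuration; its rows and columns
#' sum to zero.
#'
#' @param delta `midp_dissim` object or a symmetric matrix with zero
#'   diagonal.
#' @return symmetric `N x N` matrix.
#' @export
double_center <- function(delta) {
  d <- dissim_matrix(delta)
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d))))
    stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12 * max(1, max(abs(d)))))
    stop("dissimilarity matrix must have zero diagonal")
  d2 <- d^2
  rm <- rowMeans(d2)
  b <- -0.5 * (d2 - outer(rm, rep(1, nrow(d2))) -
                 outer(rep(1, nrow(d2)), rm) + mean(d2))
  dimnames(b) <- dimnames(d)
  (b + t(b)) / 2
}

#' Classical-scaling embedding of variables
#'
#' Embeds each variable as a point in `d`-dimensional space so that
#' pairwise Euclidean distances approximate the dissimilarities, by
#' eigendecomposition of the double-centered Gram matrix (classical metric
#' MDS): `B = V L V'`, `Y = V_d L_d^{1/2}` using the top positive
#' eigenpairs. Reciprocal-MI dissimilarities are generally non-Euclidean,
#' so `B` can have negative eigenvalues; only positive eigenpairs are
#' retained (at most `d`), and the discarded negative mass is reported as a
#' diagnostic.
#'
#' Each eigenvector's sign is fixed so that its largest-magnitude component
#' is positive, making coordinates reproducible across linear-algebra
#' backends.
#'
#' @param delta `midp_dissim` or symmetric zero-diagonal matrix.
#' @param d target dimension (default 2).
#' @param dim_auto if `TRUE`, ignore `d` and choose the smallest dimension
#'   whose leading positive eigenvalues explain at least `var_explained`
#'   of the positive eigenvalue mass.
#' @param var_explained fraction of positive eigenvalue mass for
#'   `dim_auto` (default 0.9).
#' @return object of class `midp_embedding`: `Y` (N x d' coordinates, one
#'   row per variable), `eigenvalues` (retained, decreasing),
#'   `all_eigenvalues`, `neg_mass` (fraction of total absolute eigenvalue
#'   mass that is negative), `names`.
#' @export
embed_variables <- function(delta, d = 2, dim_auto = FALSE,
                            var_explained = 0.9) {
  if (!dim_auto && (length(d) != 1L || d < 1)) stop("`d` must be >= 1")
  b <- double_center(delta)
  nms <- rownames(b) %||%
    (if (inherits(delta, "midp_dissim")) delta$names else
       paste0("v", seq_len(nrow(b))))
  eig <- eigen(b, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-10
  pos <- which(vals > tol)
  if (length(pos) == 0L) stop("Gram matrix has no positive eigenvalue")
  neg_mass <- sum(abs(vals[vals < -tol])) / sum(abs(vals))
  if (dim_auto) {
    frac <- cumsum(vals[pos]) / sum(vals[pos])
    d <- which(frac >= var_explained)[1L]
  }
  d_use <- min(as.integer(d), length(pos))
  if (d_use < d)
    warning("only ", d_use, " positive eigenvalue(s); embedding at d = ",
            d_use, " instead of ", d)
  keep <- pos[seq_len(d_use)]
  v <- eig$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  y <- sweep(v, 2L, sqrt(vals[keep]), `*`)
  rownames(y) <- nms
  colnames(y) <- paste0("y", seq_len(ncol(y)))
  structure(
    list(Y = y, eigenvalues = vals[keep], all_eigenvalues = vals,
         neg_mass = neg_mass, names = nms),
    class = "midp_embedding")
}

#' @export
print.midp_embedding <- function(x, ...) {
  cat("Classical-scaling embedding:", nrow(x$Y), "variables in",
      ncol(x$Y), "dimension(s)\n")
  cat("  retained eigenvalues:", signif(x$eigenvalues, 4), "\n")
  cat(sprintf("  negative eigenvalue mass: %.3f\n", x$neg_mass))
  invisible(x)
}

## Coordinates from either an embedding object or a bare matrix.
embedding_coords <- function(y) {
  if (inherits(y, "midp_embedding")) return(y$Y)
  if (!is.matrix(y)) stop("expected a midp_embedding or coordinate matrix")
  y
}
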