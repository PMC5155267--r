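#' Default histogram bin count
#'
#' Deterministic rule for the number of equal-width bins per axis as a
#' function of the sample size: `floor(sqrt(n_s / 5))`, clamped to
#' \[2, 50\]. Gives 14 bins at `n_s = 1000`. Any other rule can be used by
#' passing `n_bins` explicitly to the estimators.
#'
#' @param n_s sample size.
#' @return integer bin count.
#' @export
default_bins <- function(n_s) {
  as.integer(min(50, max(2, floor(sqrt(n_s / 5)))))
}

## Equal-width bin assignment over [min, max]; bins are right-closed so a
## value falling exactly on an interior edge goes to the lower bin, and the
## minimum goes to bin 1.
bin_index <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) stop("constant vector: equal-width binning undefined")
  w <- (rng[2L] - rng[1L]) / n_bins
  idx <- ceiling((x - rng[1L]) / w)
  pmin.int(pmax.int(idx, 1L), as.integer(n_bins))
}

## Plug-in entropy of the marginal histogram (nats).
hist_entropy <- function(x, n_bins) {
  p <- tabulate(bin_index(x, n_bins), nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Plug-in histogram mutual information between two variables
#'
#' Estimates `MI(x, y) = sum p(k,l) log[p(k,l) / (p(k) p(l))]` from the
#' empirical cell frequencies of a `n_bins` x `n_bins` equal-width grid
#' over the observed ranges, with `0 log 0 := 0`. The estimator captures
#' nonlinear as well as linear dependence but is positively biased at
#' finite sample size (the bias shrinks as the sample grows at fixed bin
#' count).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param n_bins bins per axis; default [default_bins()] of the length.
#' @param unit `"nats"` (natural log, default) or `"bits"`.
#' @param on_constant what to do when an input has zero range:
#'   `"error"` (default) or `"zero"` (return 0).
#' @return nonnegative scalar MI estimate.
#' @export
estimate_mi <- function(x, y, n_bins = NULL,
                        unit = c("nats", "bits"),
                        on_constant = c("error", "zero")) {
  unit <- match.arg(unit)
  on_constant <- match.arg(on_constant)
  if (length(x) != length(y)) stop("`x` and `y` differ in length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    if (on_constant == "zero") return(0)
    stop("constant vector: equal-width binning undefined ",
         "(use on_constant = \"zero\" to force MI = 0)")
  }
  b <- as.integer(n_bins %||% default_bins(n))
  if (b < 2L) stop("n_bins must be >= 2")
  ix <- bin_index(x, b)
  iy <- bin_index(y, b)
  joint <- tabulate((iy - 1L) * b + ix, nbins = b * b) / n
  px <- tabulate(ix, nbins = b) / n
  py <- tabulate(iy, nbins = b) / n
  prod_marg <- as.vector(outer(px, py))
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / prod_marg[nz]))
  mi <- max(mi, 0)
  if (unit == "bits") mi <- mi / log(2)
  mi
}

#' Pairwise mutual-information matrix of a variable matrix
#'
#' Evaluates the plug-in histogram MI for each of the `N(N-1)/2` distinct
#' column pairs. The diagonal is filled with each variable's histogram
#' entropy (its self-MI), which bounds every off-diagonal entry involving
#' that variable.
#'
#' @param data samples-by-variables matrix (see [as_variable_matrix()]).
#' @inheritParams estimate_mi
#' @return symmetric `N x N` matrix with variable names as dimnames.
#' @export
mi_matrix <- function(data, n_bins = NULL, unit = c("nats", "bits"),
                      on_constant = c("error", "zero")) {
  unit <- match.arg(unit)
  on_constant <- match.arg(on_constant)
  data <- as_variable_matrix(data, allow_constant = on_constant == "zero")
  n_var <- ncol(data)
  b <- as.integer(n_bins %||% default_bins(nrow(data)))
  mi <- matrix(0, n_var, n_var, dimnames = list(colnames(data), colnames(data)))
  for (i in seq_len(n_var - 1L)) {
    for (j in seq.int(i + 1L, n_var)) {
      mi[i, j] <- mi[j, i] <- tryCatch(
        estimate_mi(data[, i], data[, j], n_bins = b, unit = unit,
                    on_constant = on_constant),
        error = function(e) stop("MI failed for pair (", colnames(data)[i],
                                 ", ", colnames(data)[j], "): ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  ent <- function(v) {
    if (diff(range(v)) == 0) return(0)
    h <- hist_entropy(v, b)
    if (unit == "bits") h / log(2) else h
  }
  diag(mi) <- apply(data, 2L, ent)
  attr(mi, "n_bins") <- b
  attr(mi, "n_s") <- nrow(data)
  mi
}

#' Bias floor of the plug-in MI estimator
#'
#' First-order positive bias of histogram MI for independent inputs,
#' `(B - 1)^2 / (2 n_s)` nats (the chi-square approximation to the
#' plug-in estimate under independence). MI estimates at or below this
#' level are indistinguishable from independence at the estimator's
#' resolution.
#'
#' @param n_s sample size.
#' @param n_bins bins per axis.
#' @return scalar bias floor in nats.
#' @export
mi_bias_floor <- function(n_s, n_bins) {
  (n_bins - 1)^2 / (2 * n_s)
}

#' Reciprocal-MI dissimilarity matrix
#'
#' Converts a mutual-information matrix into the dissimilarity matrix with
#' off-diagonal entries `delta_ij = min(1 / MI_ij, delta_max)`; high mutual
#' information means low dissimilarity. The diagonal is set to zero (the
#' self-dissimilarity convention required for metric embedding), and zero
#' MI is capped at `delta_max` so the matrix stays finite.
#'
#' The default cap is the reciprocal of the estimator's bias floor
#' ([mi_bias_floor()]): MI values below the small-sample bias of the
#' plug-in estimator carry no evidence of dependence, and capping their
#' reciprocal there keeps sampling noise among (near-)independent pairs
#' from dominating the geometry of the downstream embedding. When the MI
#' matrix does not carry its histogram metadata (a matrix built by hand),
#' the fallback cap is 1000.
#'
#' @param mi symmetric nonnegative MI matrix (from [mi_matrix()]).
#' @param delta_max cap for the dissimilarity of (near-)independent
#'   pairs; `NULL` (default) uses `1 / mi_bias_floor(n_s, n_bins)` when
#'   the matrix carries those attributes, else 1000.
#' @return object of class `midp_dissim` with elements `delta` (the
#'   dissimilarity matrix), `mi` (the input, kept for inspection) and
#'   `names`.
#' @export
dissimilarity_from_mi <- function(mi, delta_max = NULL) {
  if (!is.matrix(mi) || nrow(mi) != ncol(mi))
    stop("`mi` must be a square matrix")
  if (is.null(delta_max)) {
    b <- attr(mi, "n_bins")
    n_s <- attr(mi, "n_s")
    delta_max <- if (!is.null(b) && !is.null(n_s))
      1 / mi_bias_floor(n_s, b) else 1e3
  }
  if (max(abs(mi - t(mi))) > 1e-8 * max(1, max(abs(mi))))
    stop("`mi` must be symmetric")
  if (any(mi < 0)) stop("`mi` must be nonnegative")
  if (delta_max <= 0) stop("`delta_max` must be positive")
  delta <- pmin(1 / mi, delta_max)
  delta[!is.finite(delta)] <- delta_max
  diag(delta) <- 0
  delta <- (delta + t(delta)) / 2
  structure(
    list(delta = delta, mi = mi, delta_max = delta_max,
         names = colnames(mi) %||% paste0("v", seq_len(ncol(mi)))),
    class = "midp_dissim")
}

## Accept either a midp_dissim or a bare symmetric matrix downstream.
dissim_matrix <- function(delta) {
  if (inherits(delta, "midp_dissim")) return(delta$delta)
  if (!is.matrix(delta) || nrow(delta) != ncol(delta))
    stop("expected a dissimilarity matrix or midp_dissim object")
  delta
}

#' @export
print.midp_dissim <- function(x, ...) {
  cat("Reciprocal-MI dissimilarity matrix:", nrow(x$delta), "variables\n")
  off <- x$delta[upper.tri(x$delta)]
  cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n", min(off), max(off)))
  invisible(x)
}
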