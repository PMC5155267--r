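#' Construct a partition object
#'
#' @param labels integer cluster labels; relabeled to contiguous `1..K`
#'   in order of first appearance.
#' @return list with `labels`, `K`, `sizes`.
#' @export
partition <- function(labels) {
  labels <- as.integer(factor(labels, levels = unique(labels)))
  k <- max(labels)
  list(labels = labels, K = k, sizes = tabulate(labels, nbins = k))
}

#' Chinese Restaurant Process seating probabilities
#'
#' Probability that customer `n` joins each existing table or opens a new
#' one: table `k` with probability `m_k / (n - 1 + alpha)` and a new table
#' with probability `alpha / (n - 1 + alpha)`. The first customer always
#' opens the first table.
#'
#' @param sizes vector of current table sizes `m_k` (may be empty);
#'   must sum to `n - 1`.
#' @param n index of the arriving customer (>= 1).
#' @param alpha concentration parameter (> 0).
#' @return probability vector of length `length(sizes) + 1`; the last
#'   entry is the new-table probability.
#' @export
crp_assignment_probs <- function(sizes, n, alpha) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (n < 1) stop("`n` must be >= 1")
  if (sum(sizes) != n - 1)
    stop("table sizes must sum to n - 1 (", n - 1, "), got ", sum(sizes))
  c(sizes, alpha) / (n - 1 + alpha)
}

#' Normal-Inverse-Wishart prior for the DP mixture
#'
#' Conjugate base measure over cluster means and covariances. Defaults are
#' empirical-Bayes: prior mean at the data centroid, a weak mean coupling
#' `kappa0 = 0.01`, the minimal-variance degrees of freedom
#' `nu0 = d + 2` (so the prior expected cluster covariance equals
#' `Psi0`), and an isotropic prior covariance scale
#' `Psi0 = (v / E[K]^2) I` with `v` the average per-axis variance of `Y`
#' and `E[K] = sum_i alpha / (alpha + i - 1)` the number of clusters the
#' CRP prior expects for `N` points. The division anticipates that the
#' total spread of the data is shared among about `E[K]` clusters, so a
#' single cluster should be correspondingly tighter than the whole cloud
#' (taking `Psi0 = cov(Y)` itself describes clusters as broad as all the
#' data and biases the posterior toward merging distinct groups), and the
#' scale is isotropic because the anisotropy of the total spread reflects
#' where clusters sit, not their internal shape — cluster shape itself is
#' learned from the data through the weak `nu0`. Degenerate coordinates
#' (zero variance) fall back to the identity.
#'
#' @param Y coordinate matrix (used for empirical defaults).
#' @param m0 prior mean (length d).
#' @param kappa0 prior mean coupling (> 0).
#' @param nu0 degrees of freedom (> d - 1).
#' @param Psi0 positive-definite d x d scale matrix.
#' @param alpha DP concentration used for the default `Psi0` scaling
#'   (default 1).
#' @return list of hyperparameters with precomputed constants.
#' @export
niw_prior <- function(Y, m0 = NULL, kappa0 = 0.01, nu0 = NULL, Psi0 = NULL,
                      alpha = 1) {
  y <- embedding_coords(Y)
  d <- ncol(y)
  m0 <- m0 %||% colMeans(y)
  nu0 <- nu0 %||% (d + 2)
  if (is.null(Psi0)) {
    e_k <- sum(alpha / (alpha + seq_len(nrow(y)) - 1))
    v <- mean(apply(y, 2L, stats::var))
    Psi0 <- if (is.na(v) || v <= 0) diag(d) else (v / e_k^2) * diag(d)
  }
  if (kappa0 <= 0) stop("`kappa0` must be positive")
  if (nu0 <= d - 1) stop("`nu0` must exceed d - 1")
  ch <- tryCatch(chol(Psi0), error = function(e)
    stop("`Psi0` must be positive definite"))
  list(m0 = as.numeric(m0), kappa0 = kappa0, nu0 = nu0, Psi0 = Psi0,
       d = d, logdet_Psi0 = 2 * sum(log(diag(ch))))
}

## log multivariate gamma
lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

## log density of a multivariate Student-t
mvt_logdens <- function(y, mu, scale, df) {
  d <- length(y)
  r <- chol(scale)
  quad <- sum(backsolve(r, y - mu, transpose = TRUE)^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - 0.5 * d * log(df * pi) -
    sum(log(diag(r))) - 0.5 * (df + d) * log1p(quad / df)
}

## Posterior-predictive log density of y under the collapsed NIW posterior
## of a cluster with sufficient statistics (n, s = sum, ss = sum of outer
## products); n = 0 gives the prior predictive.
niw_post_pred <- function(y, n, s, ss, prior) {
  kap <- prior$kappa0 + n
  nu <- prior$nu0 + n
  if (n == 0) {
    mn <- prior$m0
    psi <- prior$Psi0
  } else {
    ybar <- s / n
    dm <- ybar - prior$m0
    psi <- prior$Psi0 + (ss - n * tcrossprod(ybar)) +
      (prior$kappa0 * n / kap) * tcrossprod(dm)
    psi <- (psi + t(psi)) / 2
    mn <- (prior$kappa0 * prior$m0 + s) / kap
  }
  df <- nu - prior$d + 1
  mvt_logdens(y, mn, psi * (kap + 1) / (kap * df), df)
}

## log marginal likelihood of the rows of y under the NIW base measure
niw_log_marginal <- function(y, prior) {
  n <- nrow(y)
  d <- prior$d
  kap_n <- prior$kappa0 + n
  nu_n <- prior$nu0 + n
  ybar <- colMeans(y)
  yc <- sweep(y, 2L, ybar)
  dm <- ybar - prior$m0
  psi_n <- prior$Psi0 + crossprod(yc) +
    (prior$kappa0 * n / kap_n) * tcrossprod(dm)
  psi_n <- (psi_n + t(psi_n)) / 2
  logdet_n <- 2 * sum(log(diag(chol(psi_n))))
  -n * d / 2 * log(pi) + d / 2 * (log(prior$kappa0) - log(kap_n)) +
    prior$nu0 / 2 * prior$logdet_Psi0 - nu_n / 2 * logdet_n +
    lmvgamma(nu_n / 2, d) - lmvgamma(prior$nu0 / 2, d)
}

#' Joint log posterior of a partition under the DP Gaussian mixture
#'
#' Chinese-Restaurant-Process partition prior plus the product of
#' per-cluster NIW marginal likelihoods (component parameters integrated
#' out). Used to rank Gibbs samples and extract the MAP partition.
#'
#' @param labels cluster labels (contiguous or not).
#' @param Y coordinates (`midp_embedding` or matrix).
#' @param alpha DP concentration.
#' @param prior from [niw_prior()].
#' @return scalar log posterior (up to the model's normalizing constant).
#' @export
dp_log_posterior <- function(labels, Y, alpha, prior) {
  y <- embedding_coords(Y)
  part <- partition(labels)
  n <- length(part$labels)
  lp <- part$K * log(alpha) + sum(lgamma(part$sizes)) +
    lgamma(alpha) - lgamma(alpha + n)
  for (k in seq_len(part$K)) {
    lp <- lp + niw_log_marginal(y[part$labels == k, , drop = FALSE], prior)
  }
  lp
}

## One collapsed Gibbs sweep over all points in index order (Neal's
## algorithm 3). `state` is an environment holding labels and per-cluster
## sufficient statistics; modified in place.
gibbs_sweep_env <- function(state, y, alpha, prior) {
  n_pts <- nrow(y)
  for (i in seq_len(n_pts)) {
    yi <- y[i, ]
    k_old <- state$labels[i]
    state$n[[k_old]] <- state$n[[k_old]] - 1L
    state$s[[k_old]] <- state$s[[k_old]] - yi
    state$ss[[k_old]] <- state$ss[[k_old]] - tcrossprod(yi)
    if (state$n[[k_old]] == 0L) {
      state$n[[k_old]] <- NULL
      state$s[[k_old]] <- NULL
      state$ss[[k_old]] <- NULL
      shift <- state$labels > k_old
      state$labels[shift] <- state$labels[shift] - 1L
    }
    k_occ <- length(state$n)
    logw <- numeric(k_occ + 1L)
    for (k in seq_len(k_occ)) {
      logw[k] <- log(state$n[[k]]) +
        niw_post_pred(yi, state$n[[k]], state$s[[k]], state$ss[[k]], prior)
    }
    logw[k_occ + 1L] <- log(alpha) + niw_post_pred(yi, 0L, NULL, NULL, prior)
    w <- exp(logw - max(logw))
    k_new <- sample.int(k_occ + 1L, 1L, prob = w)
    if (k_new > k_occ) {
      state$n[[k_new]] <- 1L
      state$s[[k_new]] <- yi
      state$ss[[k_new]] <- tcrossprod(yi)
    } else {
      state$n[[k_new]] <- state$n[[k_new]] + 1L
      state$s[[k_new]] <- state$s[[k_new]] + yi
      state$ss[[k_new]] <- state$ss[[k_new]] + tcrossprod(yi)
    }
    state$labels[i] <- k_new
  }
  invisible(state)
}

#' One collapsed Gibbs sweep of the DP Gaussian mixture
#'
#' Resamples every point's cluster indicator once, in index order: the
#' point is removed from its cluster, each occupied cluster is weighted by
#' `m_k` times the Student-t posterior-predictive density of the point
#' under that cluster's collapsed NIW posterior, a new cluster by `alpha`
#' times the prior predictive, and the indicator is drawn from the
#' normalized weights. Emptied clusters are deleted and labels compacted.
#' Uses the current R RNG stream.
#'
#' @param Y coordinates (`midp_embedding` or matrix).
#' @param labels current cluster labels (contiguous `1..K`).
#' @param alpha DP concentration (> 0).
#' @param prior from [niw_prior()]; default built from `Y`.
#' @return updated integer label vector.
#' @export
gibbs_sweep <- function(Y, labels, alpha = 1, prior = NULL) {
  y <- embedding_coords(Y)
  prior <- prior %||% niw_prior(y, alpha = alpha)
  part <- partition(labels)
  if (length(part$labels) != nrow(y)) stop("labels do not match Y")
  state <- init_state(y, part$labels)
  gibbs_sweep_env(state, y, alpha, prior)
  state$labels
}

init_state <- function(y, labels) {
  state <- new.env(parent = emptyenv())
  state$labels <- labels
  k <- max(labels)
  state$n <- lapply(seq_len(k), function(j) sum(labels == j))
  state$s <- lapply(seq_len(k), function(j)
    colSums(y[labels == j, , drop = FALSE]))
  state$ss <- lapply(seq_len(k), function(j)
    crossprod(y[labels == j, , drop = FALSE]))
  state
}

#' Fit a Dirichlet-process Gaussian mixture by collapsed Gibbs sampling
#'
#' Clusters the rows of `Y` (embedded variables) without fixing the number
#' of clusters. Starting from a single cluster (or one cluster per point),
#' runs `n_sweeps` collapsed Gibbs sweeps, records the post-burn-in trace
#' of partitions with their joint log posteriors, and extracts the
#' maximum-a-posteriori partition and the posterior co-clustering
#' frequency matrix. Fully reproducible given `seed`.
#'
#' @param Y `midp_embedding` or an `N x d` coordinate matrix.
#' @param alpha DP concentration (default 1).
#' @param n_sweeps total Gibbs sweeps (default 1000).
#' @param burn_in sweeps discarded before recording (default 200).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param prior NIW hyperparameters ([niw_prior()]); empirical defaults.
#' @param init `"single"` (all points in one cluster, default) or
#'   `"perpoint"` (one cluster per point).
#' @return object of class `midp_dpposterior`: `map_partition` (a
#'   [partition()]), `trace_labels` (kept sweeps x N matrix),
#'   `log_posterior` (per kept sweep), `cosim` (N x N co-clustering
#'   frequencies, unit diagonal), `names`, `config`.
#' @export
fit_dpmm <- function(Y, alpha = 1, n_sweeps = 1000, burn_in = 200,
                     seed = NULL, prior = NULL,
                     init = c("single", "perpoint")) {
  init <- match.arg(init)
  y <- embedding_coords(Y)
  n_pts <- nrow(y)
  nms <- rownames(y) %||% paste0("v", seq_len(n_pts))
  if (n_sweeps < 1) stop("`n_sweeps` must be >= 1")
  if (burn_in < 0 || burn_in >= n_sweeps)
    stop("`burn_in` must be in [0, n_sweeps)")
  if (!is.null(seed)) set.seed(seed)
  if (n_pts == 1L) {
    cfg <- list(alpha = alpha, n_sweeps = n_sweeps, burn_in = burn_in,
                seed = seed, init = init)
    return(structure(
      list(map_partition = partition(1L),
           trace_labels = matrix(1L, n_sweeps - burn_in, 1L),
           log_posterior = rep(0, n_sweeps - burn_in),
           cosim = matrix(1, 1, 1), names = nms, config = cfg),
      class = "midp_dpposterior"))
  }
  prior <- prior %||% niw_prior(y, alpha = alpha)
  labels0 <- if (init == "single") rep(1L, n_pts) else seq_len(n_pts)
  state <- init_state(y, labels0)
  n_keep <- n_sweeps - burn_in
  trace_labels <- matrix(NA_integer_, n_keep, n_pts)
  log_post <- numeric(n_keep)
  cosim <- matrix(0, n_pts, n_pts)
  for (sweep in seq_len(n_sweeps)) {
    gibbs_sweep_env(state, y, alpha, prior)
    if (sweep > burn_in) {
      j <- sweep - burn_in
      trace_labels[j, ] <- state$labels
      log_post[j] <- dp_log_posterior(state$labels, y, alpha, prior)
      cosim <- cosim + outer(state$labels, state$labels, `==`)
    }
  }
  cosim <- cosim / n_keep
  dimnames(cosim) <- list(nms, nms)
  best <- which.max(log_post)
  colnames(trace_labels) <- nms
  structure(
    list(map_partition = partition(trace_labels[best, ]),
         trace_labels = trace_labels,
         log_posterior = log_post,
         cosim = cosim,
         names = nms,
         config = list(alpha = alpha, n_sweeps = n_sweeps,
                       burn_in = burn_in, seed = seed, init = init)),
    class = "midp_dpposterior")
}

#' @export
print.midp_dpposterior <- function(x, ...) {
  cat("DP mixture posterior over", length(x$names), "variables\n")
  cat("  MAP partition: K =", x$map_partition$K,
      "(sizes:", paste(x$map_partition$sizes, collapse = ", "), ")\n")
  cat("  kept sweeps:", nrow(x$trace_labels),
      " alpha =", x$config$alpha, "\n")
  invisible(x)
}
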