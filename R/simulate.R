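## x-component of a Lorenz system (sigma = 10, rho = 28, beta = 8/3)
## integrated by fixed-step 4th-order Runge-Kutta at dt = 0.01, after a
## burn-in that lands the trajectory on the attractor.
lorenz_x <- function(n_steps, dt = 0.01, sigma = 10, rho = 28, beta = 8 / 3,
                     burn = 1000, init = c(x = 1, y = 1, z = 1)) {
  deriv <- function(t, s, p) {
    list(c(sigma * (s[2] - s[1]),
           s[1] * (rho - s[3]) - s[2],
           s[1] * s[2] - beta * s[3]))
  }
  times <- seq(0, (burn + n_steps) * dt, by = dt)
  out <- deSolve::rk4(init, times, deriv, NULL)
  out[(burn + 2):(burn + 1 + n_steps), 2L]
}

## logistic map x -> r x (1 - x) with burn-in
logistic_map <- function(n, r = 3.8, x0 = NULL, burn = 100) {
  x0 <- x0 %||% stats::runif(1, 0.1, 0.9)
  x <- x0
  for (i in seq_len(burn)) x <- r * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- r * x * (1 - x)
    out[i] <- x
  }
  out
}

new_sim <- function(data, labels, response = NULL, generator, params, seed) {
  structure(list(data = data, true_labels = partition(labels),
                 response = response,
                 provenance = list(generator = generator, params = params,
                                   seed = seed)),
            class = "midp_sim")
}

#' @export
print.midp_sim <- function(x, ...) {
  cat("Simulated dataset (", x$provenance$generator, "): ",
      nrow(x$data), " samples x ", ncol(x$data), " variables, ",
      x$true_labels$K, " true cluster(s)\n", sep = "")
  invisible(x)
}

#' Four-cluster benchmark simulation (20 variables)
#'
#' Generates the standard four-cluster variable-clustering benchmark, five
#' variables per cluster, each of length `n`:
#' \itemize{
#'   \item Cluster 1: `v1 ~ N(0,1)` and deterministic nonlinear transforms
#'     `v2 = |v1|`, `v3 = v1^2`, `v4 = v1^3`, `v5 = sin(v1)`.
#'   \item Cluster 2: the same construction from an independent `v6`.
#'   \item Cluster 3: `v11` sampled from the chaotic logistic map
#'     `x -> 3.8 x (1 - x)`, with `v12..v15` its lagged copies at lags
#'     3, 5, 7, 9.
#'   \item Cluster 4: `v16` an AR(2) process nonlinearly coupled to the
#'     x-component of a Lorenz system (`sigma = 10, rho = 28, beta = 8/3`,
#'     step 0.01): `v16(t) = 0.5 v16(t-1) - 0.3 v16(t-2) +
#'     0.1 x(t)^2 + eps`, `eps ~ N(0, 0.01)` (variance); `v17..v20` its
#'     lagged copies at lags 10, 20, 30, 40.
#' }
#' Lagged copies are aligned by trimming so every column has length `n`.
#' Within-cluster dependence is strong but mostly nonlinear, so linear
#' correlation fails to reveal the structure while mutual information
#' does.
#'
#' @param n samples per variable (default 1000; >= 100).
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param transforms list of three functions applied to the parent normal
#'   variable to make the 3rd..5th members of clusters 1 and 2.
#' @return `midp_sim` with `data` (n x 20), `true_labels` (4 clusters of
#'   5), `provenance`.
#' @export
simulate_table1 <- function(n = 1000, seed = NULL,
                            transforms = list(function(v) v^2,
                                              function(v) v^3,
                                              sin)) {
  if (n < 100) stop("`n` must be >= 100 (maximum lag is 40)")
  if (!is.null(seed)) set.seed(seed)
  nonlinear_block <- function(v) {
    cbind(v, abs(v), transforms[[1L]](v), transforms[[2L]](v),
          transforms[[3L]](v))
  }
  b1 <- nonlinear_block(stats::rnorm(n))
  b2 <- nonlinear_block(stats::rnorm(n))

  lag_block <- function(x, lags, n) {
    vapply(c(0L, lags), function(l) x[(1L + l):(n + l)], numeric(n))
  }
  x3 <- logistic_map(n + 9L)
  b3 <- lag_block(x3, c(3L, 5L, 7L, 9L), n)

  ar_burn <- 100L
  len <- ar_burn + n + 40L
  xl <- lorenz_x(len, init = c(x = 1, y = 1, z = 1) + 0.1 * stats::rnorm(3))
  a <- numeric(len)
  eps <- stats::rnorm(len, sd = 0.1)
  for (t in 3:len) {
    a[t] <- 0.5 * a[t - 1] - 0.3 * a[t - 2] + 0.1 * xl[t]^2 + eps[t]
  }
  a <- a[-seq_len(ar_burn)]
  b4 <- lag_block(a, c(10L, 20L, 30L, 40L), n)

  data <- cbind(b1, b2, b3, b4)
  colnames(data) <- paste0("v", 1:20)
  new_sim(data, rep(1:4, each = 5L), generator = "table1",
          params = list(n = n), seed = seed)
}

#' Two-cluster motivating simulation (8 variables)
#'
#' Two groups of four variables, each driven by an independent standard
#' normal parent: `v1` with `v2 = v1 + noise` (linear), `v3 = v1^2` and
#' `v4 = |v1|` (purely nonlinear: both are even functions of a symmetric
#' parent, so their Pearson correlation with `v1` vanishes while their
#' mutual information is large); `v5..v8` repeat the construction from
#' `v5`. Hierarchical clustering on a linear-correlation dissimilarity
#' misplaces the nonlinear members, which the MI-based pipeline recovers.
#'
#' @param n samples (default 1000).
#' @param seed integer seed.
#' @param noise_sd sd of the additive noise on the linear member
#'   (default 0.1).
#' @return `midp_sim` with `data` (n x 8) and two true clusters of 4.
#' @export
simulate_motivating <- function(n = 1000, seed = NULL, noise_sd = 0.1) {
  if (n < 100) stop("`n` must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  block <- function(v) cbind(v, v + stats::rnorm(length(v), sd = noise_sd),
                             v^2, abs(v))
  data <- cbind(block(stats::rnorm(n)), block(stats::rnorm(n)))
  colnames(data) <- paste0("v", 1:8)
  new_sim(data, rep(1:2, each = 4L), generator = "motivating",
          params = list(n = n, noise_sd = noise_sd), seed = seed)
}

#' Isotropic Gaussian blob coordinates
#'
#' Fixture generator for the DP mixture: `K` isotropic Gaussian blobs of
#' unit spread whose centers are placed (in the first two coordinates) on
#' a circle scaled so adjacent centers are `separation` apart; `K = 1`
#' sits at the origin, `K = 2` at `(+-separation/2, 0)`.
#'
#' @param K number of blobs.
#' @param n_per points per blob (default 10).
#' @param separation distance between adjacent centers (default 20).
#' @param d dimension (default 2).
#' @param sd within-blob spread (default 1).
#' @param seed integer seed.
#' @return list with `Y` (coordinates) and `labels`.
#' @export
simulate_blobs <- function(K, n_per = 10, separation = 20, d = 2, sd = 1,
                           seed = NULL) {
  if (K < 1) stop("`K` must be >= 1")
  if (d < 2 && K > 1) stop("`d` must be >= 2 for multiple blobs")
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(0, K, d)
  if (K > 1) {
    radius <- separation / (2 * sin(pi / K))
    ang <- 2 * pi * (seq_len(K) - 1) / K
    centers[, 1L] <- radius * cos(ang)
    centers[, 2L] <- radius * sin(ang)
  }
  labels <- rep(seq_len(K), each = n_per)
  y <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(K * n_per * d, sd = sd), K * n_per, d)
  rownames(y) <- paste0("p", seq_len(nrow(y)))
  list(Y = y, labels = labels)
}

#' Grouped redundant-feature surrogate with a binary outcome
#'
#' Emulates a feature matrix with blocks of mutually redundant, nonlinearly
#' related features (as arises when signal-model weights and their absolute
#' values are both included as predictors): each group has a latent
#' standard-normal factor per subject, and every feature in the group is a
#' nonlinear view of that factor plus independent Gaussian noise. The
#' first member of each group is a monotone view (`tanh`); the remaining
#' members are localized views `exp(-(f - c)^2)` with centers `c` spread
#' over \[-2, 2\], the non-monotone analogue of magnitude features such as
#' absolute weights. Every member is strongly (and mostly nonlinearly)
#' dependent on its factor, so within-group mutual information is high,
#' while each localized view on its own is almost linearly uninformative
#' about the factor — the linearly usable signal is spread densely across
#' the whole group. The binary response follows a logistic model on a
#' sparse subset of the factors, making entire groups jointly relevant
#' while the remaining groups are null: the regime in which group-level
#' selection is expected to beat feature-by-feature selection.
#'
#' @param n_subjects samples (default 300).
#' @param n_groups feature groups (default 6).
#' @param group_size features per group (default 8).
#' @param n_active factors entering the response (default 2, alternating
#'   sign).
#' @param effect absolute logistic coefficient per active factor
#'   (default 1.5).
#' @param noise_sd feature noise sd (default 0.25).
#' @param intercept logistic intercept (default 0; prevalence ~
#'   `plogis(intercept)`).
#' @param seed integer seed.
#' @return `midp_sim` with `data`, `true_labels` (group per feature) and
#'   `response`.
#' @export
simulate_vcg_like <- function(n_subjects = 300, n_groups = 6,
                              group_size = 8, n_active = 2, effect = 1.5,
                              noise_sd = 0.25, intercept = 0, seed = NULL) {
  if (min(n_subjects, n_groups, group_size) < 1) stop("sizes must be >= 1")
  if (n_active > n_groups) stop("`n_active` cannot exceed `n_groups`")
  if (!is.null(seed)) set.seed(seed)
  centers <- if (group_size > 1) {
    seq(-2, 2, length.out = group_size - 1)
  } else {
    numeric(0)
  }
  factors <- matrix(stats::rnorm(n_subjects * n_groups), n_subjects,
                    n_groups)
  data <- matrix(0, n_subjects, n_groups * group_size)
  labels <- integer(n_groups * group_size)
  nm <- character(n_groups * group_size)
  col <- 0L
  for (g in seq_len(n_groups)) {
    for (m in seq_len(group_size)) {
      col <- col + 1L
      v <- if (m == 1L) tanh(factors[, g])
           else exp(-(factors[, g] - centers[m - 1L])^2)
      data[, col] <- v + stats::rnorm(n_subjects, sd = noise_sd)
      labels[col] <- g
      nm[col] <- paste0("g", g, "_f", m)
    }
  }
  colnames(data) <- nm
  coefs <- rep(0, n_groups)
  if (n_active > 0)
    coefs[seq_len(n_active)] <- effect * (-1)^(seq_len(n_active) - 1)
  eta <- intercept + drop(factors %*% coefs)
  z <- stats::rbinom(n_subjects, 1L, stats::plogis(eta))
  new_sim(data, labels, response = z, generator = "vcg_like",
          params = list(n_subjects = n_subjects, n_groups = n_groups,
                        group_size = group_size, n_active = n_active,
                        effect = effect, noise_sd = noise_sd,
                        intercept = intercept),
          seed = seed)
}
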