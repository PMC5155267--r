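test_that("CRP seating probabilities follow m_k/(n-1+alpha) and alpha/(n-1+alpha)", {
  # the first customer always opens the first table
  expect_equal(crp_assignment_probs(integer(0), 1, 1), 1)
  # n = 5, sizes (2, 2), alpha = 1 -> (2/5, 2/5, 1/5)
  expect_equal(crp_assignment_probs(c(2, 2), 5, 1), c(0.4, 0.4, 0.2))
  # normalization for random valid states
  set.seed(1)
  for (i in 1:20) {
    sizes <- rpois(sample(1:5, 1), 3) + 1
    p <- crp_assignment_probs(sizes, sum(sizes) + 1, runif(1, 0.1, 5))
    expect_equal(sum(p), 1)
  }
  expect_error(crp_assignment_probs(c(2, 2), 4, 1), "sum to")
})

test_that("expected CRP table count matches sum alpha/(alpha + i - 1)", {
  set.seed(99)
  n <- 25
  for (alpha in c(0.5, 1, 3)) {
    ks <- vapply(1:2000, function(r) {
      sizes <- integer(0)
      for (i in seq_len(n)) {
        p <- crp_assignment_probs(sizes, i, alpha)
        pick <- sample.int(length(p), 1, prob = p)
        if (pick > length(sizes)) sizes <- c(sizes, 1L)
        else sizes[pick] <- sizes[pick] + 1L
      }
      length(sizes)
    }, integer(1))
    expected <- sum(alpha / (alpha + seq_len(n) - 1))
    mc_se <- stats::sd(ks) / sqrt(length(ks))
    expect_lt(abs(mean(ks) - expected), 4 * mc_se + 1e-9)
  }
})

test_that("a single point always forms one cluster", {
  post <- fit_dpmm(matrix(c(1, 2), 1, 2), n_sweeps = 10, burn_in = 0,
                   seed = 1)
  expect_identical(post$map_partition$K, 1L)
})

test_that("vanishing concentration keeps a tight blob in one cluster", {
  set.seed(2)
  y <- matrix(rnorm(30), 15, 2)
  post <- fit_dpmm(y, alpha = 1e-8, n_sweeps = 100, burn_in = 20, seed = 2)
  expect_identical(post$map_partition$K, 1L)
})

test_that("two well-separated blobs are recovered exactly", {
  set.seed(3)
  y <- rbind(matrix(rnorm(20), 10, 2) + cbind(rep(-50, 10), 0),
             matrix(rnorm(20), 10, 2) + cbind(rep(50, 10), 0))
  post <- fit_dpmm(y, alpha = 1, n_sweeps = 200, burn_in = 50, seed = 3)
  expect_identical(post$map_partition$K, 2L)
  truth <- rep(1:2, each = 10)
  expect_equal(adjusted_rand_index(post$map_partition$labels, truth), 1)
  # both initializations agree on well-separated data
  post2 <- fit_dpmm(y, alpha = 1, n_sweeps = 200, burn_in = 50, seed = 3,
                    init = "perpoint")
  expect_identical(post2$map_partition$K, 2L)
  expect_equal(adjusted_rand_index(post2$map_partition$labels, truth), 1)
})

test_that("the sampler is reproducible given a seed", {
  bl <- simulate_blobs(3, n_per = 5, separation = 15, seed = 7)
  p1 <- fit_dpmm(bl$Y, n_sweeps = 50, burn_in = 10, seed = 42)
  p2 <- fit_dpmm(bl$Y, n_sweeps = 50, burn_in = 10, seed = 42)
  expect_identical(p1$trace_labels, p2$trace_labels)
  expect_identical(p1$log_posterior, p2$log_posterior)
})

test_that("trace labels are always contiguous and the log posterior finite", {
  bl <- simulate_blobs(2, n_per = 6, separation = 5, seed = 5)
  post <- fit_dpmm(bl$Y, n_sweeps = 80, burn_in = 0, seed = 5)
  expect_true(all(is.finite(post$log_posterior)))
  for (r in seq_len(nrow(post$trace_labels))) {
    lab <- post$trace_labels[r, ]
    expect_identical(sort(unique(lab)), seq_len(max(lab)))
  }
})

test_that("co-clustering frequencies are symmetric probabilities with unit diagonal", {
  bl <- simulate_blobs(2, n_per = 6, separation = 8, seed = 6)
  post <- fit_dpmm(bl$Y, n_sweeps = 100, burn_in = 20, seed = 6)
  cs <- post$cosim
  expect_identical(cs, t(cs))
  expect_true(all(cs >= 0 & cs <= 1))
  expect_equal(diag(cs), rep(1, nrow(cs)), ignore_attr = TRUE)
})

test_that("near-coincident points collapse to one cluster, matching a Monte-Carlo oracle", {
  # three nearly identical points under an explicit proper prior: the MAP
  # must be the single-cluster partition among all 5 partitions of 3 items
  y <- rbind(c(0.00, 0.02), c(0.03, -0.01), c(-0.02, 0.01))
  prior <- niw_prior(y, m0 = c(0, 0), kappa0 = 1, nu0 = 4, Psi0 = diag(2))
  partitions <- list(c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(1, 2, 2),
                     c(1, 2, 3))
  lp <- vapply(partitions, dp_log_posterior, numeric(1), Y = y, alpha = 1,
               prior = prior)
  expect_identical(which.max(lp), 1L)

  # independent Monte-Carlo marginal likelihood (draw NIW parameters,
  # average Gaussian likelihoods) must agree on the ranking
  set.seed(123)
  mc_marginal <- function(pts, n_draws = 40000) {
    vals <- vapply(seq_len(n_draws), function(i) {
      sigma <- solve(stats::rWishart(1, 4, solve(diag(2)))[, , 1])
      r <- chol(sigma)
      mu <- drop(crossprod(r, stats::rnorm(2)))  # N(0, sigma), kappa0 = 1
      q <- colSums(backsolve(r, t(pts) - mu, transpose = TRUE)^2)
      exp(sum(-q / 2 - sum(log(diag(r))) - log(2 * pi)))
    }, numeric(1))
    log(mean(vals))
  }
  crp_log <- function(lab, alpha = 1) {
    part <- partition(lab)
    part$K * log(alpha) + sum(lgamma(part$sizes)) + lgamma(alpha) -
      lgamma(alpha + length(lab))
  }
  lp_mc <- vapply(partitions, function(lab) {
    crp_log(lab) + sum(vapply(unique(lab), function(k)
      mc_marginal(y[lab == k, , drop = FALSE]), numeric(1)))
  }, numeric(1))
  expect_identical(which.max(lp_mc), 1L)
  # the analytic and Monte-Carlo log posteriors agree within MC error
  expect_equal(lp, lp_mc, tolerance = 0.05)

  # the sampler itself lands there, and exactly coincident rows also work
  post <- fit_dpmm(y, n_sweeps = 100, burn_in = 20, seed = 9, prior = prior)
  expect_identical(post$map_partition$K, 1L)
  y_id <- matrix(1, 3, 2)
  post_id <- fit_dpmm(y_id, n_sweeps = 50, burn_in = 10, seed = 9)
  expect_identical(post_id$map_partition$K, 1L)
})

test_that("a single Gibbs sweep preserves label validity", {
  set.seed(31)
  bl <- simulate_blobs(2, n_per = 8, separation = 10, seed = 31)
  lab <- gibbs_sweep(bl$Y, rep(1L, 16), alpha = 1)
  expect_length(lab, 16)
  expect_identical(sort(unique(lab)), seq_len(max(lab)))
})
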