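# shared fixtures built in code

# squared Euclidean configuration -> dissimilarity matrix
dist_matrix <- function(coords) {
  as.matrix(stats::dist(coords))
}

# brute-force group-average agglomeration, used as the independent oracle
# for hc_cluster on small instances
brute_ga_hc <- function(d, K) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > K) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        ga <- mean(d[clusters[[a]], clusters[[b]]])
        if (ga < best_d - 1e-12) {
          best_d <- ga
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(d))
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  list(labels = labels, heights = heights)
}

# permutation null quantile for the histogram MI of a variable pair
perm_mi_quantile <- function(x, y, n_perm = 200, q = 0.99, n_bins = NULL) {
  stats::quantile(
    vapply(seq_len(n_perm), function(i)
      estimate_mi(x, sample(y), n_bins = n_bins), numeric(1)),
    probs = q, names = FALSE)
}
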