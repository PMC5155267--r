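#' Logistic log-likelihood
#'
#' `sum_i [z_i log h_i + (1 - z_i) log(1 - h_i)]` where `h_i` is the
#' logistic function of `intercept + W_i' beta`. Computed on the linear
#' predictor scale for numerical stability; always <= 0.
#'
#' @param beta coefficient vector (length = `ncol(W)`).
#' @param intercept scalar intercept.
#' @param W design matrix.
#' @param z binary 0/1 response.
#' @return scalar log-likelihood.
#' @export
logistic_loglik <- function(beta, intercept, W, z) {
  check_binary(z, nrow(W))
  eta <- drop(intercept + W %*% beta)
  ## z*eta - log(1 + exp(eta)), stable for large |eta|
  sum(z * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

check_binary <- function(z, n = NULL) {
  if (!is.null(n) && length(z) != n) stop("response length mismatch")
  if (length(z) == 0L) stop("empty response")
  if (!all(z %in% c(0, 1))) stop("response must be binary 0/1")
  invisible(z)
}

## prox of t * [lambda ||b||_1 + gamma sum_k sqrt(p_k) ||b_k||_2]
## (sequential soft-threshold then groupwise shrinkage is the exact prox
## of the sparse-group-lasso penalty)
sgl_prox <- function(b, t, lambda, gamma, groups, sqrt_pk) {
  if (lambda > 0) b <- sign(b) * pmax(abs(b) - t * lambda, 0)
  if (gamma > 0) {
    for (k in unique(groups)) {
      idx <- which(groups == k)
      nrm <- sqrt(sum(b[idx]^2))
      if (nrm == 0) next
      b[idx] <- b[idx] * max(0, 1 - t * gamma * sqrt_pk[k] / nrm)
    }
  }
  b
}

#' Group elastic-net logistic regression
#'
#' Minimizes the penalized negative log-likelihood
#' \deqn{-\ell(\beta) + \gamma \sum_k \sqrt{p_k} \|\beta_k\|_2 +
#'       \lambda \|\beta\|_1}
#' over the intercept (unpenalized) and the coefficients, where the groups
#' `k` are the cluster blocks of the design and `p_k` their sizes. The
#' group term selects whole clusters, the `l1` term individual columns
#' within them. Solved by proximal gradient descent with backtracking line
#' search; the objective decreases monotonically and iteration stops when
#' its relative change falls below `tol` or `max_iter` is reached.
#'
#' @param W design matrix (e.g. from [orthonormalize_clusters()]).
#' @param z binary 0/1 response.
#' @param groups integer group id per column of `W`.
#' @param gamma group-penalty weight (>= 0).
#' @param lambda individual `l1` weight (>= 0).
#' @param max_iter maximum proximal-gradient iterations (default 5000).
#' @param tol relative objective-change tolerance (default 1e-8).
#' @param init_beta,init_intercept optional starting point (defaults:
#'   zeros). The objective is convex, so any start converges to the same
#'   optimum.
#' @return object of class `midp_genet`: `beta` (named), `intercept`,
#'   `gamma`, `lambda`, `group_index`, `converged`, `objective_trace`,
#'   `n_iter`.
#' @export
fit_group_enet <- function(W, z, groups = rep(1L, ncol(W)),
                           gamma = 0, lambda = 0,
                           max_iter = 5000, tol = 1e-8,
                           init_beta = NULL, init_intercept = 0) {
  if (inherits(W, "midp_blocks")) {
    groups <- W$group_index
    W <- W$W
  }
  check_binary(z, nrow(W))
  if (length(groups) != ncol(W)) stop("`groups` must index columns of W")
  if (gamma < 0 || lambda < 0) stop("penalties must be nonnegative")
  groups <- as.integer(factor(groups, levels = unique(groups)))
  sqrt_pk <- sqrt(tabulate(groups))
  p <- ncol(W)
  b <- init_beta %||% numeric(p)
  b0 <- init_intercept
  penalty <- function(b) {
    pen <- lambda * sum(abs(b))
    if (gamma > 0)
      pen <- pen + gamma * sum(sqrt_pk * sqrt(rowsum(b^2, groups)))
    pen
  }
  smooth_f <- function(b0, b) -logistic_loglik(b, b0, W, z)
  f <- smooth_f(b0, b)
  obj <- f + penalty(b)
  trace <- obj
  t_step <- 4 / max(colSums(W^2) + 1)  # 1/L guess; refined by backtracking
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(b0 + W %*% b)
    h <- stats::plogis(eta)
    g0 <- sum(h - z)
    g <- drop(crossprod(W, h - z))
    repeat {
      b0_new <- b0 - t_step * g0
      b_new <- sgl_prox(b - t_step * g, t_step, lambda, gamma, groups,
                        sqrt_pk)
      f_new <- smooth_f(b0_new, b_new)
      db0 <- b0_new - b0
      db <- b_new - b
      quad <- f + g0 * db0 + sum(g * db) +
        (db0^2 + sum(db^2)) / (2 * t_step)
      if (f_new <= quad + 1e-12 * abs(f)) break
      t_step <- t_step / 2
      if (t_step < 1e-16) break
    }
    obj_new <- f_new + penalty(b_new)
    if (obj_new > obj) {  # safeguard: reject non-decreasing step
      t_step <- t_step / 2
      if (t_step < 1e-16) break
      next
    }
    b0 <- b0_new; b <- b_new; f <- f_new
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(1, abs(obj))) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
    t_step <- t_step * 1.5  # allow recovery after conservative shrinks
  }
  if (!converged)
    warning("proximal gradient did not converge in ", max_iter,
            " iterations")
  names(b) <- colnames(W)
  structure(list(beta = b, intercept = b0, gamma = gamma, lambda = lambda,
                 group_index = groups, converged = converged,
                 objective_trace = trace, n_iter = it,
                 columns = colnames(W)),
            class = "midp_genet")
}

#' Predicted success probabilities from a fitted model
#'
#' @param model `midp_genet` fit.
#' @param W design matrix aligned (same columns, same order) with the
#'   training design.
#' @return vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, W) {
  if (inherits(W, "midp_blocks")) W <- W$W
  if (ncol(W) != length(model$beta)) stop("design column mismatch")
  if (!is.null(model$columns) && !is.null(colnames(W)) &&
      !identical(colnames(W), model$columns))
    stop("design column names do not match the training design")
  stats::plogis(drop(model$intercept + W %*% model$beta))
}

#' Classify at a probability threshold
#'
#' @param model `midp_genet` fit.
#' @param W design matrix.
#' @param threshold classification cutoff (default 0.5).
#' @return integer 0/1 predictions.
#' @export
classify <- function(model, W, threshold = 0.5) {
  as.integer(predict_proba(model, W) > threshold)
}

#' Classification report (accuracy, sensitivity, specificity)
#'
#' Confusion counts of predicted vs true binary labels with the three
#' standard rates as percentages: accuracy `(TP+TN)/n`, sensitivity
#' `TP/(TP+FN)` (true-positive rate among cases), specificity
#' `TN/(TN+FP)` (true-negative rate among controls).
#'
#' @param predicted,truth binary 0/1 vectors of equal length.
#' @return object of class `midp_report` with `TP`, `TN`, `FP`, `FN`,
#'   `accuracy`, `sensitivity`, `specificity` (percentages).
#' @export
evaluate_classification <- function(predicted, truth) {
  check_binary(truth)
  check_binary(predicted, length(truth))
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA),
            class = "midp_report")
}

#' @export
print.midp_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Seeded stratified k-fold split
#'
#' Assigns each sample to exactly one fold, stratifying on the binary
#' response so class proportions are balanced across folds.
#'
#' @param z binary 0/1 response.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per sample (1..k).
#' @export
make_folds <- function(z, k = 10, seed = 1) {
  check_binary(z)
  if (k < 2 || k > length(z)) stop("invalid number of folds")
  set.seed(seed)
  fold <- integer(length(z))
  for (cls in c(0, 1)) {
    idx <- sample(which(z == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated tuning of the group elastic net
#'
#' Seeded stratified k-fold cross-validation over a grid of `(gamma,
#' lambda)` pairs, then a refit on the full data at the selected pair.
#' Selection follows the one-standard-error convention by default: among
#' all pairs whose mean validation accuracy is within one standard error
#' (of the best pair's fold accuracies) of the maximum, the most
#' regularized pair is chosen (largest `gamma`, then largest `lambda`).
#' Accuracy-maximizing CV systematically under-penalizes; the 1-SE rule
#' trades a statistically indistinguishable amount of accuracy for the
#' sparser, more stable model. `select = "best"` takes the accuracy
#' maximum instead (ties broken toward larger `gamma` then `lambda`).
#'
#' Default grids are scale-free: fractions of the data-derived maximal
#' penalties `lambda_max = max_j |W_j' (z - mean(z))|` (smallest `lambda`
#' that zeroes every coefficient at `gamma = 0`) and
#' `gamma_max = max_k ||W_k' (z - mean(z))|| / sqrt(p_k)` (smallest
#' `gamma` that zeroes every group at `lambda = 0`), so tuning behaves
#' identically whether the design columns have unit norm (orthonormalized
#' blocks) or unit variance (standardized raw features).
#'
#' @inheritParams fit_group_enet
#' @param gamma_grid,lambda_grid candidate penalty values; `NULL`
#'   (default) uses fractions `c(0, 0.05, 0.2, 0.8)` of `gamma_max` and
#'   `c(0.01, 0.05, 0.2, 0.8)` of `lambda_max`.
#' @param nfolds folds (default 10).
#' @param seed fold seed (default 1).
#' @param select `"1se"` (default) or `"best"`.
#' @param tol solver tolerance used during CV (looser than the final
#'   refit).
#' @return list with `model` (final [fit_group_enet()] fit), `gamma`,
#'   `lambda`, `cv_table` (grid with mean accuracy and its fold-based
#'   standard error).
#' @export
cv_group_enet <- function(W, z, groups = NULL,
                          gamma_grid = NULL,
                          lambda_grid = NULL,
                          nfolds = 10, seed = 1,
                          select = c("1se", "best"), tol = 1e-6,
                          max_iter = 2000) {
  select <- match.arg(select)
  if (inherits(W, "midp_blocks")) {
    groups <- W$group_index
    W <- W$W
  }
  groups <- groups %||% rep(1L, ncol(W))
  if (is.null(gamma_grid) || is.null(lambda_grid)) {
    score <- drop(crossprod(W, z - mean(z)))
    if (is.null(lambda_grid))
      lambda_grid <- max(abs(score)) * c(0.01, 0.05, 0.2, 0.8)
    if (is.null(gamma_grid)) {
      gnorm <- sqrt(rowsum(score^2, groups)) / sqrt(tabulate(
        as.integer(factor(groups, levels = unique(groups)))))
      gamma_grid <- max(gnorm) * c(0, 0.05, 0.2, 0.8)
    }
  }
  fold <- make_folds(z, nfolds, seed)
  grid <- expand.grid(gamma = gamma_grid, lambda = lambda_grid)
  fold_acc <- matrix(0, nrow(grid), nfolds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      fit <- suppressWarnings(
        fit_group_enet(W[tr, , drop = FALSE], z[tr], groups,
                       gamma = grid$gamma[g], lambda = grid$lambda[g],
                       max_iter = max_iter, tol = tol))
      pred <- classify(fit, W[!tr, , drop = FALSE])
      fold_acc[g, f] <- mean(pred == z[!tr])
    }
  }
  acc <- rowMeans(fold_acc)
  se <- apply(fold_acc, 1L, stats::sd) / sqrt(nfolds)
  top <- which.max(acc)
  best <- if (select == "1se") {
    eligible <- which(acc >= acc[top] - se[top])
    eligible[order(-grid$gamma[eligible], -grid$lambda[eligible])][1L]
  } else {
    order(-acc, -grid$gamma, -grid$lambda)[1L]
  }
  model <- fit_group_enet(W, z, groups, gamma = grid$gamma[best],
                          lambda = grid$lambda[best])
  list(model = model, gamma = grid$gamma[best], lambda = grid$lambda[best],
       cv_table = cbind(grid, accuracy = acc, se = se))
}
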