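test_that("logistic log-likelihood matches direct evaluation", {
  w <- rbind(c(1, 0), c(0, 1), c(1, 1))
  z <- c(1, 0, 1)
  beta <- c(0.5, -0.25)
  b0 <- 0.1
  eta <- b0 + w %*% beta
  h <- 1 / (1 + exp(-eta))
  direct <- sum(z * log(h) + (1 - z) * log(1 - h))
  expect_equal(logistic_loglik(beta, b0, w, z), direct)
  # null model: h = 1/2 everywhere
  expect_equal(logistic_loglik(c(0, 0), 0, w, z), 3 * log(0.5))
  # perfectly separating huge coefficients push the likelihood to 0-
  w2 <- cbind(c(-1, -1, 1, 1))
  z2 <- c(0, 0, 1, 1)
  expect_gt(logistic_loglik(50, 0, w2, z2), -1e-10)
  expect_lte(logistic_loglik(50, 0, w2, z2), 0)
  expect_error(logistic_loglik(beta, b0, w, c(1, 2, 0)), "binary")
})

test_that("the unpenalized fit matches the IRLS oracle to 1e-4", {
  set.seed(42)
  w <- matrix(rnorm(100 * 6), 100, 6)
  colnames(w) <- paste0("x", 1:6)
  z <- rbinom(100, 1, plogis(0.5 + w %*% c(1, -0.5, 0, 0.3, 0, 0)))
  fit <- fit_group_enet(w, z, gamma = 0, lambda = 0, tol = 1e-12)
  oracle <- stats::glm(z ~ w, family = stats::binomial)
  expect_lt(max(abs(c(fit$intercept, fit$beta) - stats::coef(oracle))),
            1e-4)
  expect_true(fit$converged)
  expect_true(all(diff(fit$objective_trace) <= 0))
  # fitted probabilities match the oracle too
  expect_lt(max(abs(predict_proba(fit, w) - stats::fitted(oracle))), 1e-4)
})

test_that("an overwhelming l1 penalty zeroes all slopes, leaving logit(mean)", {
  set.seed(43)
  w <- matrix(rnorm(80 * 4), 80, 4)
  z <- rbinom(80, 1, 0.3)
  fit <- fit_group_enet(w, z, gamma = 0, lambda = 1e6)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, qlogis(mean(z)), tolerance = 1e-3)
})

test_that("the group penalty zeroes null groups exactly while keeping active ones", {
  set.seed(7)
  p <- 36
  grp <- rep(1:6, each = 6)
  x <- matrix(rnorm(500 * p), 500, p)
  beta_true <- numeric(p)
  beta_true[grp <= 2] <- rep(c(3, -3, 3, -3, 3, 3), 2)
  z <- rbinom(500, 1, plogis(x %*% beta_true))
  fit <- fit_group_enet(x, z, grp, gamma = 12, lambda = 0.5)
  norms <- tapply(abs(fit$beta), grp, sum)
  expect_true(all(norms[3:6] == 0))
  expect_true(all(norms[1:2] > 0))
})

test_that("the convex objective reaches the same optimum from random starts", {
  set.seed(51)
  w <- matrix(rnorm(120 * 5), 120, 5)
  z <- rbinom(120, 1, plogis(w %*% c(1, -1, 0.5, 0, 0)))
  obj_final <- function(init_b, init_b0) {
    f <- fit_group_enet(w, z, rep(1:2, c(3, 2)), gamma = 2, lambda = 0.5,
                        init_beta = init_b, init_intercept = init_b0,
                        tol = 1e-12, max_iter = 20000)
    min(f$objective_trace)
  }
  o1 <- obj_final(NULL, 0)
  o2 <- obj_final(rnorm(5), rnorm(1))
  o3 <- obj_final(rnorm(5, sd = 3), 1)
  expect_equal(o1, o2, tolerance = 1e-6)
  expect_equal(o1, o3, tolerance = 1e-6)
})

test_that("the pure-lasso special case agrees with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(52)
  n <- 200
  w <- matrix(rnorm(n * 8), n, 8)
  z <- rbinom(n, 1, plogis(w %*% c(1.5, -1, 0, 0, 0.5, 0, 0, 0)))
  lam <- 8
  fit <- fit_group_enet(w, z, gamma = 0, lambda = lam, tol = 1e-12,
                        max_iter = 20000)
  gn <- glmnet::glmnet(w, z, family = "binomial", alpha = 1,
                       lambda = lam / n, standardize = FALSE,
                       thresh = 1e-12)
  objective <- function(b0, b) {
    -logistic_loglik(b, b0, w, z) + lam * sum(abs(b))
  }
  o_ours <- objective(fit$intercept, fit$beta)
  o_glmnet <- objective(gn$a0, as.numeric(gn$beta))
  expect_lt(abs(o_ours - o_glmnet) / abs(o_glmnet), 1e-4)
})

test_that("predictions are probabilities, monotone in positive coefficients", {
  set.seed(53)
  w <- matrix(rnorm(50 * 3), 50, 3)
  z <- rbinom(50, 1, 0.5)
  zero_model <- fit_group_enet(w, z * 0 + rep(c(0, 1), 25), gamma = 0,
                               lambda = 1e9)
  expect_equal(predict_proba(zero_model, w), rep(0.5, 50))
  fit <- fit_group_enet(w, z, gamma = 0, lambda = 0)
  p <- predict_proba(fit, w)
  expect_true(all(p > 0 & p < 1))
  j <- which.max(abs(fit$beta))
  w_up <- w
  w_up[, j] <- w[, j] + sign(fit$beta[j])
  expect_true(all(predict_proba(fit, w_up) >= p))
  expect_error(predict_proba(fit, w[, 1:2]), "mismatch")
})

test_that("classification metrics follow their confusion-count definitions", {
  rep1 <- evaluate_classification(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(rep1$accuracy, 100)
  expect_equal(rep1$sensitivity, 100)
  # TP=2, FN=1, TN=3, FP=0
  pred <- c(1, 1, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 0, 0)
  r <- evaluate_classification(pred, truth)
  expect_equal(r$sensitivity, 100 * 2 / 3, tolerance = 1e-10)
  expect_equal(r$specificity, 100)
  expect_equal(r$accuracy, 100 * 5 / 6, tolerance = 1e-10)
  # all-positive predictions have zero specificity
  r2 <- evaluate_classification(rep(1, 6), truth)
  expect_equal(r2$specificity, 0)
  expect_error(evaluate_classification(integer(0), integer(0)), "empty")
})

test_that("stratified folds partition the samples and balance classes", {
  z <- rep(c(0, 1), c(30, 70))
  fold <- make_folds(z, 10, seed = 3)
  expect_identical(sort(unique(fold)), 1:10)
  expect_true(all(tabulate(fold) == 10))
  for (f in 1:10) expect_equal(sum(z[fold == f]), 7)
  expect_identical(make_folds(z, 10, seed = 3), fold)
})

test_that("cross-validation selects within the grid and refits on all data", {
  set.seed(54)
  p <- 12
  grp <- rep(1:3, each = 4)
  x <- matrix(rnorm(150 * p), 150, p)
  z <- rbinom(150, 1, plogis(x %*% c(rep(2, 4), rep(0, 8))))
  cv <- cv_group_enet(x, z, grp, nfolds = 5, seed = 1)
  expect_true(cv$gamma %in% cv$cv_table$gamma)
  expect_true(cv$lambda %in% cv$cv_table$lambda)
  expect_s3_class(cv$model, "midp_genet")
  expect_identical(nrow(cv$cv_table), 16L)
})
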