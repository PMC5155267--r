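#' End-to-end MI-DP pipeline
#'
#' Runs the full variable-clustering (and optionally predictive) pipeline
#' in order: histogram mutual information over all variable pairs ->
#' reciprocal-MI dissimilarity -> classical-scaling embedding ->
#' Dirichlet-process Gaussian-mixture clustering by collapsed Gibbs
#' sampling. When a binary response is supplied, the clusters are
#' Gram-Schmidt orthonormalized and a group elastic-net logistic
#' regression is tuned by cross-validation and fitted; without a response
#' the pipeline stops after clustering and no model is produced.
#' Identical inputs, configuration and seed give identical outputs.
#'
#' @param data samples-by-variables matrix (or path handled by
#'   [read_variable_matrix()] upstream).
#' @param response optional binary 0/1 vector, one label per sample.
#' @param n_bins histogram bins ([default_bins()] of the sample size when
#'   `NULL`).
#' @param delta_max dissimilarity cap; `NULL` (default) uses the
#'   bias-floor rule of [dissimilarity_from_mi()].
#' @param dim embedding dimension (default 2).
#' @param dim_auto pick the dimension explaining >= 90% of positive
#'   eigenvalue mass.
#' @param alpha DP concentration (default 1).
#' @param n_sweeps,burn_in Gibbs schedule (defaults 1000 / 200).
#' @param seed master seed for the sampler and CV folds.
#' @param gso_tol Gram-Schmidt rank tolerance.
#' @param gamma_grid,lambda_grid CV penalty grids; `NULL` (default) uses
#'   the scale-free grids of [cv_group_enet()].
#' @param nfolds CV folds (default 10).
#' @param cv_select penalty-selection rule, see [cv_group_enet()].
#' @param out_dir if non-`NULL`, write per-stage artifacts (MI and
#'   dissimilarity matrices, coordinates, labels, co-clustering matrix,
#'   model coefficients, report) as CSV/JSON into this directory.
#' @return object of class `midp_pipeline`: `mi`, `dissim`, `embedding`,
#'   `posterior`, `partition`, and with a response also `blocks`, `cv`,
#'   `model`, `fitted_proba`, `report` (training-set metrics).
#' @export
run_pipeline <- function(data, response = NULL, n_bins = NULL,
                         delta_max = NULL, dim = 2, dim_auto = FALSE,
                         alpha = 1, n_sweeps = 1000, burn_in = 200,
                         seed = 1, gso_tol = 1e-8,
                         gamma_grid = NULL, lambda_grid = NULL,
                         nfolds = 10, cv_select = c("1se", "best"),
                         out_dir = NULL) {
  cv_select <- match.arg(cv_select)
  data <- as_variable_matrix(data)
  if (!is.null(response)) check_binary(response, nrow(data))
  mi <- mi_matrix(data, n_bins = n_bins)
  dis <- dissimilarity_from_mi(mi, delta_max = delta_max)
  emb <- embed_variables(dis, d = dim, dim_auto = dim_auto)
  post <- fit_dpmm(emb, alpha = alpha, n_sweeps = n_sweeps,
                   burn_in = burn_in, seed = seed)
  res <- list(mi = mi, dissim = dis, embedding = emb, posterior = post,
              partition = post$map_partition,
              config = list(n_bins = n_bins, delta_max = delta_max,
                            dim = dim, dim_auto = dim_auto, alpha = alpha,
                            n_sweeps = n_sweeps, burn_in = burn_in,
                            seed = seed, gso_tol = gso_tol,
                            gamma_grid = gamma_grid,
                            lambda_grid = lambda_grid, nfolds = nfolds))
  if (!is.null(response)) {
    blocks <- orthonormalize_clusters(data, post$map_partition,
                                      tol = gso_tol)
    cv <- cv_group_enet(blocks$W, response, blocks$group_index,
                        gamma_grid = gamma_grid,
                        lambda_grid = lambda_grid,
                        nfolds = nfolds, seed = seed, select = cv_select)
    proba <- predict_proba(cv$model, blocks$W)
    res$blocks <- blocks
    res$cv <- cv
    res$model <- cv$model
    res$fitted_proba <- proba
    res$report <- evaluate_classification(as.integer(proba > 0.5), response)
  }
  res <- structure(res, class = "midp_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.midp_pipeline <- function(x, ...) {
  cat("MI-DP pipeline on", nrow(x$mi), "variables\n")
  cat("  MAP partition: K =", x$partition$K,
      "(sizes:", paste(x$partition$sizes, collapse = ", "), ")\n")
  if (!is.null(x$report)) {
    cat("  training-set classification: ")
    print(x$report)
  }
  invisible(x)
}

## Write per-stage pipeline artifacts as plain text.
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_square_matrix(res$mi, file.path(out_dir, "mi.csv"))
  write_square_matrix(res$dissim$delta, file.path(out_dir, "dissim.csv"))
  utils::write.csv(data.frame(name = rownames(res$embedding$Y),
                              res$embedding$Y, check.names = FALSE),
                   file.path(out_dir, "coordinates.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(name = res$posterior$names,
                              cluster = res$partition$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  write_square_matrix(res$posterior$cosim,
                      file.path(out_dir, "cosim.csv"))
  if (!is.null(res$model) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(intercept = res$model$intercept,
           beta = as.list(res$model$beta),
           gamma = res$model$gamma, lambda = res$model$lambda,
           groups = res$model$group_index,
           report = unclass(res$report)),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(res$config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
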