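`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a variable matrix
#'
#' Checks that `x` is a numeric matrix of samples (rows) by variables
#' (columns) suitable for mutual-information estimation: at least two rows
#' and two columns, no missing values, and (unless `allow_constant`) a
#' nonzero range in every column. Column names are filled in as `v1..vN`
#' when absent.
#'
#' @param x numeric matrix or data frame, samples in rows, variables in
#'   columns.
#' @param allow_constant logical; permit zero-range columns.
#' @return the validated numeric matrix with column names.
#' @export
as_variable_matrix <- function(x, allow_constant = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix (samples in rows, variables in columns)")
  if (nrow(x) < 2L) stop("need at least 2 samples (rows)")
  if (ncol(x) < 2L) stop("need at least 2 variables (columns)")
  if (anyNA(x)) stop("missing values are not supported; impute beforehand")
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("variable names must be unique")
  if (!allow_constant) {
    rng <- apply(x, 2L, function(v) diff(range(v)))
    if (any(rng == 0))
      stop("constant column(s): ", paste(colnames(x)[rng == 0], collapse = ", "))
  }
  x
}

#' Read a variable matrix from CSV/TSV
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @param header logical; first row holds variable names.
#' @return numeric matrix with variable names as column names.
#' @export
read_variable_matrix <- function(path, sep = ",", header = TRUE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          check.names = FALSE)
  as_variable_matrix(df)
}

#' Write a square named matrix as CSV
#'
#' Writes the matrix with variable names as both the header row and the
#' first column, the interchange format used for MI and dissimilarity
#' matrices.
#'
#' @param m square matrix with dimnames.
#' @param path output file path.
#' @export
write_square_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, ~0 is the expectation under independent
#' random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  a_comb <- sum(choose(rowSums(tab), 2))
  b_comb <- sum(choose(colSums(tab), 2))
  expected <- a_comb * b_comb / choose(n, 2)
  max_comb <- (a_comb + b_comb) / 2
  if (max_comb == expected) return(1)
  (sum_comb - expected) / (max_comb - expected)
}
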