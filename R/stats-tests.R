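# Statistical layer: two-sample and contingency tests, FDR, ECDF,
# correlation and PCA-based QC. Test computations are delegated to the
# standard stats implementations behind a uniform result shape.

.test_result <- function(method, statistic, p, sizes, two_tailed = TRUE) {
  structure(list(method = method, statistic = unname(statistic),
                 p = unname(p), sizes = sizes, two_tailed = two_tailed),
            class = "decaykit_test")
}

#' @export
print.decaykit_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact two-tailed p-value (by enumeration over rank assignments) when
#' both samples have at most `exact_max` observations and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max exact-enumeration cutoff on the larger group size
#'   (default 12).
#' @return list of class `decaykit_test` (method, statistic = U for `x`,
#'   p, sizes).
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- max(length(x), length(y)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = use_exact, correct = TRUE, alternative = "two.sided"))
  .test_result("Mann-Whitney U", wt$statistic, wt$p.value,
               c(length(x), length(y)))
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Two-tailed p is the sum of hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return list of class `decaykit_test` (statistic = odds ratio
#'   estimate).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table)))
    stop("need a 2x2 table of non-negative integers", call. = FALSE)
  ft <- stats::fisher.test(table, alternative = "two.sided")
  .test_result("Fisher exact", ft$estimate, ft$p.value, rowSums(table))
}

#' Chi-square test of equal proportions on a 2 x k table
#'
#' Pearson chi-square statistic with k - 1 degrees of freedom, no
#' continuity correction.
#'
#' @param table 2 x k matrix of counts; all expected cell counts must be
#'   positive.
#' @return list of class `decaykit_test`.
#' @export
chi_square_proportions <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0))
    stop("zero expected cell count", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  .test_result("chi-square", ct$statistic, ct$p.value, colSums(table))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; q >= p and q is monotone in the p-value rank.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Empirical cumulative distribution table
#'
#' @param values non-empty numeric vector.
#' @return data.frame with sorted `value` and cumulative `fraction`
#'   (share of observations <= value).
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  v <- sort(values)
  data.frame(value = v, fraction = seq_along(v) / length(v))
}

#' Pearson or Spearman correlation with r-squared
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @param method "pearson" or "spearman".
#' @return list with `r` and `r2`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  r <- stats::cor(x, y, method = method)
  list(r = r, r2 = r^2)
}

#' Principal-component QC of sample structure
#'
#' Centers the log-expression matrix per gene, decomposes by SVD and, for
#' each of the first `n_components` components, reports which sample-label
#' factor (e.g. fraction, condition, replicate) best separates the scores,
#' measured by the between-group share of score variance (R2 of a one-way
#' fit).
#'
#' @param mat numeric matrix, genes x samples (log scale recommended).
#' @param labels data.frame of factors, one row per sample.
#' @param n_components components to summarize (default 3).
#' @return list: `scores` (samples x components), `variance_explained`,
#'   `separation` (data.frame component, factor, r2 for the best factor
#'   per component).
#' @export
pca_qc <- function(mat, labels, n_components = 3) {
  stopifnot(is.matrix(mat), nrow(labels) == ncol(mat))
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  centered <- mat - rowMeans(mat)
  if (sum(centered^2) == 0)
    stop("zero total variance", call. = FALSE)
  sv <- svd(t(centered))
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(mat)
  ve <- sv$d^2 / sum(sv$d^2)

  sep <- do.call(rbind, lapply(seq_len(k), function(j) {
    r2s <- vapply(names(labels), function(f) {
      g <- as.factor(labels[[f]])
      if (nlevels(g) < 2) return(NA_real_)
      s <- scores[, j]
      gm <- tapply(s, g, mean)
      ss_b <- sum(table(g) * (gm - mean(s))^2)
      ss_t <- sum((s - mean(s))^2)
      if (ss_t == 0) NA_real_ else ss_b / ss_t
    }, numeric(1))
    best <- which.max(r2s)
    data.frame(component = paste0("PC", j), factor = names(labels)[best],
               r2 = r2s[best], stringsAsFactors = FALSE)
  }))
  rownames(sep) <- NULL
  list(scores = scores, variance_explained = ve[seq_len(k)],
       separation = sep)
}
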