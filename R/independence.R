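# Joint-independence diagnostic for the channel p-value streams: d-variable
# Hilbert-Schmidt independence criterion with a permutation null.

gaussian_kernel <- function(x) {
  D <- abs(outer(x, x, `-`))
  sig <- stats::median(D[upper.tri(D)])
  if (!is.finite(sig) || sig <= 0)
    stop("constant (or near-constant) column: median pairwise distance is 0")
  exp(-(D / sig)^2 / 2)
}

#' d-variable HSIC test of joint independence
#'
#' Computes the d-variable Hilbert-Schmidt independence criterion with
#' Gaussian kernels (median-heuristic bandwidth per column) and a
#' permutation null: columns 2..d are independently permuted, the observed
#' statistic is compared with the `(1 - alpha)` quantile of the permuted
#' statistics, and joint independence is rejected exactly when the
#' threshold is less than or equal to the observed HSIC score.
#'
#' @param samples `n x d` numeric matrix (n >= 10 rows, d >= 2
#'   non-constant columns), e.g. per-site p-values of the five channels.
#' @param alpha Significance level in `(0, 1)`.
#' @param n_perm Number of permutations for the null distribution.
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `"hsic_result"` with fields `statistic`,
#'   `threshold`, `alpha`, `reject`, `perm_p` (permutation p-value) and
#'   `n_perm`.
#' @export
dhsic_test <- function(samples, alpha = 0.05, n_perm = 1000L, seed = NULL) {
  x <- as.matrix(samples)
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) stop("need at least 2 variables (columns)")
  if (nrow(x) < 10L) stop("need at least 10 observations (rows)")
  if (any(!is.finite(x))) stop("samples must be finite")
  if (any(apply(x, 2, stats::var) == 0)) stop("constant column in samples")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Ks <- lapply(seq_len(ncol(x)), function(j) gaussian_kernel(x[, j]))
  res <- dhsic_perm_cpp(Ks, n_perm)
  threshold <- as.numeric(stats::quantile(res$perms, 1 - alpha, type = 1))
  structure(
    list(statistic = res$stat, threshold = threshold, alpha = alpha,
         reject = threshold <= res$stat,
         perm_p = (1 + sum(res$perms >= res$stat)) / (n_perm + 1),
         n_perm = n_perm, n = nrow(x), d = ncol(x)),
    class = "hsic_result")
}

#' @export
print.hsic_result <- function(x, ...) {
  cat(sprintf(
    "dHSIC joint-independence test (n=%d, d=%d, %d permutations)\n",
    x$n, x$d, x$n_perm))
  cat(sprintf("  statistic = %.6g, threshold(alpha=%g) = %.6g\n",
              x$statistic, x$alpha, x$threshold))
  cat(sprintf("  permutation p = %.4g -> %s joint independence\n", x$perm_p,
              if (x$reject) "REJECT" else "do not reject"))
  invisible(x)
}

#' Read a numeric p-value table (TSV with header)
#'
#' @param path Path to a tab-separated table of per-site channel p-values.
#' @return A numeric matrix.
#' @export
read_pvalue_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a one-line HSIC report
#'
#' @param result An `"hsic_result"`.
#' @param path Output path for the TSV report (columns `statistic`,
#'   `threshold`, `alpha`, `reject`).
#' @return `path`, invisibly.
#' @export
write_hsic_report <- function(result, path) {
  stopifnot(inherits(result, "hsic_result"))
  writeLines(c("statistic\tthreshold\talpha\treject",
               sprintf("%.10g\t%.10g\t%g\t%s", result$statistic,
                       result$threshold, result$alpha,
                       tolower(result$reject))),
             path)
  invisible(path)
}
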