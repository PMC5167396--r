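# Fisher's combined probability test and Storey-style q-values.

# Upper-tail chi-squared probability at even df = 2k via the closed form
#   P(X >= x) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!
# evaluated in log space for numerical stability. Vectorized over x.
chisq_upper_even <- function(x, k) {
  xh <- pmax(x, 0) / 2
  out <- rep(1, length(xh))
  pos <- xh > 0
  if (any(pos)) {
    lxh <- log(xh[pos])
    j <- seq.int(0L, k - 1L)
    M <- outer(lxh, j) -
      matrix(lgamma(j + 1), nrow = sum(pos), ncol = k, byrow = TRUE)
    mx <- do.call(pmax, c(as.data.frame(M), list(na.rm = TRUE)))
    ls <- mx + log(rowSums(exp(M - mx)))
    out[pos] <- exp(-xh[pos] + ls)
  }
  pmin(pmax(out, MIN_P), 1)
}

#' Fisher's combined probability test
#'
#' Combines k p-values into the statistic `chi2 = -2 * sum(log(p_i))`,
#' referred to a chi-squared distribution with `2k` degrees of freedom
#' (df = 10 for the five scoring channels). The upper-tail probability is
#' evaluated with the even-df closed form
#' `exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!`.
#'
#' @param pvals Numeric vector of k p-values in `(0, 1]`. Values below
#'   `1e-300` (including zeros) are clamped with a warning.
#' @return A list with elements `chi2`, `df` (`= 2k`) and `combined_p`.
#' @examples
#' fisher_combine(rep(0.5, 5))
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) < 1L) stop("need at least one p-value to combine")
  if (any(!is.finite(pvals)) || any(pvals > 1))
    stop("p-values must be finite and <= 1")
  if (any(pvals <= 0))
    warning("non-positive p-value(s) clamped to ", MIN_P)
  p <- pmin(pmax(pvals, MIN_P), 1)
  chi2 <- -2 * sum(log(p))
  list(chi2 = chi2, df = 2L * length(p),
       combined_p = chisq_upper_even(chi2, length(p)))
}

# Row-wise Fisher combination of an n x k matrix of p-values.
fisher_combine_matrix <- function(P) {
  P <- pmin(pmax(P, MIN_P), 1)
  chi2 <- -2 * rowSums(log(P))
  list(chi2 = chi2, df = 2L * ncol(P),
       combined_p = chisq_upper_even(chi2, ncol(P)))
}

#' Estimate the null proportion pi0 by Storey's bootstrap
#'
#' Computes `pi0(lambda) = #(p > lambda) / (m * (1 - lambda))` over a grid
#' of lambda values and picks the lambda whose bootstrap mean squared error
#' against the plug-in minimum of `pi0(lambda)` is smallest.
#'
#' @param pvals Numeric vector of at least 10 p-values in `[0, 1]`.
#' @param lambda_grid Grid of tuning values in `[0, 1)`.
#' @param B Number of bootstrap resamples.
#' @param seed Optional integer seed (the estimate is deterministic given
#'   the seed).
#' @return The estimated null proportion, clamped into `(0, 1]`.
#' @export
estimate_pi0_bootstrap <- function(pvals, lambda_grid = seq(0, 0.90, 0.05),
                                   B = 100L, seed = NULL) {
  m <- length(pvals)
  if (m < 10L) stop("need at least 10 p-values to estimate pi0")
  if (B < 1L) stop("B must be >= 1")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (length(unique(pvals)) == 1L) {
    warning("all p-values identical; falling back to pi0 = 1")
    return(1)
  }
  if (!is.null(seed)) set.seed(seed)
  pi0_fun <- function(p) vapply(lambda_grid,
    function(l) mean(p > l) / (1 - l), numeric(1))
  pi0l <- pi0_fun(pvals)
  target <- min(pi0l)
  mse <- numeric(length(lambda_grid))
  for (b in seq_len(B)) {
    pb <- pvals[sample.int(m, m, replace = TRUE)]
    mse <- mse + (pi0_fun(pb) - target)^2
  }
  pi0 <- pi0l[which.min(mse)]
  min(max(pi0, 1e-8), 1)
}

#' q-values from p-values
#'
#' For sorted p-values `p(1) <= ... <= p(m)`, the q-value of rank i is
#' `min_{j >= i} pi0 * m * p(j) / j`, mapped back to the input order. Ties
#' share a q-value and q is non-decreasing in p.
#'
#' @param pvals Numeric vector of p-values.
#' @param pi0 Null proportion in `(0, 1]` (e.g. from
#'   [estimate_pi0_bootstrap()]).
#' @return Numeric vector of q-values in `(0, 1]`, aligned with `pvals`.
#' @examples
#' compute_qvalues(c(0.01, 0.02, 0.03, 0.04, 1.0), pi0 = 1)
#' @export
compute_qvalues <- function(pvals, pi0 = 1) {
  m <- length(pvals)
  if (m < 1L) stop("need at least one p-value")
  if (!is.numeric(pi0) || pi0 <= 0 || pi0 > 1)
    stop("pi0 must lie in (0, 1]")
  ord <- order(pvals)
  q <- pi0 * m * pvals[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- q
  pmin(pmax(out, MIN_P), 1)
}
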