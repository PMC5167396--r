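# Five scoring channels with exact p-values under a Markov background null.
#
# Every channel reduces to an additive position score matrix; exact null
# distributions are obtained by dynamic programming over a fine discrete
# score grid (n_bins * width levels), so that per-window p-values computed
# from the discretized totals are exact for the discrete statistic. For an
# order-1 background the DP state is (score level, previous base).

CHANNEL_IDS <- c("c1_logodds_uniformbg", "c2_logodds_seqbg",
                 "c3_markov1_weight", "c4_matchsim", "c5_floored_logodds")

MIN_P <- 1e-300

#' Default channel specifications
#'
#' The five channels emulate the diversity of classic motif scanners while
#' sharing one calibrated p-value engine:
#' * `c1_logodds_uniformbg` - log2-odds against a uniform background;
#' * `c2_logodds_seqbg` - log2-odds against the order-0 base composition of
#'   the scanned input;
#' * `c3_markov1_weight` - natural-log motif likelihood (weight score),
#'   calibrated against an order-1 Markov background;
#' * `c4_matchsim` - probability-similarity score (sum of the motif
#'   probabilities of the matched bases) against a uniform background;
#' * `c5_floored_logodds` - natural-log odds with motif probabilities
#'   floored at `prob_floor` before the log, against a uniform background.
#'
#' @param prob_floor Floor applied to motif probabilities in channel c5.
#' @return A named list of five channel specification lists with fields
#'   `channel_id`, `log_base`, `background_mode` and `prob_floor`.
#' @export
channel_specs <- function(prob_floor = 1e-3) {
  specs <- list(
    list(channel_id = "c1_logodds_uniformbg", log_base = 2,
         background_mode = "uniform", prob_floor = 0),
    list(channel_id = "c2_logodds_seqbg", log_base = 2,
         background_mode = "order0_from_input", prob_floor = 0),
    list(channel_id = "c3_markov1_weight", log_base = exp(1),
         background_mode = "order1_from_input", prob_floor = 0),
    list(channel_id = "c4_matchsim", log_base = NA_real_,
         background_mode = "uniform", prob_floor = 0),
    list(channel_id = "c5_floored_logodds", log_base = exp(1),
         background_mode = "uniform", prob_floor = prob_floor))
  names(specs) <- CHANNEL_IDS
  specs
}

required_bg_order <- function(spec) {
  switch(spec$background_mode,
         uniform = 0L, order0_from_input = 0L, order1_from_input = 1L,
         stop("unknown background_mode ", spec$background_mode))
}

#' Build a position-specific scoring matrix for one channel
#'
#' @param m A `"motif"` object.
#' @param bg A `"background_model"` whose order matches the channel's
#'   background mode (order 0 for uniform/order-0 channels, order 1 for the
#'   Markov-weight channel). `NULL` falls back to the uniform background of
#'   the required order.
#' @param spec One channel specification from [channel_specs()].
#' @return An object of class `"pssm"` with fields `channel_id`,
#'   `motif_id`, `width`, `score_matrix`, `min_score`, `max_score`.
#' @export
build_pssm <- function(m, bg = NULL, spec = channel_specs()[[1]]) {
  stopifnot(inherits(m, "motif"))
  need <- required_bg_order(spec)
  if (is.null(bg)) bg <- uniform_background(need)
  stopifnot(inherits(bg, "background_model"))
  if (bg$order != need)
    stop("channel ", spec$channel_id, " needs an order-", need,
         " background, got order ", bg$order)
  p <- m$probs
  sm <- switch(spec$channel_id,
    c1_logodds_uniformbg = log2(p / 0.25),
    c2_logodds_seqbg = sweep(log2(p), 2, log2(bg$marginal), `-`),
    c3_markov1_weight = log(p),
    c4_matchsim = p,
    c5_floored_logodds = log(pmax(p, spec$prob_floor) / 0.25),
    stop("unknown channel_id ", spec$channel_id))
  if (any(!is.finite(sm)))
    stop("non-finite score entry; motif probabilities or background ",
         "must be floored before log transforms")
  dimnames(sm) <- list(NULL, DNA_BASES)
  structure(
    list(channel_id = spec$channel_id, motif_id = m$id, width = m$width,
         score_matrix = sm,
         min_score = sum(apply(sm, 1, min)),
         max_score = sum(apply(sm, 1, max))),
    class = "pssm")
}

# Reverse-complement a PSSM: reverse rows, swap A<->T and C<->G columns.
# Scoring the result on a forward-strand word equals scoring the original
# on the reverse complement of that word.
rc_pssm <- function(pssm) {
  sm <- pssm$score_matrix[rev(seq_len(pssm$width)), c(4L, 3L, 2L, 1L),
                          drop = FALSE]
  colnames(sm) <- DNA_BASES
  pssm$score_matrix <- sm
  pssm
}

#' Score a single window
#'
#' @param pssm A `"pssm"`.
#' @param word ACGT string of length `pssm$width`. A word containing `N`
#'   yields `NA` (the skip signal), not an error.
#' @return The additive score (sum of per-position matrix entries), or `NA`
#'   for windows that must be skipped.
#' @export
score_window <- function(pssm, word) {
  codes <- dna_codes(word)
  if (length(codes) != pssm$width)
    stop("word length ", length(codes), " does not match motif width ",
         pssm$width)
  if (anyNA(codes)) return(NA_real_)
  sum(pssm$score_matrix[cbind(seq_len(pssm$width), codes)])
}

dp_order0 <- function(isc, pb) {
  K <- sum(apply(isc, 1, max))
  v <- numeric(K + 1L)
  v[1L] <- 1
  for (j in seq_len(nrow(isc))) {
    nv <- numeric(K + 1L)
    for (b in 1:4) {
      sh <- isc[j, b]
      idx <- seq_len(K + 1L - sh)
      nv[idx + sh] <- nv[idx + sh] + v[idx] * pb[b]
    }
    v <- nv
  }
  v
}

dp_order1 <- function(isc, cond, init) {
  K <- sum(apply(isc, 1, max))
  V <- matrix(0, nrow = K + 1L, ncol = 4L)
  for (b in 1:4) V[isc[1L, b] + 1L, b] <- V[isc[1L, b] + 1L, b] + init[b]
  w <- nrow(isc)
  if (w >= 2L) for (j in 2:w) {
    M <- V %*% cond            # M[t, b] = sum_prev V[t, prev] P(b | prev)
    NV <- matrix(0, nrow = K + 1L, ncol = 4L)
    for (b in 1:4) {
      sh <- isc[j, b]
      idx <- seq_len(K + 1L - sh)
      NV[idx + sh, b] <- M[idx, b]
    }
    V <- NV
  }
  rowSums(V)
}

#' Exact null distribution of a channel's score
#'
#' Discretizes the score matrix on a fine grid (`n_bins * width` levels
#' across the score range) and computes the exact probability mass function
#' of the discretized window score under the background model by dynamic
#' programming. The survival function drives all p-value lookups.
#'
#' @param pssm A `"pssm"`.
#' @param bg `"background_model"` of the order required by the channel
#'   (`NULL` for uniform).
#' @param n_bins Number of coarse score bins (>= 2); the internal grid is
#'   `n_bins * width` fine levels so that the per-window total-score
#'   rounding error stays below one coarse bin.
#' @return An object of class `"score_distribution"` with fields
#'   `channel_id`, `bin_width`, `offset`, `pmf`, `survival`, plus the
#'   integer score matrix used for consistent window lookups.
#' @export
score_distribution <- function(pssm, bg = NULL, n_bins = 1000L) {
  stopifnot(inherits(pssm, "pssm"))
  if (!is.numeric(n_bins) || n_bins < 2L)
    stop("n_bins must be an integer >= 2")
  n_bins <- as.integer(n_bins)
  if (is.null(bg)) bg <- uniform_background(0L)
  sm <- pssm$score_matrix
  w <- pssm$width
  offsets <- apply(sm, 1, min)
  rel <- sweep(sm, 1, offsets, `-`)
  rng <- sum(apply(rel, 1, max))
  if (rng <= 0) {                       # degenerate: single point mass
    delta <- 1
    isc <- matrix(0L, nrow = w, ncol = 4L)
  } else {
    n_fine <- n_bins * w
    delta <- rng / (n_fine - 1L)
    isc <- matrix(as.integer(round(rel / delta)), nrow = w)
  }
  pmf <- if (bg$order >= 1L) {
    if (bg$order > 1L)
      stop("score distributions support background orders 0 and 1 only")
    dp_order1(isc, bg$cond_probs, bg$marginal)
  } else {
    dp_order0(isc, bg$cond_probs[1L, ])
  }
  pmf <- pmf / sum(pmf)
  survival <- rev(cumsum(rev(pmf)))
  structure(
    list(channel_id = pssm$channel_id, motif_id = pssm$motif_id,
         width = w, bin_width = delta, offset = pssm$min_score,
         max_score = pssm$max_score, pmf = pmf, survival = survival,
         iscore = isc, lookup_slack = as.integer(ceiling(w / 2)) + 1L,
         n_bins = n_bins, bg = bg),
    class = "score_distribution")
}

#' Convert a raw score to an exact p-value
#'
#' Returns the survival probability of the discretized null distribution at
#' the level containing `s`, rounding conservatively downwards by the
#' maximal entry-rounding slack so that the result is an upper bound on the
#' exact tail probability. Scores above the maximum attainable score have
#' an empty tail and are clamped to `1e-300`.
#'
#' @param dist A `"score_distribution"`.
#' @param s Finite numeric score.
#' @return A p-value in `(0, 1]`, non-increasing in `s`.
#' @export
score_to_pvalue <- function(dist, s) {
  stopifnot(inherits(dist, "score_distribution"))
  if (!is.finite(s)) stop("score must be finite")
  if (s > dist$max_score + 1e-9) return(MIN_P)
  if (s < dist$offset) return(1)
  K <- length(dist$survival) - 1L
  k <- floor((s - dist$offset) / dist$bin_width + 1e-9) - dist$lookup_slack
  k <- min(max(k, 0L), K)
  min(max(dist$survival[k + 1L], MIN_P), 1)
}

# Vectorized: integer window totals -> exact p-values.
pvalue_from_total <- function(dist, total) {
  K <- length(dist$survival) - 1L
  pmin(pmax(dist$survival[pmin(pmax(total, 0L), K) + 1L], MIN_P), 1)
}

# Score every window of `codes` (integer codes, NA = ambiguous) with an
# integer or numeric position matrix. Returns a vector of window sums with
# NA where a window touches an ambiguous base.
score_all_windows <- function(mat, codes) {
  w <- nrow(mat)
  n <- length(codes)
  nw <- n - w + 1L
  if (nw < 1L) return(numeric(0))
  isna <- is.na(codes)
  cs <- cumsum(isna)
  bad <- (cs[seq.int(w, n)] - c(0, cs)[seq_len(nw)]) > 0
  codes0 <- ifelse(isna, 1L, codes)
  s <- numeric(nw)
  for (j in seq_len(w)) {
    row <- mat[j, ]
    s <- s + row[codes0[seq.int(j, j + nw - 1L)]]
  }
  s[bad] <- NA
  s
}

#' Scan one sequence with one channel
#'
#' Windows containing `N` are skipped. With `strand_policy = "both"` the
#' minus strand is scored by applying the reverse-complement PSSM to the
#' forward sequence; minus-strand rows report forward coordinates of the
#' covered window, and their p-values come from the reverse-complement
#' PSSM's own null distribution under the same background.
#'
#' @param pssm A `"pssm"`.
#' @param dist The matching `"score_distribution"`.
#' @param seq A [sequence_record()] or plain nucleotide string.
#' @param strand_policy `"both"` or `"forward_only"`.
#' @param rc Optional precomputed list `(pssm, dist)` for the
#'   reverse-complement matrix (computed on the fly when absent).
#' @return A data frame with columns `position0`, `strand`, `score`,
#'   `pvalue`, one row per scored window per strand. Sequences shorter
#'   than the motif yield an empty data frame.
#' @export
scan_channel <- function(pssm, dist, seq,
                         strand_policy = c("both", "forward_only"),
                         rc = NULL) {
  strand_policy <- match.arg(strand_policy)
  if (is.character(seq)) seq <- sequence_record("seq", seq)
  codes <- dna_codes(seq$seq)
  w <- pssm$width
  empty <- data.frame(position0 = integer(0), strand = character(0),
                      score = numeric(0), pvalue = numeric(0))
  if (length(codes) < w) return(empty)

  one_strand <- function(ps, ds, strand) {
    tot <- score_all_windows(ds$iscore, codes)
    sc <- score_all_windows(ps$score_matrix, codes)
    keep <- !is.na(tot)
    if (!any(keep)) return(empty)
    data.frame(position0 = which(keep) - 1L, strand = strand,
               score = sc[keep],
               pvalue = pvalue_from_total(ds, as.integer(tot[keep])))
  }

  out <- one_strand(pssm, dist, "+")
  if (strand_policy == "both") {
    if (is.null(rc)) {
      rcp <- rc_pssm(pssm)
      rc <- list(pssm = rcp,
                 dist = score_distribution(rcp, dist$bg, dist$n_bins))
    }
    out <- rbind(out, one_strand(rc$pssm, rc$dist, "-"))
  }
  out
}
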