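# Shared fixture builders: everything is generated in code, no stored data.

BASES <- c("A", "C", "G", "T")

# Random motif with continuous-valued (gamma) counts, so score distributions
# have many distinct levels and tiny atoms.
rand_motif <- function(width, seed, shape = 0.5, scale = 20) {
  set.seed(seed)
  new_motif(paste0("rand_w", width, "_s", seed),
            matrix(stats::rgamma(4 * width, shape), width, 4) * scale)
}

# High-information motif: one dominant base per position
# (prob ~ (hi + 0.1) / (hi + 3 * lo + 0.4)).
info_motif <- function(width = 10L, hi = 17, lo = 1, seed = 7) {
  set.seed(seed)
  cons <- sample.int(4L, width, replace = TRUE)
  cnt <- matrix(lo, width, 4)
  cnt[cbind(seq_len(width), cons)] <- hi
  m <- new_motif(paste0("info_w", width), cnt)
  attr(m, "consensus_codes") <- cons
  m
}

random_dna <- function(n, seed = NULL, prob = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# All 4^w words as an integer code matrix (one row per word).
all_word_codes <- function(w) {
  as.matrix(rev(expand.grid(rev(rep(list(1:4), w)))))
}

# Word probabilities under an order-0 or order-1 background model.
word_probs <- function(codes, bg) {
  w <- ncol(codes)
  if (bg$order == 0L) {
    p <- bg$cond_probs[1L, ]
    apply(codes, 1, function(cd) prod(p[cd]))
  } else {
    pr <- bg$marginal[codes[, 1]]
    for (j in 2:w)
      pr <- pr * bg$cond_probs[cbind(codes[, j - 1], codes[, j])]
    pr
  }
}

# Sum a per-position matrix over the word codes (exact scores or integer
# totals of every word).
word_sums <- function(mat, codes) {
  s <- numeric(nrow(codes))
  for (j in seq_len(ncol(codes))) s <- s + mat[j, codes[, j]]
  s
}

# n i.i.d. length-w words drawn from a background model, as a code matrix.
sample_word_codes <- function(n, w, bg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (bg$order == 0L)
    return(matrix(sample.int(4L, n * w, replace = TRUE,
                             prob = bg$cond_probs[1L, ]), n, w))
  C <- matrix(0L, n, w)
  C[, 1] <- sample.int(4L, n, replace = TRUE, prob = bg$marginal)
  for (j in 2:w) {
    u <- stats::runif(n)
    cum <- t(apply(bg$cond_probs, 1, cumsum))
    prev <- C[, j - 1]
    C[, j] <- 1L + rowSums(u > cum[prev, , drop = FALSE])
  }
  C
}

# Max ECDF deviation from uniform on [0, 1].
ks_uniform <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(abs(s - seq_len(n) / n), abs(s - (seq_len(n) - 1) / n))
}

# Uniform background of the order a channel spec requires.
bg_for_spec <- function(spec) {
  uniform_background(if (spec$background_mode == "order1_from_input") 1L
                     else 0L)
}
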