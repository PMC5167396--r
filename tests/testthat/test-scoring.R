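# Channel score matrices, exact null distributions and window scanning.

test_that("channel score matrices follow their definitions", {
  m <- new_motif("m", matrix(c(7, 1, 1, 1), 1), pseudocount = 0)
  sp <- channel_specs()
  c1 <- build_pssm(m, NULL, sp$c1_logodds_uniformbg)
  expect_equal(unname(c1$score_matrix[1, ]),
               c(log2(2.8), rep(log2(0.4), 3)), tolerance = 1e-9)
  c4 <- build_pssm(m, NULL, sp$c4_matchsim)
  expect_equal(c4$score_matrix, m$probs)
  # c5 floors a sub-floor motif probability at 1e-3 before the log
  mlow <- new_motif("low", matrix(1, 1, 4),
                    probs = matrix(c(0.0005, 0.9985, 0.0005, 0.0005), 1))
  c5 <- build_pssm(mlow, NULL, sp$c5_floored_logodds)
  expect_equal(unname(c5$score_matrix[1, 1]), log(0.001 / 0.25),
               tolerance = 1e-12)
  # mismatched background order is rejected
  expect_error(build_pssm(m, uniform_background(1), sp$c1_logodds_uniformbg),
               "order")
})

test_that("score_window adds per-position entries and signals N windows", {
  m2 <- new_motif("m2", matrix(c(7, 1, 1, 1, 7, 1, 1, 1), 2, byrow = TRUE),
                  pseudocount = 0)
  ps <- build_pssm(m2, NULL, channel_specs()$c1_logodds_uniformbg)
  expect_equal(score_window(ps, "AA"), 2 * log2(2.8), tolerance = 1e-9)
  expect_equal(score_window(ps, "AC"), log2(2.8) + log2(0.4),
               tolerance = 1e-9)
  expect_true(is.na(score_window(ps, "AN")))
  expect_error(score_window(ps, "AAA"), "width")
})

test_that("two-letter worked example: P(score >= score(AA)) = 1/16", {
  m2 <- new_motif("m2", matrix(c(7, 1, 1, 1, 7, 1, 1, 1), 2, byrow = TRUE),
                  pseudocount = 0)
  ps <- build_pssm(m2, NULL, channel_specs()$c1_logodds_uniformbg)
  ds <- score_distribution(ps, NULL, 1000)
  expect_equal(score_to_pvalue(ds, score_window(ps, "AA")), 0.0625)
  expect_equal(score_to_pvalue(ds, ps$min_score - 1), 1)
  expect_equal(score_to_pvalue(ds, ps$max_score + 1), 1e-300)
  expect_equal(ds$survival[1], 1)
  expect_equal(sum(ds$pmf), 1, tolerance = 1e-9)
  expect_error(score_distribution(ps, NULL, 1), "n_bins")
})

test_that("DP survival matches exhaustive enumeration for all channels", {
  specs <- channel_specs()
  # non-uniform backgrounds exercise the order-0 and order-1 DP paths
  bg_skew0 <- new_background(0, c(0.35, 0.15, 0.2, 0.3))
  set.seed(31)
  cp <- t(apply(matrix(rgamma(16, 2), 4), 1, function(r) r / sum(r)))
  bg_skew1 <- new_background(1, cp, marginal = c(0.3, 0.2, 0.2, 0.3))
  for (seed in c(11, 12)) {
    w <- 3 + (seed %% 3)
    m <- rand_motif(w, seed)
    codes <- all_word_codes(w)
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      bg <- switch(sp$background_mode,
                   uniform = uniform_background(0),
                   order0_from_input = bg_skew0,
                   order1_from_input = bg_skew1)
      ps <- build_pssm(m, bg, sp)
      ds <- score_distribution(ps, bg, 400)
      wp <- word_probs(codes, bg)
      tt <- word_sums(ds$iscore, codes)
      # the DP null of the discretized statistic is exact
      for (t0 in unique(round(stats::quantile(tt, c(0.1, 0.5, 0.9))))) {
        expect_equal(ds$survival[t0 + 1], sum(wp[tt >= t0]),
                     tolerance = 1e-10)
      }
      # score -> p-value lookup is conservative and within one coarse
      # bin's mass of the exact continuous tail
      sc <- word_sums(ps$score_matrix, codes)
      win <- (ds$lookup_slack + ceiling(w / 2) + 2) * ds$bin_width
      idx <- sample(length(sc), 25)
      for (i in idx) {
        pv <- score_to_pvalue(ds, sc[i])
        exact <- sum(wp[sc >= sc[i] - 1e-12])
        slackmass <- sum(wp[sc >= sc[i] - win & sc < sc[i] - 1e-12])
        expect_gte(pv, exact - 1e-10)
        expect_lte(pv - exact, slackmass + 1e-10)
      }
    }
  }
})

test_that("score_to_pvalue is non-increasing in the score", {
  m <- rand_motif(6, 3)
  ps <- build_pssm(m, NULL, channel_specs()$c1_logodds_uniformbg)
  ds <- score_distribution(ps, NULL, 500)
  grid <- seq(ps$min_score - 1, ps$max_score + 1, length.out = 300)
  pv <- vapply(grid, function(s) score_to_pvalue(ds, s), numeric(1))
  expect_true(all(diff(pv) <= 1e-15))
})

test_that("minus-strand hits equal forward hits of the rc motif", {
  m <- rand_motif(7, 21)
  sp <- channel_specs()$c1_logodds_uniformbg
  ps <- build_pssm(m, NULL, sp)
  ds <- score_distribution(ps, NULL, 300)
  seq <- sequence_record("s", random_dna(400, seed = 22))
  both <- scan_channel(ps, ds, seq, "both")
  fwd <- both[both$strand == "+", ]
  minus <- both[both$strand == "-", ]

  rcm <- reverse_complement_motif(m)
  psr <- build_pssm(rcm, NULL, sp)
  dsr <- score_distribution(psr, NULL, 300)
  rc_fwd <- scan_channel(psr, dsr, seq, "forward_only")
  expect_equal(minus$position0, rc_fwd$position0)
  expect_equal(minus$score, rc_fwd$score, tolerance = 1e-9)
  expect_equal(minus$pvalue, rc_fwd$pvalue, tolerance = 1e-12)

  # scanning the reverse complement of the sequence mirrors coordinates
  rseq <- sequence_record("r", revcomp(seq$seq))
  mirror <- scan_channel(ps, ds, rseq, "forward_only")
  L <- nchar(seq$seq)
  expect_equal(sort(L - m$width - mirror$position0), sort(minus$position0))
  expect_equal(sum(mirror$score), sum(minus$score), tolerance = 1e-9)

  # forward_only output is exactly the + subset of both
  fo <- scan_channel(ps, ds, seq, "forward_only")
  expect_equal(fo, fwd, ignore_attr = TRUE)
})

test_that("windows touching N are skipped, short sequences give no hits", {
  m <- rand_motif(4, 5)
  ps <- build_pssm(m, NULL, channel_specs()$c1_logodds_uniformbg)
  ds <- score_distribution(ps, NULL, 300)
  expect_identical(nrow(scan_channel(ps, ds, "ACG", "both")), 0L)
  hits <- scan_channel(ps, ds, "ACGTNACGTA", "forward_only")
  # windows 0..6 exist; 1..4 touch the N at index 4 (0-based)
  expect_setdiff <- setdiff(0:6, hits$position0)
  expect_equal(sort(expect_setdiff), 1:4)
})

test_that("a planted consensus word attains the channel maximum score", {
  m <- info_motif(8, seed = 41)
  cons <- paste(BASES[attr(m, "consensus_codes")], collapse = "")
  sp <- channel_specs()$c1_logodds_uniformbg
  ps <- build_pssm(m, NULL, sp)
  ds <- score_distribution(ps, NULL, 500)
  s <- paste0(random_dna(50, seed = 42), cons, random_dna(50, seed = 43))
  hits <- scan_channel(ps, ds, s, "forward_only")
  expect_equal(max(hits$score), ps$max_score, tolerance = 1e-9)
  expect_equal(hits$position0[which.max(hits$score)], 50L)
})
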