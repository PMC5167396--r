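# Motif parsing, probability conversion and background estimation.

test_that("counts_to_probs applies the pseudocount row-wise", {
  expect_equal(as.numeric(counts_to_probs(matrix(c(7, 1, 1, 1), 1), 0)),
               c(0.7, 0.1, 0.1, 0.1))
  expect_equal(as.numeric(counts_to_probs(matrix(c(7, 1, 1, 1), 1), 1)),
               c(8, 2, 2, 2) / 14)
  expect_equal(as.numeric(counts_to_probs(matrix(0, 1, 4), 1)),
               rep(0.25, 4))
  expect_error(counts_to_probs(matrix(c(-1, 1, 1, 1), 1)), "negative")
  expect_error(counts_to_probs(matrix(0, 1, 4), 0), "zero total")
  for (seed in 1:5) {
    set.seed(seed)
    p <- counts_to_probs(matrix(rgamma(20, 1), 5, 4), runif(1))
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("reverse_complement_motif flips rows/columns and is an involution", {
  m1 <- new_motif("allA", matrix(c(1, 0, 0, 0), 1), pseudocount = 0)
  expect_equal(as.numeric(reverse_complement_motif(m1)$probs), c(0, 0, 0, 1))
  # palindromic probability matrix maps to itself
  pal <- new_motif("pal", rbind(c(4, 1, 2, 3), c(3, 2, 1, 4)),
                   pseudocount = 0)
  expect_equal(reverse_complement_motif(pal)$probs, pal$probs)
  for (seed in 1:5) {
    m <- rand_motif(6, seed)
    expect_equal(reverse_complement_motif(reverse_complement_motif(m)),
                 m)
  }
})

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

meme_fixture <- function() write_tmp(c(
  "MEME version 4", "",
  "ALPHABET= ACGT", "",
  "Background letter frequencies",
  "A 0.25 C 0.25 G 0.25 T 0.25", "",
  "MOTIF M1 alt1",
  "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0",
  " 0.70 0.10 0.10 0.10",
  " 0.10 0.70 0.10 0.10",
  " 0.25 0.25 0.25 0.25",
  " 0.05 0.05 0.05 0.85"))

test_that("MEME records parse to width-4 motifs with unit probability rows", {
  ms <- parse_motifs(meme_fixture(), "meme")
  expect_length(ms, 1)
  m <- ms[[1]]
  expect_s3_class(m, "motif")
  expect_identical(m$id, "M1")
  expect_identical(m$alt_name, "alt1")
  expect_identical(m$width, 4L)
  expect_equal(rowSums(m$probs), rep(1, 4), tolerance = 1e-9)
  expect_equal(m$probs[1, ], c(A = 0.7, C = 0.1, G = 0.1, T = 0.1))
})

jaspar_fixture <- function() write_tmp(c(
  ">MJ1 jaspar_test",
  "A [ 7 0 ]",
  "C [ 1 0 ]",
  "G [ 1 0 ]",
  "T [ 1 10 ]"))

test_that("JASPAR counts parse and normalize as stated", {
  ms <- parse_motifs(jaspar_fixture(), "jaspar", pseudocount = 0)
  m <- ms[[1]]
  expect_identical(m$width, 2L)
  expect_equal(unname(m$counts[, "A"]), c(7, 0))
  expect_equal(unname(m$probs[1, ]), c(0.7, 0.1, 0.1, 0.1))
  expect_equal(unname(m$probs[2, ]), c(0, 0, 0, 1))
})

transfac_fixture <- function() write_tmp(c(
  "AC MT1", "ID MT1", "NA transfac_test",
  "P0      A      C      G      T",
  "01      7      1      1      1      A",
  "02      0      0      0     10      T",
  "XX", "//"))

test_that("TRANSFAC and JASPAR records with the same counts agree", {
  mt <- parse_motifs(transfac_fixture(), "transfac", pseudocount = 0.1)[[1]]
  mj <- parse_motifs(jaspar_fixture(), "jaspar", pseudocount = 0.1)[[1]]
  expect_equal(mt$counts, mj$counts)
  expect_equal(mt$probs, mj$probs)
})

test_that("dialect auto-sniffing and error contracts work", {
  expect_identical(parse_motifs(meme_fixture())[[1]]$id, "M1")
  expect_identical(parse_motifs(jaspar_fixture())[[1]]$id, "MJ1")
  expect_identical(parse_motifs(transfac_fixture())[[1]]$id, "MT1")
  expect_error(parse_motifs(jaspar_fixture(), "nope"), "arg")
  # zero-sum matrix column (= motif position) is a validation error
  bad <- write_tmp(c(">B1", "A [ 0 1 ]", "C [ 0 1 ]", "G [ 0 1 ]",
                     "T [ 0 1 ]"))
  expect_error(parse_motifs(bad, "jaspar"), "zero total")
  expect_error(parse_motifs(write_tmp("gibberish"), "auto"), "dialect")
})

test_that("parse -> serialize -> parse reproduces probabilities to 1e-9", {
  for (fix in list(c("jaspar", jaspar_fixture()),
                   c("transfac", transfac_fixture()),
                   c("meme", meme_fixture()))) {
    m0 <- parse_motifs(fix[2], fix[1])[[1]]
    out <- tempfile(fileext = ".meme")
    write_meme(m0, out)
    m1 <- parse_motifs(out, "meme")[[1]]
    expect_lt(max(abs(m1$probs - m0$probs)), 1e-9)
  }
})

test_that("order-0 background estimation matches base composition", {
  bg <- estimate_background("ACGT", order = 0)
  expect_equal(unname(bg$marginal), rep(0.25, 4))
  bgA <- estimate_background("AAAA", order = 0, floor = 1e-3)
  expect_equal(unname(bgA$marginal["A"]), 1 - 3e-3)
  expect_true(all(bgA$marginal >= 1e-3))
  expect_error(estimate_background(character(0), 0), "no sequence")
  expect_error(estimate_background("ACGT", 3), "unsupported")
  expect_error(estimate_background("NNNN", 0), "unambiguous")
})

test_that("order-1 conditionals match hand-counted transitions", {
  s <- "AACGTACGTAACCGGTTAAC"   # 19 transitions, counted by hand below
  bg <- estimate_background(s, order = 1, floor = 0)
  cnt <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  ch <- strsplit(s, "")[[1]]
  for (i in 2:length(ch)) cnt[ch[i - 1], ch[i]] <- cnt[ch[i - 1], ch[i]] + 1
  expect_equal(unname(bg$cond_probs), unname(cnt / rowSums(cnt)),
               tolerance = 1e-12)
  # every context is a proper distribution even with the floor applied
  bgf <- estimate_background(s, order = 1, floor = 1e-3)
  expect_equal(unname(rowSums(bgf$cond_probs)), rep(1, 4),
               tolerance = 1e-9)
  expect_true(all(bgf$cond_probs >= 1e-3))
})

test_that("ambiguous symbols are skipped in background training", {
  # "ANA": both transitions touch the N and must be dropped
  bg <- estimate_background("ANA", order = 1)
  expect_equal(unname(bg$cond_probs),
               matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_gt(bg$marginal[["A"]], 0.9)
})
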