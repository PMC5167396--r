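# End-to-end scanning, ranking and output formats.

scan_fixture <- function(seq_seed = 11, plant_seed = 12, n_sites = 10,
                         L = 10000, p_threshold = 1e-6) {
  m <- info_motif(10, seed = 7)
  bgrec <- simulate_background(L, seed = seq_seed, name = "chr1")
  pl <- plant_motifs(bgrec, m, n_sites, seed = plant_seed)
  occ <- scan_sequences(m, pl$record,
                        scan_config(p_threshold = p_threshold, seed = 13))
  list(motif = m, truth = pl$truth, record = pl$record, occ = occ)
}

test_that("sequences shorter than the motif give an empty result", {
  m <- info_motif(10, seed = 7)
  expect_warning(occ <- scan_sequences(m, sequence_record("s", "ACGT")),
                 "no scorable window")
  expect_identical(nrow(occ), 0L)
})

test_that("scan recovers planted high-information sites", {
  fx <- scan_fixture()
  hit <- vapply(fx$truth$position0, function(p)
    any(fx$occ$start0 < p + 5 & fx$occ$end0 > p + 5), logical(1))
  expect_gte(mean(hit), 0.8)
  # recovered sites overlap the exact planted windows
  expect_true(all(fx$occ$combined_p <= 1e-6))
})

test_that("per-channel p-values stay calibrated across a background scan", {
  # combined p-values are NOT expected to be calibrated (the five channels
  # score the same word and are positively dependent); the per-channel
  # exactness is the property the engine guarantees. A motif with
  # continuous-valued probabilities keeps the null atoms tiny, so the mean
  # of the (discrete, slightly conservative) p-values is close to 1/2.
  m <- rand_motif(9, 101)
  bgrec <- simulate_background(10000, seed = 31, name = "chr1")
  occ <- scan_sequences(m, bgrec, scan_config(p_threshold = 1, seed = 32))
  expect_gt(nrow(occ), 15000)
  expect_true(all(occ$end0 - occ$start0 == m$width))
  for (cn in paste0("p_c", 1:5)) {
    expect_lt(abs(mean(occ[[cn]]) - 0.5), 0.02)
    expect_lt(abs(mean(occ[[cn]] <= 0.25) - 0.25), 0.03)
  }
})

test_that("output is ranked by combined p with coherent q-values", {
  fx <- scan_fixture()
  occ <- fx$occ
  expect_true(all(diff(occ$combined_p) >= 0))
  expect_true(all(diff(occ$qvalue) >= -1e-15))
  expect_true(all(occ$end0 - occ$start0 == fx$motif$width))
  # q-values were computed over every scored window, not just survivors
  expect_gt(attr(occ, "n_windows")[[fx$motif$id]], 19000)
  # chi2 is consistent with the five channel p-values
  P <- as.matrix(as.data.frame(occ)[, paste0("p_c", 1:5)])
  expect_equal(occ$chi2, unname(-2 * rowSums(log(P))), tolerance = 1e-9)
})

test_that("every minus hit matches a forward hit of the rc motif", {
  m <- info_motif(9, seed = 19)
  bgrec <- simulate_background(3000, seed = 20, name = "chr1")
  cfg <- scan_config(p_threshold = 1e-3, seed = 3)
  occ <- scan_sequences(m, bgrec, cfg)
  occ_rc <- scan_sequences(reverse_complement_motif(m), bgrec, cfg)
  minus <- occ[occ$strand == "-", ]
  plus_rc <- occ_rc[occ_rc$strand == "+", ]
  key <- function(d) paste(d$seq_name, d$start0)
  expect_true(all(key(minus) %in% key(plus_rc)))
  mm <- merge(as.data.frame(minus), as.data.frame(plus_rc),
              by = c("seq_name", "start0"))
  expect_equal(mm$chi2.x, mm$chi2.y, tolerance = 1e-9)
})

test_that("matched words are reported on the motif strand", {
  fx <- scan_fixture()
  occ <- fx$occ
  top <- occ[1, ]
  slice <- substr(fx$record$seq, top$start0 + 1, top$end0)
  expect_identical(top$matched_word,
                   if (top$strand == "-") revcomp(slice) else slice)
})

test_that("text output round-trips numeric fields at 6 significant digits", {
  fx <- scan_fixture()
  f <- tempfile(fileext = ".tsv")
  write_results(fx$occ, "text", f)
  back <- read_results(f)
  expect_identical(nrow(back), nrow(fx$occ))
  expect_identical(back$start0, fx$occ$start0)
  expect_identical(back$end0, fx$occ$end0)
  for (cn in c("chi2", "combined_p", "qvalue", paste0("p_c", 1:5)))
    expect_equal(back[[cn]], signif(fx$occ[[cn]], 6),
                 tolerance = 1e-6 * 2)
  expect_identical(back$matched_word, fx$occ$matched_word)
})

test_that("GFF output uses 1-based closed coordinates", {
  occ <- scan_fixture()$occ
  f <- tempfile(fileext = ".gff")
  write_results(occ, "gff", f)
  gff <- read_intervals(f, "gff")
  expect_equal(gff$start0, occ$start0)
  expect_equal(gff$end0, occ$end0)
  lines <- readLines(f)
  expect_identical(lines[1], "##gff-version 3")
  # GFF score column is -log10(combined p)
  sc <- as.numeric(vapply(strsplit(lines[-1], "\t"), `[`, character(1), 6))
  expect_equal(sc, -log10(occ$combined_p), tolerance = 1e-4)
})

test_that("CisML output is well-formed with the expected structure", {
  occ <- scan_fixture()$occ
  f <- tempfile(fileext = ".xml")
  write_results(occ, "cisml", f)
  doc <- xml2::read_xml(f)
  expect_identical(xml2::xml_name(doc), "cis-element-search")
  pats <- xml2::xml_find_all(doc, ".//pattern")
  expect_length(pats, 1)
  me <- xml2::xml_find_all(doc, ".//pattern/scanned-sequence/matched-element")
  expect_length(me, nrow(occ))
  pv <- as.numeric(xml2::xml_attr(me, "pvalue"))
  expect_equal(sort(pv), sort(signif(occ$combined_p, 6)),
               tolerance = 1e-6 * 2)
  # minus-strand matches have start > stop in CisML convention
  st <- as.integer(xml2::xml_attr(me, "start"))
  en <- as.integer(xml2::xml_attr(me, "stop"))
  expect_true(all((st > en) == (occ$strand == "-")))
})

test_that("all four formats are valid for an empty occurrence set", {
  m <- info_motif(10, seed = 7)
  occ <- suppressWarnings(
    scan_sequences(m, sequence_record("s", random_dna(200, 5)),
                   scan_config(p_threshold = 1e-30)))
  expect_identical(nrow(occ), 0L)
  for (fmt in c("text", "gff", "cisml", "html")) {
    f <- tempfile()
    write_results(occ, fmt, f)
    expect_true(file.exists(f))
  }
  expect_identical(nrow(read_results(
    write_results(occ, "text", tempfile()))), 0L)
  xml2::read_xml(write_results(occ, "cisml", tempfile()))
})

test_that("identical inputs and seed give byte-identical outputs", {
  run <- function() {
    fx <- scan_fixture()
    fs <- c(text = tempfile(), gff = tempfile(), cisml = tempfile())
    for (fmt in names(fs)) write_results(fx$occ, fmt, fs[[fmt]])
    lapply(fs, readLines)
  }
  expect_identical(run(), run())
})
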