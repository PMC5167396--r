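# Seeded synthetic fixtures: background sequences, planted motif sites,
# peak intervals and read profiles with known ground truth.

#' Derive a component sub-seed from a global seed
#'
#' One global seed fans out to per-component seeds through a fixed affine
#' splitting rule modulo `2^31 - 1`, so the component streams are
#' reproducible and decoupled.
#'
#' @param seed Global integer seed.
#' @param k Component index (any non-negative integer).
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
split_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + 1000003 * as.double(k)
  as.integer(s %% 2147483646) + 1L
}

#' Sample a background sequence from a Markov model
#'
#' @param length Sequence length (>= 1).
#' @param bg A `"background_model"` (order 0-2); defaults to uniform.
#' @param seed Optional integer seed.
#' @param name Record name.
#' @return A [sequence_record()].
#' @export
simulate_background <- function(length, bg = uniform_background(0L),
                                seed = NULL, name = "background") {
  if (length < 1L) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(length)
  codes <- integer(n)
  m <- bg$order
  init_n <- min(m, n)
  if (m == 0L) {
    codes <- sample.int(4L, n, replace = TRUE, prob = bg$marginal)
  } else {
    for (i in seq_len(init_n))
      codes[i] <- sample.int(4L, 1L, prob = bg$marginal)
    if (n > m) {
      pow <- 4L^(seq_len(m) - 1L)
      for (i in seq.int(m + 1L, n)) {
        ctx <- 1L + sum((codes[i - seq_len(m)] - 1L) * pow)
        codes[i] <- sample.int(4L, 1L, prob = bg$cond_probs[ctx, ])
      }
    }
  }
  sequence_record(name, paste(DNA_BASES[codes], collapse = ""))
}

#' Plant motif instances into a sequence
#'
#' Chooses `n_sites` non-overlapping positions uniformly at random and
#' replaces each window with a word sampled from the motif's probability
#' rows (reverse-complemented for minus-strand placements).
#'
#' @param seq A [sequence_record()].
#' @param motif A `"motif"`.
#' @param n_sites Number of sites to plant; must satisfy
#'   `n_sites * width <= length / 2`.
#' @param strand_mix Probability that a planted site goes on the minus
#'   strand.
#' @param seed Optional integer seed.
#' @return A list with `record` (the modified sequence) and `truth`, a
#'   data frame `(seq_name, position0, strand, motif_id)` sorted by
#'   position.
#' @export
plant_motifs <- function(seq, motif, n_sites, strand_mix = 0.5,
                         seed = NULL) {
  stopifnot(inherits(seq, "sequence_record"), inherits(motif, "motif"))
  L <- nchar(seq$seq)
  w <- motif$width
  if (n_sites * w > L / 2)
    stop("infeasible packing: n_sites * width exceeds half the sequence")
  if (!is.null(seed)) set.seed(seed)
  truth <- data.frame(seq_name = character(0), position0 = integer(0),
                      strand = character(0), motif_id = character(0))
  if (n_sites == 0L) return(list(record = seq, truth = truth))
  cand <- sample.int(L - w + 1L) - 1L   # candidate starts, random order
  chosen <- integer(0)
  for (p in cand) {
    if (length(chosen) == n_sites) break
    if (all(abs(chosen - p) >= w)) chosen <- c(chosen, p)
  }
  if (length(chosen) < n_sites)
    stop("could not place ", n_sites, " non-overlapping sites")
  chosen <- sort(chosen)
  strands <- ifelse(stats::runif(n_sites) < strand_mix, "-", "+")
  s <- strsplit(seq$seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(n_sites)) {
    word <- vapply(seq_len(w), function(j)
      DNA_BASES[sample.int(4L, 1L, prob = motif$probs[j, ])], character(1))
    word <- paste(word, collapse = "")
    if (strands[i] == "-") word <- revcomp(word)
    s[(chosen[i] + 1L):(chosen[i] + w)] <- strsplit(word, "")[[1]]
  }
  rec <- sequence_record(seq$name, paste(s, collapse = ""),
                         origin = seq$origin)
  truth <- data.frame(seq_name = seq$name, position0 = chosen,
                      strand = strands, motif_id = motif$id,
                      stringsAsFactors = FALSE)
  list(record = rec, truth = truth)
}

#' Simulate treatment/control read counts over intervals
#'
#' Treatment counts are Poisson with rate
#' `base_rate * (1 + enrichment * overlap)`, where `overlap` indicates
#' whether the interval overlaps any planted site; control counts are
#' Poisson with `base_rate` everywhere.
#'
#' @param truth Truth data frame from [plant_motifs()] (may be empty), with
#'   the motif width needed to form site intervals supplied via `width`.
#' @param intervals Interval data frame (`chrom`, `start0`, `end0`).
#' @param width Motif width used to extend truth positions to intervals.
#' @param base_rate Poisson base rate per interval (> 0).
#' @param enrichment Fold enrichment added on truth-overlapping intervals
#'   (>= 0).
#' @param totals Named vector with `treat` and `control` library totals.
#' @param seed Optional integer seed.
#' @return A [read_profile()].
#' @export
simulate_reads <- function(truth, intervals, width, base_rate = 20,
                           enrichment = 10,
                           totals = c(treat = 1e6, control = 1e6),
                           seed = NULL) {
  if (base_rate <= 0) stop("base_rate must be > 0")
  if (enrichment < 0) stop("enrichment must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ov <- if (nrow(truth) > 0L) {
    sites <- data.frame(chrom = truth$seq_name, start0 = truth$position0,
                        end0 = truth$position0 + width)
    overlaps_any(intervals, sites)
  } else rep(FALSE, nrow(intervals))
  treat <- stats::rpois(nrow(intervals),
                        base_rate * (1 + enrichment * ov))
  control <- stats::rpois(nrow(intervals), base_rate)
  read_profile(intervals, treat, control,
               total_treat = max(totals[["treat"]], sum(treat)),
               total_control = max(totals[["control"]], sum(control)))
}

#' Write a complete synthetic fixture set
#'
#' Generates a background sequence with planted motif sites, tiled
#' intervals with simulated treatment/control reads and peak calls at the
#' planted sites, and writes FASTA, MEME, BED and TSV fixtures.
#'
#' @param dir Output directory (created if needed).
#' @param motif A `"motif"` to plant.
#' @param seq_length Background sequence length.
#' @param n_sites Number of planted sites.
#' @param tile_bp Width of the tiled read-count intervals.
#' @param bg Background model for the sequence.
#' @param seed Global seed; component streams are derived with
#'   [split_seed()].
#' @return Invisibly, a list with the generated `record`, `truth`,
#'   `profile`, `peaks` and the file paths.
#' @export
write_fixture_set <- function(dir, motif, seq_length = 10000L,
                              n_sites = 10L, tile_bp = 200L,
                              bg = uniform_background(0L), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- simulate_background(seq_length, bg, seed = split_seed(seed, 1L),
                             name = "synth_chr1")
  pl <- plant_motifs(rec, motif, n_sites, seed = split_seed(seed, 2L))
  starts <- seq.int(0L, seq_length - tile_bp, by = tile_bp)
  tiles <- data.frame(chrom = "synth_chr1", start0 = starts,
                      end0 = starts + tile_bp)
  prof <- simulate_reads(pl$truth, tiles, width = motif$width,
                         seed = split_seed(seed, 3L))
  peaks <- if (nrow(pl$truth)) {
    data.frame(chrom = pl$truth$seq_name,
               start0 = pmax(pl$truth$position0 - 50L, 0L),
               end0 = pl$truth$position0 + motif$width + 50L,
               strand = ".", name = sprintf("peak%d",
                                            seq_len(nrow(pl$truth))))
  } else tiles[0, ]
  paths <- list(
    fasta = file.path(dir, "sequence.fa"),
    motif = file.path(dir, "motif.meme"),
    truth = file.path(dir, "truth.bed"),
    peaks = file.path(dir, "peaks.bed"),
    reads = file.path(dir, "reads.tsv"))
  write_fasta(pl$record, paths$fasta)
  write_meme(motif, paths$motif)
  write_intervals(data.frame(chrom = pl$truth$seq_name,
                             start0 = pl$truth$position0,
                             end0 = pl$truth$position0 + motif$width,
                             strand = pl$truth$strand,
                             name = pl$truth$motif_id),
                  paths$truth, "bed")
  write_intervals(peaks, paths$peaks, "bed")
  write_read_profile(prof, paths$reads)
  invisible(list(record = pl$record, truth = pl$truth, profile = prof,
                 peaks = peaks, paths = paths))
}
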