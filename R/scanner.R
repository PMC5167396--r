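# End-to-end scanning: five channels per window per strand, Fisher fusion,
# q-values, ranked output in text / GFF3 / CisML / HTML.

#' Scan configuration
#'
#' @param p_threshold Report threshold on the combined p-value (default
#'   1e-4; genome-scale runs typically use far stricter cutoffs).
#' @param q_threshold Optional additional threshold on the q-value.
#' @param strand_policy `"both"` or `"forward_only"`.
#' @param n_bins Number of coarse score bins for the null distributions.
#' @param background_mode `"auto"` estimates order-0 and order-1
#'   backgrounds from the scanned sequences; `"uniform"` uses uniform
#'   backgrounds for every channel.
#' @param prob_floor Motif probability floor for channel c5.
#' @param seed Integer seed used for the pi0 bootstrap.
#' @return A list of class `"scan_config"`.
#' @export
scan_config <- function(p_threshold = 1e-4, q_threshold = NULL,
                        strand_policy = c("both", "forward_only"),
                        n_bins = 1000L,
                        background_mode = c("auto", "uniform"),
                        prob_floor = 1e-3, seed = 17L) {
  strand_policy <- match.arg(strand_policy)
  background_mode <- match.arg(background_mode)
  if (!(p_threshold > 0 && p_threshold <= 1))
    stop("p_threshold must lie in (0, 1]")
  if (!is.null(q_threshold) && !(q_threshold > 0 && q_threshold <= 1))
    stop("q_threshold must lie in (0, 1]")
  structure(list(p_threshold = p_threshold, q_threshold = q_threshold,
                 strand_policy = strand_policy, n_bins = n_bins,
                 background_mode = background_mode,
                 prob_floor = prob_floor, seed = seed),
            class = "scan_config")
}

occurrence_columns <- function() {
  c("motif_id", "seq_name", "start0", "end0", "strand", "matched_word",
    paste0("s_c", 1:5), paste0("p_c", 1:5), "chi2", "combined_p", "qvalue")
}

empty_occurrences <- function() {
  df <- data.frame(motif_id = character(0), seq_name = character(0),
                   start0 = integer(0), end0 = integer(0),
                   strand = character(0), matched_word = character(0))
  for (nm in c(paste0("s_c", 1:5), paste0("p_c", 1:5),
               "chi2", "combined_p", "qvalue"))
    df[[nm]] <- numeric(0)
  df
}

#' Scan sequences with motifs through all five channels
#'
#' For every N-free window on every scanned strand, the five channel
#' p-values are combined with Fisher's test (chi-squared, 10 df);
#' q-values are computed per motif over the combined p-values of *all*
#' evaluated windows (not just reported survivors); occurrences with
#' `combined_p <= p_threshold` (and, when set, `qvalue <= q_threshold`)
#' are returned sorted by ascending combined p-value with deterministic
#' tie-breaking by `(seq_name, start0, strand, motif_id)`.
#'
#' @param motifs A `"motif"` or list of motifs.
#' @param sequences A [sequence_record()], list of records, or named
#'   character vector of sequences.
#' @param config A [scan_config()].
#' @return A data frame of motif occurrences (class
#'   `"motif_occurrences"`) with per-channel scores `s_c1..s_c5`,
#'   per-channel p-values `p_c1..p_c5`, `chi2`, `combined_p` and `qvalue`.
#'   The attribute `n_windows` records the number of scored window/strand
#'   tests per motif.
#' @export
scan_sequences <- function(motifs, sequences, config = scan_config()) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  if (length(motifs) < 1L) stop("need at least one motif")
  if (inherits(sequences, "sequence_record")) sequences <- list(sequences)
  if (is.character(sequences)) {
    nms <- if (is.null(names(sequences)))
      paste0("seq", seq_along(sequences)) else names(sequences)
    sequences <- mapply(sequence_record, nms, sequences, SIMPLIFY = FALSE)
  }
  if (length(sequences) < 1L) stop("need at least one sequence")

  if (config$background_mode == "uniform") {
    bg0 <- uniform_background(0L)
    bg1 <- uniform_background(1L)
  } else {
    # Estimate from both strands so the background is complement-symmetric:
    # the reverse-complement PSSM then has exactly the mirrored null, and
    # minus-strand hits coincide with forward hits of the rc motif.
    seq_strs <- vapply(sequences, `[[`, character(1), "seq")
    both <- c(seq_strs, vapply(seq_strs, revcomp, character(1),
                               USE.NAMES = FALSE))
    bg0 <- estimate_background(both, order = 0L)
    bg1 <- estimate_background(both, order = 1L)
  }
  specs <- channel_specs(prob_floor = config$prob_floor)
  bg_for <- function(spec) switch(spec$background_mode,
    uniform = if (required_bg_order(spec) == 0L) uniform_background(0L)
              else uniform_background(1L),
    order0_from_input = bg0,
    order1_from_input = bg1)

  results <- list()
  n_windows <- integer(0)
  for (m in motifs) {
    engines <- lapply(specs, function(sp) {
      bg <- bg_for(sp)
      ps <- build_pssm(m, bg, sp)
      ds <- score_distribution(ps, bg, config$n_bins)
      rc <- NULL
      if (config$strand_policy == "both") {
        rcp <- rc_pssm(ps)
        rc <- list(pssm = rcp,
                   dist = score_distribution(rcp, bg, config$n_bins))
      }
      list(pssm = ps, dist = ds, rc = rc)
    })
    per_seq <- list()
    for (sr in sequences) {
      hits <- lapply(engines, function(en)
        scan_channel(en$pssm, en$dist, sr, config$strand_policy,
                     rc = en$rc))
      base <- hits[[1L]]
      if (nrow(base) == 0L) next
      S <- vapply(hits, `[[`, numeric(nrow(base)), "score")
      P <- vapply(hits, `[[`, numeric(nrow(base)), "pvalue")
      if (nrow(base) == 1L) { S <- matrix(S, 1L); P <- matrix(P, 1L) }
      df <- data.frame(motif_id = m$id, seq_name = sr$name,
                       start0 = base$position0,
                       end0 = base$position0 + m$width,
                       strand = base$strand,
                       matched_word = NA_character_,
                       stringsAsFactors = FALSE)
      colnames(S) <- paste0("s_c", 1:5)
      colnames(P) <- paste0("p_c", 1:5)
      per_seq[[length(per_seq) + 1L]] <- cbind(df, S, P)
    }
    if (length(per_seq) == 0L) {
      n_windows[m$id] <- 0L
      next
    }
    occ <- do.call(rbind, per_seq)
    fc <- fisher_combine_matrix(as.matrix(occ[, paste0("p_c", 1:5)]))
    occ$chi2 <- fc$chi2
    occ$combined_p <- fc$combined_p
    pi0 <- if (nrow(occ) >= 10L)
      estimate_pi0_bootstrap(occ$combined_p, seed = config$seed) else 1
    occ$qvalue <- compute_qvalues(occ$combined_p, pi0)
    n_windows[m$id] <- nrow(occ)
    keep <- occ$combined_p <= config$p_threshold
    if (!is.null(config$q_threshold))
      keep <- keep & occ$qvalue <= config$q_threshold
    occ <- occ[keep, , drop = FALSE]
    if (nrow(occ) > 0L) {
      seq_map <- vapply(sequences, `[[`, character(1), "seq")
      names(seq_map) <- vapply(sequences, `[[`, character(1), "name")
      word <- substr(seq_map[occ$seq_name], occ$start0 + 1L, occ$end0)
      minus <- occ$strand == "-"
      if (any(minus))
        word[minus] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(word[minus])))
      occ$matched_word <- unname(word)
    }
    results[[length(results) + 1L]] <- occ
  }
  out <- if (length(results)) do.call(rbind, results) else empty_occurrences()
  if (nrow(out) == 0L) {
    if (sum(n_windows) == 0L)
      warning("no scorable window (sequences shorter than the motifs?)")
    out <- empty_occurrences()
  } else {
    out <- out[order(out$combined_p, out$seq_name, out$start0, out$strand,
                     out$motif_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, n_windows = n_windows,
            class = c("motif_occurrences", "data.frame"))
}

fmt_num <- function(x) sprintf("%.6g", x)

#' Write ranked motif occurrences
#'
#' @param occurrences Data frame from [scan_sequences()] (already ranked).
#' @param format One of `"text"` (TSV, 1-based closed coordinates),
#'   `"gff"` (GFF3, score column `-log10(combined_p)`), `"cisml"`
#'   (CisML-style XML) or `"html"` (static ranked table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(occurrences,
                          format = c("text", "gff", "cisml", "html"),
                          path) {
  format <- match.arg(format)
  occ <- as.data.frame(occurrences)
  switch(format,
    text = write_results_text(occ, path),
    gff = write_results_gff(occ, path),
    cisml = write_results_cisml(occ, path),
    html = write_results_html(occ, path))
  invisible(path)
}

write_results_text <- function(occ, path) {
  hdr <- paste(c("motif_id", "seq_name", "start", "stop", "strand", "chi2",
                 "combined_p", "qvalue", "matched_word",
                 paste0("p_c", 1:5)), collapse = "\t")
  body <- if (nrow(occ)) {
    pcols <- vapply(paste0("p_c", 1:5), function(cn) fmt_num(occ[[cn]]),
                    character(nrow(occ)))
    if (nrow(occ) == 1L) pcols <- matrix(pcols, 1L)
    apply(cbind(occ$motif_id, occ$seq_name, occ$start0 + 1L, occ$end0,
                occ$strand, fmt_num(occ$chi2), fmt_num(occ$combined_p),
                fmt_num(occ$qvalue), occ$matched_word, pcols),
          1, paste, collapse = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
}

#' Read back a text results file
#'
#' @param path Path written by `write_results(..., format = "text")`.
#' @return A data frame with internal 0-based half-open coordinates.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$start0 <- df$start - 1L
  df$end0 <- df$stop
  df$start <- df$stop <- NULL
  df
}

write_results_gff <- function(occ, path) {
  lines <- "##gff-version 3"
  if (nrow(occ)) {
    attrs <- sprintf(
      "ID=occ%d;Name=%s;pvalue=%s;qvalue=%s;sequence=%s",
      seq_len(nrow(occ)), occ$motif_id, fmt_num(occ$combined_p),
      fmt_num(occ$qvalue), occ$matched_word)
    lines <- c(lines, sprintf(
      "%s\tfusemotif\tnucleotide_motif\t%d\t%d\t%s\t%s\t.\t%s",
      occ$seq_name, occ$start0 + 1L, occ$end0,
      fmt_num(-log10(occ$combined_p)), occ$strand, attrs))
  }
  writeLines(lines, path)
}

write_results_cisml <- function(occ, path) {
  doc <- xml2::xml_new_root("cis-element-search")
  xml2::xml_add_child(doc, "program-name", "fusemotif")
  xml2::xml_add_child(doc, "parameters")
  if (nrow(occ)) {
    for (mid in unique(occ$motif_id)) {
      mocc <- occ[occ$motif_id == mid, , drop = FALSE]
      pat <- xml2::xml_add_child(doc, "pattern", accession = mid,
                                 name = mid)
      for (sq in unique(mocc$seq_name)) {
        socc <- mocc[mocc$seq_name == sq, , drop = FALSE]
        scanned <- xml2::xml_add_child(pat, "scanned-sequence",
                                       accession = sq, name = sq)
        for (r in seq_len(nrow(socc))) {
          # CisML convention: minus-strand matches have start > stop
          st <- socc$start0[r] + 1L
          en <- socc$end0[r]
          if (socc$strand[r] == "-") { tmp <- st; st <- en; en <- tmp }
          me <- xml2::xml_add_child(
            scanned, "matched-element",
            start = as.character(st), stop = as.character(en),
            score = fmt_num(socc$chi2[r]),
            pvalue = fmt_num(socc$combined_p[r]))
          xml2::xml_add_child(me, "qvalue", fmt_num(socc$qvalue[r]))
          xml2::xml_add_child(me, "sequence", socc$matched_word[r])
        }
      }
    }
  }
  xml2::write_xml(doc, path)
}

write_results_html <- function(occ, path) {
  rows <- if (nrow(occ)) {
    sprintf(paste0("<tr><td>%s</td><td>%s</td><td>%d</td><td>%d</td>",
                   "<td>%s</td><td>%s</td><td>%s</td><td>%s</td>",
                   "<td>%s</td></tr>"),
            occ$motif_id, occ$seq_name, occ$start0 + 1L, occ$end0,
            occ$strand, fmt_num(occ$chi2), fmt_num(occ$combined_p),
            fmt_num(occ$qvalue), occ$matched_word)
  } else character(0)
  writeLines(c(
    "<!DOCTYPE html>", "<html><head><title>fusemotif results</title>",
    "</head><body>", "<h1>Ranked motif occurrences</h1>",
    "<table border=\"1\">",
    paste0("<tr><th>motif</th><th>sequence</th><th>start</th>",
           "<th>stop</th><th>strand</th><th>chi2</th><th>p-value</th>",
           "<th>q-value</th><th>site</th></tr>"),
    rows, "</table>", "</body></html>"), path)
}
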