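# Motif matrices and background models.
#
# Column order is fixed as A,C,G,T everywhere in the package; dialects that
# write other orders are remapped at parse time.

DNA_BASES <- c("A", "C", "G", "T")

#' Convert a count matrix to a probability matrix
#'
#' Applies an additive pseudocount and row-normalizes, so that each motif
#' position becomes a proper distribution over A,C,G,T.
#'
#' @param counts Numeric matrix with one row per motif position and four
#'   columns in A,C,G,T order. Entries must be non-negative; they may be
#'   real-valued (e.g. probability rows scaled by a site count).
#' @param pseudocount Non-negative value added to every cell before
#'   normalization. The default 0.1 keeps probabilities strictly positive so
#'   log-odds scores stay finite.
#' @return A `width x 4` matrix whose rows each sum to 1.
#' @examples
#' counts_to_probs(matrix(c(7, 1, 1, 1), 1), pseudocount = 0)
#' @export
counts_to_probs <- function(counts, pseudocount = 0.1) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (ncol(counts) != 4L)
    stop("count matrix must have 4 columns (A,C,G,T)")
  if (any(!is.finite(counts)))
    stop("count matrix contains non-finite values")
  if (any(counts < 0))
    stop("negative count in motif matrix")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  denom <- rowSums(counts) + 4 * pseudocount
  if (any(denom <= 0))
    stop("motif position with zero total count and zero pseudocount")
  p <- (counts + pseudocount) / denom
  dimnames(p) <- list(NULL, DNA_BASES)
  p
}

#' Construct a motif object
#'
#' @param id Motif identifier.
#' @param counts `width x 4` non-negative matrix (A,C,G,T columns).
#' @param alt_name Optional alternative name.
#' @param pseudocount Pseudocount used to derive `probs` from `counts`
#'   (ignored when `probs` is supplied directly).
#' @param probs Optional pre-computed probability matrix; when given it is
#'   stored as-is (rows must sum to 1).
#' @return An object of class `"motif"` with fields `id`, `alt_name`,
#'   `width`, `counts` and `probs`.
#' @export
new_motif <- function(id, counts, alt_name = NULL, pseudocount = 0.1,
                      probs = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (ncol(counts) != 4L)
    stop("motif matrix must have 4 columns (A,C,G,T)")
  if (any(counts < 0)) stop("negative count in motif matrix")
  colnames(counts) <- DNA_BASES
  if (is.null(probs)) {
    probs <- counts_to_probs(counts, pseudocount)
  } else {
    probs <- as.matrix(probs)
    colnames(probs) <- DNA_BASES
    if (nrow(probs) != nrow(counts))
      stop("counts and probs must have the same number of rows")
    if (max(abs(rowSums(probs) - 1)) > 1e-6)
      stop("probability rows must sum to 1")
  }
  structure(
    list(id = as.character(id),
         alt_name = if (is.null(alt_name) || is.na(alt_name)) NULL
                    else as.character(alt_name),
         width = nrow(counts),
         counts = counts,
         probs = probs),
    class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif %s%s width=%d>\n", x$id,
              if (!is.null(x$alt_name)) paste0(" (", x$alt_name, ")") else "",
              x$width))
  print(round(x$probs, 4))
  invisible(x)
}

#' Reverse-complement a motif
#'
#' Rows are reversed and the A/T and C/G columns swapped, for both the count
#' and the probability matrix. Applying the operation twice returns the
#' original motif.
#'
#' @param m A `"motif"` object.
#' @return The reverse-complement `"motif"`.
#' @export
reverse_complement_motif <- function(m) {
  stopifnot(inherits(m, "motif"))
  flip <- function(x) {
    y <- x[rev(seq_len(nrow(x))), c(4L, 3L, 2L, 1L), drop = FALSE]
    colnames(y) <- DNA_BASES
    y
  }
  m$counts <- flip(m$counts)
  m$probs <- flip(m$probs)
  m
}

## ---------------------------------------------------------------------------
## Parsing

sniff_dialect <- function(lines) {
  if (any(grepl("^MEME version", lines))) return("meme")
  if (any(grepl("^P[O0]\\b", lines)) || any(grepl("^//", lines)))
    return("transfac")
  if (any(startsWith(lines, ">"))) return("jaspar")
  stop("cannot determine motif dialect from file header")
}

#' Parse motifs from MEME, JASPAR or TRANSFAC files
#'
#' @param path Path to the motif file.
#' @param dialect One of `"auto"`, `"meme"`, `"jaspar"`, `"transfac"`.
#'   `"auto"` sniffs by header tokens (MEME version line, TRANSFAC `P0`
#'   row, JASPAR `>` record).
#' @param pseudocount Pseudocount used when converting counts to
#'   probabilities (see [counts_to_probs()]). MEME records already carrying
#'   a strictly positive probability matrix are renormalized without
#'   additional smoothing, so serialized motifs round-trip exactly.
#' @return A list of `"motif"` objects in file order.
#' @export
parse_motifs <- function(path, dialect = c("auto", "meme", "jaspar",
                                           "transfac"),
                         pseudocount = 0.1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") dialect <- sniff_dialect(lines)
  out <- switch(dialect,
    meme = parse_meme(lines, pseudocount),
    jaspar = parse_jaspar(lines, pseudocount),
    transfac = parse_transfac(lines, pseudocount))
  if (length(out) == 0L) stop("no motif records found in ", path)
  out
}

check_position_sums <- function(mat, what) {
  if (any(rowSums(mat) == 0))
    stop("motif ", what, " has a position (matrix column) with zero total")
}

parse_meme <- function(lines, pseudocount) {
  motif_at <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    i <- motif_at[k]
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) < 2L)
      stop("MEME format error at line ", i, ": MOTIF line without an id")
    id <- toks[2]
    alt <- if (length(toks) >= 3L) toks[3] else NULL
    stop_at <- if (k < length(motif_at)) motif_at[k + 1] - 1L
               else length(lines)
    block <- grep("letter-probability matrix", lines[i:stop_at]) + i - 1L
    if (length(block) == 0L)
      stop("MEME format error: motif ", id,
           " has no letter-probability matrix (line ", i, ")")
    hdr <- lines[block[1]]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    nsites <- suppressWarnings(
      as.numeric(sub(".*\\bnsites=\\s*([0-9.eE+-]+).*", "\\1", hdr)))
    if (is.na(w))
      stop("MEME format error at line ", block[1], ": missing w= field")
    rows <- character(0)
    j <- block[1] + 1L
    while (length(rows) < w && j <= length(lines)) {
      ln <- trimws(lines[j])
      if (nzchar(ln)) rows <- c(rows, ln)
      j <- j + 1L
    }
    if (length(rows) < w)
      stop("MEME format error: motif ", id, " matrix truncated")
    mat <- t(vapply(seq_along(rows), function(r) {
      v <- suppressWarnings(as.numeric(strsplit(rows[r], "\\s+")[[1]]))
      if (length(v) != 4L || any(is.na(v)))
        stop("MEME format error at line ", block[1] + r,
             ": expected 4 numeric letter probabilities")
      v
    }, numeric(4)))
    check_position_sums(mat, id)
    ns <- if (is.na(nsites) || nsites <= 0) 20 else nsites
    if (all(mat > 0)) {
      probs <- mat / rowSums(mat)
      counts <- mat * ns
      motifs[[k]] <- new_motif(id, counts, alt, probs = probs)
    } else {
      motifs[[k]] <- new_motif(id, mat * ns, alt, pseudocount = pseudocount)
    }
  }
  motifs
}

parse_jaspar <- function(lines, pseudocount) {
  rec_at <- which(startsWith(lines, ">"))
  if (length(rec_at) == 0L) stop("JASPAR format error: no '>' record header")
  motifs <- vector("list", length(rec_at))
  for (k in seq_along(rec_at)) {
    i <- rec_at[k]
    hdr <- strsplit(trimws(sub("^>", "", lines[i])), "\\s+")[[1]]
    id <- hdr[1]
    alt <- if (length(hdr) >= 2L) paste(hdr[-1], collapse = " ") else NULL
    body <- character(0)
    j <- i + 1L
    while (j <= length(lines) && !startsWith(lines[j], ">")) {
      if (nzchar(trimws(lines[j]))) body <- c(body, lines[j])
      j <- j + 1L
    }
    if (length(body) != 4L)
      stop("JASPAR format error near line ", i, ": motif ", id,
           " must have exactly 4 base rows, found ", length(body))
    letters <- character(4)
    rows <- vector("list", 4)
    for (r in 1:4) {
      ln <- gsub("[][]", " ", body[r])
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (toupper(toks[1]) %in% DNA_BASES) {
        letters[r] <- toupper(toks[1])
        toks <- toks[-1]
      }
      v <- suppressWarnings(as.numeric(toks))
      if (length(v) == 0L || any(is.na(v)))
        stop("JASPAR format error: non-numeric row for motif ", id)
      rows[[r]] <- v
    }
    if (length(unique(lengths(rows))) != 1L)
      stop("JASPAR format error: ragged matrix for motif ", id)
    mat4 <- do.call(rbind, rows)
    if (all(nzchar(letters))) {
      if (!setequal(letters, DNA_BASES))
        stop("JASPAR format error: row letters must be A,C,G,T for ", id)
      mat4 <- mat4[match(DNA_BASES, letters), , drop = FALSE]
    }
    counts <- t(mat4)
    check_position_sums(counts, id)
    motifs[[k]] <- new_motif(id, counts, alt, pseudocount = pseudocount)
  }
  motifs
}

parse_transfac <- function(lines, pseudocount) {
  recs <- split(lines, cumsum(grepl("^//", c("", lines[-length(lines)]))))
  motifs <- list()
  for (rec in recs) {
    po <- grep("^P[O0]\\b", rec)
    if (length(po) == 0L) next
    get_field <- function(tag) {
      at <- grep(paste0("^", tag, "\\b"), rec)
      if (length(at) == 0L) return(NULL)
      val <- trimws(sub(paste0("^", tag, "\\s*"), "", rec[at[1]]))
      if (nzchar(val)) val else NULL
    }
    id <- get_field("ID")
    if (is.null(id)) id <- get_field("AC")
    if (is.null(id)) id <- "transfac_motif"
    alt <- get_field("NA")
    hdr <- strsplit(trimws(rec[po[1]]), "\\s+")[[1]][-1]
    hdr <- toupper(hdr[seq_len(min(4L, length(hdr)))])
    if (!setequal(hdr, DNA_BASES))
      stop("TRANSFAC format error: P0 header of ", id,
           " must list A, C, G, T")
    row_at <- grep("^\\s*[0-9]+\\s", rec)
    row_at <- row_at[row_at > po[1]]
    if (length(row_at) == 0L)
      stop("TRANSFAC format error: motif ", id, " has no matrix rows")
    mat <- t(vapply(row_at, function(r) {
      toks <- strsplit(trimws(rec[r]), "\\s+")[[1]][-1]
      v <- suppressWarnings(as.numeric(toks[1:4]))
      if (any(is.na(v)))
        stop("TRANSFAC format error: bad matrix row '", rec[r],
             "' in motif ", id)
      v
    }, numeric(4)))
    mat <- mat[, match(DNA_BASES, hdr), drop = FALSE]
    check_position_sums(mat, id)
    motifs[[length(motifs) + 1L]] <-
      new_motif(id, mat, alt, pseudocount = pseudocount)
  }
  motifs
}

#' Serialize motifs in MEME minimal format
#'
#' Writes the probability matrices (10 significant digits, so a
#' parse/serialize/parse round trip preserves probabilities to well under
#' 1e-9) with `nsites` recording the original count total.
#'
#' @param motifs A `"motif"` or list of them.
#' @param path Output path.
#' @param background Length-4 background frequencies written in the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  out <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           paste(sprintf("%s %.6f", DNA_BASES, background), collapse = " "),
           "")
  for (m in motifs) {
    nsites <- max(1, round(sum(m$counts[1, ])))
    out <- c(out,
      paste(c("MOTIF", m$id, m$alt_name), collapse = " "),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              m$width, nsites),
      apply(m$probs, 1, function(r)
        paste(sprintf("%.10f", r), collapse = "  ")),
      "")
  }
  writeLines(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Background models

# Raise entries below `floor` to `floor` and rescale the rest so the vector
# still sums to 1 and no entry drops below the floor.
floor_renorm <- function(p, floor_val) {
  if (floor_val <= 0) return(p / sum(p))
  for (it in 1:8) {
    low <- p < floor_val
    if (!any(low)) break
    if (all(low)) return(rep(1 / length(p), length(p)))
    p[low] <- floor_val
    keep <- !low
    p[keep] <- p[keep] * (1 - sum(low) * floor_val) / sum(p[keep])
  }
  p / sum(p)
}

all_contexts <- function(order) {
  if (order == 0L) return("")
  do.call(paste0, rev(expand.grid(rep(list(DNA_BASES), order))[
    , seq_len(order), drop = FALSE]))
}

#' Construct a background model from explicit conditional probabilities
#'
#' @param order Markov order (0, 1 or 2).
#' @param cond_probs `4^order x 4` matrix of conditional probabilities with
#'   context strings as row names, or a length-4 vector for order 0.
#' @param marginal Length-4 marginal base distribution used to start chains
#'   and as the order-0 view of the model; defaults to the mean of
#'   `cond_probs` rows.
#' @param floor Probability floor recorded with the model.
#' @return An object of class `"background_model"`.
#' @export
new_background <- function(order, cond_probs, marginal = NULL,
                           floor = 1e-3) {
  order <- as.integer(order)
  if (order < 0L || order > 2L) stop("background order must be 0, 1 or 2")
  if (is.null(dim(cond_probs))) cond_probs <- matrix(cond_probs, nrow = 1)
  cond_probs <- as.matrix(cond_probs)
  if (nrow(cond_probs) != 4^order || ncol(cond_probs) != 4L)
    stop("cond_probs must be a ", 4^order, " x 4 matrix for order ", order)
  if (max(abs(rowSums(cond_probs) - 1)) > 1e-6)
    stop("conditional probability rows must sum to 1")
  rownames(cond_probs) <- all_contexts(order)
  colnames(cond_probs) <- DNA_BASES
  if (is.null(marginal)) marginal <- colMeans(cond_probs)
  marginal <- marginal / sum(marginal)
  names(marginal) <- DNA_BASES
  structure(list(order = order, cond_probs = cond_probs,
                 marginal = marginal, floor = floor),
            class = "background_model")
}

#' Uniform background model
#'
#' @param order Markov order of the returned model (all conditionals 0.25).
#' @return A `"background_model"`.
#' @export
uniform_background <- function(order = 0L) {
  new_background(order, matrix(0.25, nrow = 4^order, ncol = 4),
                 marginal = rep(0.25, 4), floor = 0)
}

#' Estimate a Markov background model from sequences
#'
#' Counts (context, base) transitions across the supplied sequences.
#' Windows containing ambiguous (non-ACGT) symbols are skipped rather than
#' distributed fractionally. Conditional distributions are floored at
#' `floor` and renormalized so log-odds scores stay finite even for skewed
#' training data; contexts never observed fall back to the uniform
#' distribution.
#'
#' @param sequences Character vector of nucleotide strings, or a list of
#'   sequence records as returned by [read_fasta()].
#' @param order Markov order: 0 (base composition), 1 or 2.
#' @param floor Probability floor applied per conditional distribution.
#' @return A `"background_model"`.
#' @export
estimate_background <- function(sequences, order = 0L, floor = 1e-3) {
  order <- as.integer(order)
  if (order < 0L) stop("background order must be non-negative")
  if (order > 2L) stop("unsupported background order ", order, " (max 2)")
  seqs <- as_sequence_strings(sequences)
  if (length(seqs) == 0L || all(!nzchar(seqs)))
    stop("no sequence data to estimate a background from")
  codes_list <- lapply(seqs, dna_codes)
  base_tab <- numeric(4)
  for (cd in codes_list) {
    ok <- cd[!is.na(cd)]
    if (length(ok)) base_tab <- base_tab + tabulate(ok, 4L)
  }
  if (sum(base_tab) == 0)
    stop("no unambiguous nucleotides in background training sequences")
  marginal <- floor_renorm(base_tab / sum(base_tab), floor)
  names(marginal) <- DNA_BASES
  if (order == 0L)
    return(new_background(0L, marginal, marginal = marginal, floor = floor))

  ncx <- 4L^order
  trans <- matrix(0, nrow = ncx, ncol = 4L)
  pow <- 4L^(seq_len(order) - 1L)
  for (cd in codes_list) {
    n <- length(cd)
    if (n <= order) next
    pos <- seq.int(order + 1L, n)
    ctx <- rep(1L, length(pos))
    bad <- is.na(cd[pos])
    for (k in seq_len(order)) {
      prev <- cd[pos - k]
      bad <- bad | is.na(prev)
      ctx <- ctx + (ifelse(is.na(prev), 0L, prev) - 1L) * pow[k]
    }
    keep <- !bad
    if (any(keep)) {
      lin <- (ctx[keep] - 1L) * 4L + cd[pos[keep]]
      trans <- trans + matrix(tabulate(lin, ncx * 4L), nrow = ncx,
                              byrow = TRUE)
    }
  }
  cond <- t(apply(trans, 1, function(row) {
    if (sum(row) == 0) rep(0.25, 4) else floor_renorm(row / sum(row), floor)
  }))
  new_background(order, cond, marginal = marginal, floor = floor)
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model order=%d floor=%g>\n", x$order, x$floor))
  print(round(x$cond_probs, 4))
  invisible(x)
}
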