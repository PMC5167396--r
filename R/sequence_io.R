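# FASTA / BED / GFF input and strand utilities.
#
# Internal coordinates are exclusively 0-based half-open; conversion happens
# only at I/O boundaries (BED is already 0-based half-open, GFF is 1-based
# closed).

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

# Encode A,C,G,T as 1..4; anything else (including N) becomes NA.
dna_codes <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
  m
}

as_sequence_strings <- function(x) {
  if (is.character(x)) return(toupper(x))
  if (inherits(x, "sequence_record")) return(toupper(x$seq))
  if (is.list(x))
    return(vapply(x, function(r) toupper(if (is.list(r)) r$seq else r),
                  character(1)))
  stop("cannot interpret input as sequences")
}

#' Construct a sequence record
#'
#' @param name Record name.
#' @param seq Nucleotide string over A,C,G,T,N (uppercased on input).
#' @param origin Optional list `(chrom, start0, end0, strand)` recording the
#'   genomic interval the sequence was extracted from.
#' @return An object of class `"sequence_record"`.
#' @export
sequence_record <- function(name, seq, origin = NULL) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence record '", name, "' has empty sequence")
  if (!is.null(origin)) {
    stopifnot(is.list(origin),
              all(c("chrom", "start0", "end0", "strand") %in% names(origin)))
    if (origin$end0 - origin$start0 != nchar(seq))
      stop("origin interval length does not match sequence length")
  }
  structure(list(name = name, seq = seq, origin = origin),
            class = "sequence_record")
}

#' Read a FASTA file
#'
#' Sequences are uppercased; IUPAC ambiguity codes and any other non-ACGTN
#' symbol are mapped to `N` (with a warning naming the record).
#'
#' @param path Path to a (possibly multi-record, line-wrapped) FASTA file.
#' @return A list of [sequence_record()] objects in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  nms <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    if (!nzchar(s))
      stop("FASTA record '", nms[i], "' has an empty sequence")
    cleaned <- gsub("[^ACGTN]", "N", s)
    n_mapped <- sum(strsplit(s, "")[[1]] != strsplit(cleaned, "")[[1]])
    if (n_mapped > 0)
      warning("record '", nms[i], "': mapped ", n_mapped,
              " non-ACGTN symbol(s) to N")
    out[[i]] <- sequence_record(nms[i], cleaned)
  }
  out
}

#' Write sequence records as FASTA
#'
#' @param records A [sequence_record()] or list of them, or a named
#'   character vector.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 70L) {
  if (inherits(records, "sequence_record")) records <- list(records)
  if (is.character(records))
    records <- mapply(sequence_record, names(records), records,
                      SIMPLIFY = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$name), con)
    s <- r$seq
    starts <- seq.int(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' Supports the full IUPAC alphabet (`N` maps to `N`); applying twice
#' returns the input.
#'
#' @param seq A single nucleotide string.
#' @return The reverse-complement string.
#' @export
revcomp <- function(seq) {
  if (grepl(sprintf("[^%s%s]", IUPAC_CHARS, tolower(IUPAC_CHARS)), seq))
    stop("sequence contains non-IUPAC symbols")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read genomic intervals from BED or GFF
#'
#' BED input is taken as 0-based half-open, GFF as 1-based closed; both are
#' normalized to the package-internal 0-based half-open convention.
#'
#' @param path Path to the interval file.
#' @param dialect `"bed"` or `"gff"`.
#' @return A data frame with columns `chrom`, `start0`, `end0`, `strand`,
#'   `name`.
#' @export
read_intervals <- function(path, dialect = c("bed", "gff")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no interval records in ", path)
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (dialect == "bed") {
      if (length(f) < 3L)
        stop("BED format error at line ", i, ": fewer than 3 fields")
      start0 <- suppressWarnings(as.numeric(f[2]))
      end0 <- suppressWarnings(as.numeric(f[3]))
      if (is.na(start0) || is.na(end0))
        stop("BED format error at line ", i, ": non-numeric coordinates")
      name <- if (length(f) >= 4L && nzchar(f[4])) f[4] else NA_character_
      strand <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "."
    } else {
      if (length(f) < 7L)
        stop("GFF format error at line ", i, ": fewer than 7 fields")
      start0 <- suppressWarnings(as.numeric(f[4])) - 1
      end0 <- suppressWarnings(as.numeric(f[5]))
      if (is.na(start0) || is.na(end0))
        stop("GFF format error at line ", i, ": non-numeric coordinates")
      strand <- if (f[7] %in% c("+", "-")) f[7] else "."
      name <- if (length(f) >= 9L && grepl("ID=", f[9]))
        sub(";.*", "", sub(".*ID=", "", f[9])) else NA_character_
    }
    if (start0 < 0)
      stop("interval error at line ", i, ": negative start coordinate")
    if (end0 <= start0)
      stop("interval error at line ", i,
           ": end <= start after normalization")
    data.frame(chrom = f[1], start0 = start0, end0 = end0,
               strand = strand, name = name, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write intervals as BED or GFF3
#'
#' Inverse of [read_intervals()]: internal 0-based half-open coordinates are
#' converted back to the dialect's native convention.
#'
#' @param intervals Data frame with columns `chrom`, `start0`, `end0` and
#'   optionally `strand`, `name`.
#' @param path Output path.
#' @param dialect `"bed"` or `"gff"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, dialect = c("bed", "gff")) {
  dialect <- match.arg(dialect)
  strand <- if ("strand" %in% names(intervals)) intervals$strand
            else rep(".", nrow(intervals))
  name <- if ("name" %in% names(intervals)) intervals$name
          else rep(NA_character_, nrow(intervals))
  name <- ifelse(is.na(name), ".", name)
  lines <- if (dialect == "bed") {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", intervals$chrom,
            as.integer(intervals$start0), as.integer(intervals$end0),
            name, strand)
  } else {
    c("##gff-version 3",
      sprintf("%s\tfusemotif\tregion\t%d\t%d\t.\t%s\t.\tID=%s",
              intervals$chrom, as.integer(intervals$start0) + 1L,
              as.integer(intervals$end0), strand, name))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract interval sequences from a genome
#'
#' Minus-strand intervals are reverse-complemented; each returned record's
#' `origin` field records the source interval.
#'
#' @param genome List of [sequence_record()] objects (e.g. from
#'   [read_fasta()]) keyed by their names.
#' @param intervals Data frame as returned by [read_intervals()].
#' @return A list of [sequence_record()] objects, one per interval.
#' @export
extract_interval_sequences <- function(genome, intervals) {
  if (inherits(genome, "sequence_record")) genome <- list(genome)
  chroms <- vapply(genome, `[[`, character(1), "name")
  seqs <- vapply(genome, `[[`, character(1), "seq")
  names(seqs) <- chroms
  out <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    if (!iv$chrom %in% chroms)
      stop("chromosome '", iv$chrom, "' not present in genome")
    s <- seqs[[iv$chrom]]
    if (iv$end0 > nchar(s))
      stop("interval ", iv$chrom, ":", iv$start0, "-", iv$end0,
           " extends past the end of the chromosome (length ",
           nchar(s), ")")
    frag <- substr(s, iv$start0 + 1L, iv$end0)
    strand <- if (identical(iv$strand, "-")) "-" else "+"
    if (strand == "-") frag <- revcomp(frag)
    nm <- if (!is.na(iv$name)) iv$name
          else sprintf("%s:%d-%d(%s)", iv$chrom, iv$start0, iv$end0, strand)
    out[[i]] <- sequence_record(nm, frag,
      origin = list(chrom = iv$chrom, start0 = iv$start0,
                    end0 = iv$end0, strand = strand))
  }
  out
}
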