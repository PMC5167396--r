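# Assessment machinery: gold-standard labeling, ROC/AUC, precision-recall,
# read-count correlation and two-sample KS comparison.

#' Construct a read profile
#'
#' Per-interval read counts for a ChIP-style treatment library and its
#' control, plus total mapped reads per library.
#'
#' @param intervals Data frame with columns `chrom`, `start0`, `end0`.
#' @param treat,control Non-negative integer counts, one per interval.
#' @param total_treat,total_control Total mapped reads per library; must be
#'   at least the corresponding interval sums.
#' @return An object of class `"read_profile"`.
#' @export
read_profile <- function(intervals, treat, control, total_treat,
                         total_control) {
  stopifnot(nrow(intervals) == length(treat),
            nrow(intervals) == length(control))
  if (any(treat < 0) || any(control < 0)) stop("read counts must be >= 0")
  if (total_treat <= 0 || total_control <= 0)
    stop("total mapped reads must be positive")
  if (total_treat < sum(treat) || total_control < sum(control))
    stop("library totals must be at least the interval sums")
  structure(list(intervals = intervals, treat = as.numeric(treat),
                 control = as.numeric(control),
                 total_treat = as.numeric(total_treat),
                 total_control = as.numeric(total_control)),
            class = "read_profile")
}

#' Write / read a read profile as TSV
#'
#' Two `#total_*` header lines followed by one row per interval
#' (`chrom`, `start0`, `end0`, `treat`, `control`).
#'
#' @param profile A `"read_profile"`.
#' @param path File path.
#' @return `write_read_profile`: `path`, invisibly. `read_read_profile`:
#'   a `"read_profile"`.
#' @export
write_read_profile <- function(profile, path) {
  lines <- c(sprintf("#total_treat\t%g", profile$total_treat),
             sprintf("#total_control\t%g", profile$total_control),
             "chrom\tstart0\tend0\ttreat\tcontrol",
             sprintf("%s\t%d\t%d\t%g\t%g", profile$intervals$chrom,
                     as.integer(profile$intervals$start0),
                     as.integer(profile$intervals$end0),
                     profile$treat, profile$control))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_read_profile
#' @export
read_read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tt <- as.numeric(sub(".*\t", "", lines[grepl("^#total_treat", lines)][1]))
  tc <- as.numeric(sub(".*\t", "",
                       lines[grepl("^#total_control", lines)][1]))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  read_profile(df[, c("chrom", "start0", "end0")], df$treat, df$control,
               tt, tc)
}

# Sum profile counts over the profile intervals overlapping each window
# (>= 1 bp overlap), per chromosome.
profile_window_counts <- function(profile, windows) {
  treat <- numeric(nrow(windows))
  control <- numeric(nrow(windows))
  pint <- profile$intervals
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    pi <- which(pint$chrom == ch)
    if (length(pi) == 0L) next
    q <- IRanges::IRanges(start = windows$start0[wi] + 1L,
                          end = windows$end0[wi])
    s <- IRanges::IRanges(start = pint$start0[pi] + 1L,
                          end = pint$end0[pi])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    treat[wi] <- treat[wi] +
      as.numeric(tapply(profile$treat[pi][sh], factor(qh,
        levels = seq_along(wi)), sum, default = 0))
    control[wi] <- control[wi] +
      as.numeric(tapply(profile$control[pi][sh], factor(qh,
        levels = seq_along(wi)), sum, default = 0))
  }
  list(treat = treat, control = control)
}

overlaps_any <- function(windows, intervals) {
  hit <- logical(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    pi <- which(intervals$chrom == ch)
    if (length(pi) == 0L) next
    q <- IRanges::IRanges(start = windows$start0[wi] + 1L,
                          end = windows$end0[wi])
    s <- IRanges::IRanges(start = intervals$start0[pi] + 1L,
                          end = intervals$end0[pi])
    hit[wi] <- IRanges::countOverlaps(q, s) > 0
  }
  hit
}

#' Label motif instances against peaks and read evidence
#'
#' Positives are occurrences with `combined_p < p_cut` overlapping (by at
#' least 1 bp) any peak; negatives are occurrences with `combined_p <
#' p_cut`, zero peak overlap and a greater fraction of total mapped reads
#' in the control than in the treatment library. All other occurrences are
#' discarded.
#'
#' @param occurrences Data frame from [scan_sequences()] (needs `seq_name`,
#'   `start0`, `end0`, `combined_p`).
#' @param peaks Interval data frame (e.g. from [read_intervals()]).
#' @param reads A [read_profile()].
#' @param p_cut Instance p-value cutoff (the reference construction uses
#'   1e-9 on deep real data; synthetic fixtures typically use milder
#'   cutoffs).
#' @return A data frame of labeled instances with columns of `occurrences`
#'   plus `in_peak`, `treat_fraction`, `control_fraction`, `label`.
#' @export
build_gold_standard <- function(occurrences, peaks, reads, p_cut = 1e-9) {
  stopifnot(inherits(reads, "read_profile"))
  if (!(p_cut > 0 && p_cut <= 1)) stop("p_cut must lie in (0, 1]")
  occ <- as.data.frame(occurrences)
  occ <- occ[occ$combined_p < p_cut, , drop = FALSE]
  if (nrow(occ) == 0L)
    return(cbind(occ, in_peak = logical(0), treat_fraction = numeric(0),
                 control_fraction = numeric(0), label = character(0)))
  win <- data.frame(chrom = occ$seq_name, start0 = occ$start0,
                    end0 = occ$end0)
  occ$in_peak <- overlaps_any(win, peaks)
  cnt <- profile_window_counts(reads, win)
  occ$treat_fraction <- cnt$treat / reads$total_treat
  occ$control_fraction <- cnt$control / reads$total_control
  occ$label <- ifelse(occ$in_peak, "positive",
    ifelse(occ$control_fraction > occ$treat_fraction, "negative",
           NA_character_))
  occ <- occ[!is.na(occ$label), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels %in% c("positive", "pos", "1", "TRUE", "true")
}

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney probability that a random positive
#' outscores a random negative, with half credit for ties (computed via
#' midranks); the curve gives (FPR, TPR) at every distinct score
#' threshold.
#'
#' @param labels Logical vector (or `"positive"`/`"negative"` strings).
#' @param scores Numeric scores, larger = more confidently positive.
#' @return A list with `auc` and `curve` (data frame with `threshold`,
#'   `fpr`, `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores))
  np <- sum(y)
  nn <- sum(!y)
  if (np == 0L || nn == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores)                       # midranks: ties get half credit
  auc <- (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!y & scores >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fp / nn),
                      tpr = c(0, tp / np))
  list(auc = auc, curve = curve)
}

#' Precision-recall curve
#'
#' Scores are processed in descending order with tied scores grouped, so
#' each row gives the precision and recall attained when everything with a
#' score at or above the threshold is called positive.
#'
#' @inheritParams roc_auc
#' @return A data frame with `threshold`, `precision`, `recall`.
#' @export
precision_recall <- function(labels, scores) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores))
  np <- sum(y)
  if (np == 0L || np == length(y))
    stop("both classes must be present to compute a PR curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y & scores >= t), numeric(1))
  n_called <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  data.frame(threshold = thr, precision = tp / n_called,
             recall = tp / np)
}

#' Correlation between occurrence scores and local read counts
#'
#' Pearson correlation between an occurrence score (`-log10(combined_p)`
#' by default) and the square-root-transformed read count in a window
#' (default 400 bp) centered on the motif midpoint, computed separately
#' for the treatment and the control library.
#'
#' @param occurrences Data frame from [scan_sequences()].
#' @param reads A [read_profile()].
#' @param window_bp Window width centered on the motif midpoint.
#' @param score Optional explicit score vector (defaults to
#'   `-log10(combined_p)`).
#' @return A list with `r_treatment` and `r_control`.
#' @export
score_signal_correlation <- function(occurrences, reads, window_bp = 400L,
                                     score = NULL) {
  occ <- as.data.frame(occurrences)
  if (nrow(occ) < 3L) stop("need at least 3 occurrences")
  if (is.null(score)) score <- -log10(occ$combined_p)
  mid <- floor((occ$start0 + occ$end0) / 2)
  half <- floor(window_bp / 2)
  win <- data.frame(chrom = occ$seq_name,
                    start0 = pmax(mid - half, 0), end0 = mid + half)
  cnt <- profile_window_counts(reads, win)
  if (stats::var(score) == 0 || stats::var(sqrt(cnt$treat)) == 0 ||
      stats::var(sqrt(cnt$control)) == 0)
    stop("zero variance: correlation undefined")
  list(r_treatment = stats::cor(score, sqrt(cnt$treat)),
       r_control = stats::cor(score, sqrt(cnt$control)))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param a,b Non-empty numeric samples.
#' @return A list with the KS statistic `D` (maximal ECDF gap) and the
#'   asymptotic p-value `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
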