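# Copy-neutral LOH: per-segment calling and cross-sample recurrence.

#' Flag copy-neutral LOH segments
#'
#' A segment is cnLOH when it is copy-neutral (`|mean_logr| < tau_logr`) yet
#' shows near-complete allelic imbalance (`0.5 - mean_cbaf < tau_baf`), and
#' it passes the minimum-length and minimum-SNP filters.  Inequalities are
#' strict; segments without SNP support are never flagged.
#'
#' @param segments Segment `data.frame` (or a `dsw_fit`).
#' @param params A [cnloh_params()] object.
#' @return The segment `data.frame` with a logical `cnloh` column.
#' @export
call_cnloh <- function(segments, params = cnloh_params()) {
  if (inherits(segments, "dsw_fit")) segments <- segments$segments
  flag <- !is.na(segments$mean_logr) & !is.na(segments$mean_cbaf) &
    abs(segments$mean_logr) < params$tau_logr &
    (0.5 - segments$mean_cbaf) < params$tau_baf &
    segments$n_snps >= params$min_snps &
    (segments$end - segments$start) >= params$min_segment_length
  segments$cnloh <- flag
  segments
}

#' Count recurrent cnLOH regions across samples
#'
#' Partitions the genome at all interval endpoints and annotates each atomic
#' interval with the number of samples whose cnLOH calls cover it (interval
#' overlap counting via coverage on genomic ranges).  Overlapping intervals
#' within one sample are merged first, so a sample contributes at most one
#' count to any base.
#'
#' @param samples A list, one element per sample: a `data.frame` with chrom,
#'   start, end (0-based half-open) — e.g. a BED file read with
#'   [read_bed()], or [call_cnloh()] output restricted to flagged rows.
#'   Paths to BED files are also accepted.
#' @return `data.frame` (chrom, start, end, count) of disjoint sorted
#'   intervals with count >= 1.
#' @export
recurrent_cnloh <- function(samples) {
  stopifnot(length(samples) >= 1)
  grs <- lapply(samples, function(s) {
    if (is.character(s)) s <- read_bed(s)
    if ("cnloh" %in% names(s)) s <- s[s$cnloh, , drop = FALSE]
    if (nrow(s) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      s$chrom, IRanges::IRanges(s$start + 1, s$end)))
  })
  grs <- grs[vapply(grs, length, 0L) > 0]
  if (length(grs) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = integer(),
                      stringsAsFactors = FALSE))
  # within-sample ranges are reduced, so each sample adds at most 1 per base
  all_gr <- suppressWarnings(do.call(c, unname(grs)))
  cov <- GenomicRanges::coverage(all_gr)
  rows <- lapply(names(cov), function(ch) {
    r <- cov[[ch]]
    rd <- data.frame(start = cumsum(c(0, S4Vectors::runLength(r)))[
                       seq_along(S4Vectors::runLength(r))],
                     len = S4Vectors::runLength(r),
                     count = S4Vectors::runValue(r))
    rd <- rd[rd$count >= 1, , drop = FALSE]
    if (nrow(rd) == 0L) return(NULL)
    data.frame(chrom = ch, start = rd$start, end = rd$start + rd$len,
               count = as.integer(rd$count), stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    d <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    count = integer(), stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}
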