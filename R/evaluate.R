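# Evaluation: breakpoint precision/recall/F-measure against ground truth,
# 100-bp blockization of call sets, and the Jaccard similarity index.

#' Match called breakpoints against truth
#'
#' Greedy one-to-one nearest matching within a tolerance, per chromosome:
#' candidate pairs are ranked by distance (ties broken by position) and
#' consumed greedily.  Unmatched calls are false positives; unmatched truth
#' breakpoints are false negatives.
#'
#' @param called,truth `data.frame`s with chrom and pos.
#' @param tolerance_bp Maximum distance for a match.
#' @return An object of class `breakpoint_eval`: tp, fp, fn, precision,
#'   recall, f_measure, tolerance_bp.  Conventions: precision = 0 when
#'   nothing is called, recall = 0 when truth is empty but calls are not,
#'   F = 0 when P + R = 0.
#' @export
match_breakpoints <- function(called, truth, tolerance_bp) {
  tp <- 0L
  for (ch in union(unique(called$chrom), unique(truth$chrom))) {
    cp <- sort(called$pos[called$chrom == ch])
    tr <- sort(truth$pos[truth$chrom == ch])
    if (!length(cp) || !length(tr)) next
    pairs <- expand.grid(ci = seq_along(cp), ti = seq_along(tr))
    pairs$d <- abs(cp[pairs$ci] - tr[pairs$ti])
    pairs <- pairs[pairs$d <= tolerance_bp, , drop = FALSE]
    pairs <- pairs[order(pairs$d, tr[pairs$ti], cp[pairs$ci]), ,
                   drop = FALSE]
    used_c <- logical(length(cp))
    used_t <- logical(length(tr))
    for (i in seq_len(nrow(pairs))) {
      ci <- pairs$ci[i]
      ti <- pairs$ti[i]
      if (!used_c[ci] && !used_t[ti]) {
        used_c[ci] <- used_t[ti] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(called) - tp
  fn <- nrow(truth) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_measure = f,
                 tolerance_bp = tolerance_bp),
            class = "breakpoint_eval")
}

#' @export
print.breakpoint_eval <- function(x, ...) {
  cat(sprintf(paste0("breakpoint evaluation (tolerance %g bp): TP %d, ",
                     "FP %d, FN %d\n  precision %.3f, recall %.3f, ",
                     "F-measure %.3f\n"),
              x$tolerance_bp, x$tp, x$fp, x$fn, x$precision, x$recall,
              x$f_measure))
  invisible(x)
}

#' Extract the SCNA intervals of a segmentation
#'
#' Binarizes a real-valued segmentation for blockization: a segment is SCNA
#' when its absolute mean log ratio exceeds `logr_threshold`.
#'
#' @param segments Segment `data.frame` (or `dsw_fit`).
#' @param logr_threshold Threshold on `|mean_logr|` (default 0.1).
#' @return `data.frame` of chrom, start, end for SCNA segments.
#' @export
scna_intervals <- function(segments, logr_threshold = 0.1) {
  if (inherits(segments, "dsw_fit")) segments <- segments$segments
  keep <- !is.na(segments$mean_logr) &
    abs(segments$mean_logr) > logr_threshold
  segments[keep, c("chrom", "start", "end"), drop = FALSE]
}

#' Annotate fixed-size genome blocks with a binary SCNA label
#'
#' The genome is broken into `block` bp blocks; a block is labelled SCNA
#' when its midpoint lies inside one of the given intervals.  Blocks whose
#' midpoint falls in an exclusion region are dropped.
#'
#' @param intervals SCNA intervals: `data.frame` with chrom, start, end.
#' @param genome Named vector of chromosome lengths in bp.
#' @param block Block size in bp (default 100).
#' @param exclusions Optional `data.frame` of regions to exclude.
#' @return `data.frame` with chrom, start, end, scna (logical) for every
#'   included block.
#' @export
blockize <- function(intervals, genome, block = 100,
                     exclusions = NULL) {
  midpoint_in <- function(mid, ch, regions) {
    if (is.null(regions) || nrow(regions) == 0L)
      return(rep(FALSE, length(mid)))
    r <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0L) return(rep(FALSE, length(mid)))
    hit <- rep(FALSE, length(mid))
    for (i in seq_len(nrow(r)))
      hit <- hit | (mid >= r$start[i] & mid < r$end[i])
    hit
  }
  rows <- lapply(names(genome), function(ch) {
    n <- ceiling(genome[[ch]] / block)
    start <- (seq_len(n) - 1) * block
    end <- pmin(start + block, genome[[ch]])
    mid <- (start + end) / 2
    keep <- !midpoint_in(mid, ch, exclusions)
    data.frame(chrom = ch, start = start[keep], end = end[keep],
               scna = midpoint_in(mid[keep], ch, intervals),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' Jaccard similarity index of two blockized call sets
#'
#' `JSI = |both SCNA| / |either SCNA|` over a common block grid; 0 when the
#' union is empty, 1 for identical non-empty label sets.
#'
#' @param annot_a,annot_b [blockize()] outputs on the same grid.
#' @return The index, in [0, 1].
#' @export
jaccard_index <- function(annot_a, annot_b) {
  if (nrow(annot_a) != nrow(annot_b) ||
      any(annot_a$chrom != annot_b$chrom) ||
      any(annot_a$start != annot_b$start))
    stop("blockizations are not on the same grid")
  inter <- sum(annot_a$scna & annot_b$scna)
  uni <- sum(annot_a$scna | annot_b$scna)
  if (uni == 0) 0 else inter / uni
}
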