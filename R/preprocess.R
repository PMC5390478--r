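# Preprocessing: log2 ratio with mode/median bias correction, and the
# simultaneous mirror-and-smooth transform of BAF values.

#' Per-bin log2 ratio of tumor to normal read depth
#'
#' `logr_i = log2(tRD_i / nRD_i)`; bins where either depth is zero carry the
#' missing marker `NA` (no pseudocounts).
#'
#' @param tumor,normal `depth_track` objects on the same bin grid.
#' @return A `log_ratio_track`: per-chromosome numeric vectors plus grid
#'   metadata.
#' @export
compute_log_ratio <- function(tumor, normal) {
  if (tumor$bin_width != normal$bin_width ||
      !setequal(names(tumor$counts), names(normal$counts)))
    stop("tumor and normal tracks are on different grids")
  logr <- lapply(names(tumor$counts), function(ch) {
    t <- tumor$counts[[ch]]
    n <- normal$counts[[ch]]
    if (length(t) != length(n))
      stop("bin count mismatch on ", ch)
    out <- rep(NA_real_, length(t))
    ok <- !is.na(t) & !is.na(n) & t > 0 & n > 0
    out[ok] <- log2(t[ok] / n[ok])
    out
  })
  names(logr) <- names(tumor$counts)
  structure(list(logr = logr, bin_width = tumor$bin_width,
                 chrom_lengths = tumor$chrom_lengths),
            class = "log_ratio_track")
}

# Histogram mode of a continuous signal: bins of fixed width centred on
# multiples of `width` so that 0 is a bin centre; ties go to the centre
# nearest 0.
histogram_mode <- function(x, width = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  centre <- round(x / width)
  tab <- table(centre)
  best <- as.numeric(names(tab)[tab == max(tab)])
  best[which.min(abs(best))] * width
}

#' Correct log-ratio tracks for library-size bias
#'
#' Estimates the mode of the finite log-ratio values of each chromosome and
#' subtracts the median of the per-chromosome modes from every value.  The
#' median makes the correction robust to a genuine copy-number shift on any
#' single chromosome.
#'
#' @param track A `log_ratio_track` from [compute_log_ratio()].
#' @param mode_bin_width Histogram bin width (log2 units) of the mode
#'   estimator.
#' @return The corrected `log_ratio_track`; the subtracted constant is
#'   attached as attribute `"correction"`.
#' @export
correct_log_ratio <- function(track, mode_bin_width = 0.05) {
  modes <- vapply(track$logr, histogram_mode, 0, width = mode_bin_width)
  modes <- modes[!is.na(modes)]
  if (length(modes) == 0L) stop("no finite log-ratio values to correct")
  shift <- stats::median(modes)
  track$logr <- lapply(track$logr, function(v) v - shift)
  attr(track, "correction") <- shift
  track
}

# Running median with window `k` (odd); at series ends the window shrinks
# symmetrically to the data available (no padding).
shrinking_median <- function(x, k = 9L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(i - 1L, n - i, half)
    stats::median(x[(i - h):(i + h)])
  }, 0)
}

#' Simultaneously mirror and smooth B-allele fractions
#'
#' Computes, per SNP, `cBAF = H * |0.5 - M9(BAF)| + (1 - H) * M9(|0.5 - BAF|)`
#' where `M9` is a 9-SNP running median (shrinking symmetrically at
#' chromosome ends) and `H = 1 - 2*|0.5 - BAF|` weights the smooth-then-mirror
#' branch by how heterozygous-looking the raw observation is.  Mirroring
#' about 0.5 is required because raw BAF values are symmetric about 0.5 and
#' naive smoothing would underestimate the divergence of the dominant allele
#' fraction.  Smoothing never crosses a chromosome boundary.
#'
#' @param baf BAF `data.frame` (see [baf_track()]), sorted by (chrom, pos).
#' @param k Median filter width in SNPs (odd; default 9).
#' @return The input with a `cbaf` column appended, each value in [0, 0.5].
#' @export
mirror_smooth_baf <- function(baf, k = 9L) {
  stopifnot(k >= 1, k %% 2 == 1)
  baf <- baf[order(baf$chrom, baf$pos), , drop = FALSE]
  cbaf <- unlist(lapply(split(baf$baf, baf$chrom), function(b) {
    h <- 1 - 2 * abs(0.5 - b)
    h * abs(0.5 - shrinking_median(b, k)) +
      (1 - h) * shrinking_median(abs(0.5 - b), k)
  }), use.names = FALSE)
  # split() orders groups by factor level = sorted chrom, matching the sort
  baf$cbaf <- cbaf
  rownames(baf) <- NULL
  baf
}

#' Resample per-SNP cBAF onto the log-ratio bin grid
#'
#' Each bin receives the mean cBAF over the SNPs it contains; bins without
#' SNPs carry `NA`.
#'
#' @param snp_cbaf Output of [mirror_smooth_baf()].
#' @param grid_of A `log_ratio_track` defining the bin grid.
#' @return Named list of per-chromosome numeric vectors on the grid.
#' @export
resample_cbaf <- function(snp_cbaf, grid_of) {
  bw <- grid_of$bin_width
  out <- lapply(names(grid_of$logr), function(ch) {
    n <- length(grid_of$logr[[ch]])
    v <- rep(NA_real_, n)
    s <- snp_cbaf[snp_cbaf$chrom == ch, , drop = FALSE]
    if (nrow(s) > 0L) {
      bin <- pmin(s$pos %/% bw + 1L, n)
      sums <- tapply(s$cbaf, bin, sum)
      cnts <- tapply(s$cbaf, bin, length)
      v[as.integer(names(sums))] <- sums / cnts
    }
    v
  })
  names(out) <- names(grid_of$logr)
  out
}
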