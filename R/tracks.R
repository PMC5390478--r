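#' Binned read-depth track
#'
#' A per-chromosome list of non-negative integer read counts on a uniform bin
#' grid.  Bin `i` (1-based in R) covers `[(i-1)*bin_width, i*bin_width)` in
#' 0-based half-open genomic coordinates; the last bin of a chromosome may be
#' partial.
#'
#' @param counts Named list of integer vectors, one per chromosome.
#' @param bin_width Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths in bp; defaults to
#'   `n_bins * bin_width` per chromosome.
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(counts, bin_width, chrom_lengths = NULL) {
  stopifnot(is.list(counts), !is.null(names(counts)), bin_width > 0)
  counts <- lapply(counts, function(x) {
    x <- as.numeric(x)
    stopifnot(all(x >= 0, na.rm = TRUE))
    x
  })
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(counts, length, 0L) * as.numeric(bin_width)
    names(chrom_lengths) <- names(counts)
  }
  stopifnot(setequal(names(chrom_lengths), names(counts)))
  n_expect <- ceiling(chrom_lengths[names(counts)] / bin_width)
  n_got <- vapply(counts, length, 0L)
  if (any(n_got != n_expect))
    stop("bin count does not match ceiling(chrom_length / bin_width)")
  structure(list(counts = counts, bin_width = as.integer(bin_width),
                 chrom_lengths = chrom_lengths[names(counts)]),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track: %d chromosome(s), bin width %d bp, %d bins\n",
              length(x$counts), x$bin_width,
              sum(vapply(x$counts, length, 0L))))
  invisible(x)
}

#' B-allele fraction track at heterozygous SNPs
#'
#' @param chrom,pos,ref_count,alt_count Per-SNP vectors; `pos` is 0-based.
#' @return A `data.frame` with columns chrom, pos, ref_count, alt_count, baf,
#'   sorted by (chrom, pos), with `baf = alt/(ref+alt)`.
#' @export
baf_track <- function(chrom, pos, ref_count, alt_count) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(ref_count),
            length(ref_count) == length(alt_count))
  tot <- ref_count + alt_count
  stopifnot(all(tot >= 1))
  d <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref_count = as.integer(ref_count),
                  alt_count = as.integer(alt_count),
                  baf = alt_count / tot, stringsAsFactors = FALSE)
  d[order(d$chrom, d$pos), , drop = FALSE]
}

#' Combine tumor/normal depth tracks and SNP BAFs into a joint signal
#'
#' Computes the corrected log2 ratio on the bin grid, the mirrored/smoothed
#' cBAF per SNP, and resamples cBAF onto the same bin grid, yielding the
#' two-signal track the segmentation slides its windows over.
#'
#' @param tumor,normal `depth_track` objects on the same grid.
#' @param baf Optional BAF `data.frame` (see [baf_track()]); `NULL` for
#'   log-ratio-only mode.
#' @param correct Subtract the median-of-chromosome-modes constant from the
#'   log ratio (default `TRUE`).
#' @return An object of class `joint_signal`: per-chromosome `logr` and
#'   `cbaf` vectors on the bin grid (`NA` marks missing bins), the per-SNP
#'   cBAF table, bin width and chromosome lengths.
#' @export
joint_signal <- function(tumor, normal, baf = NULL, correct = TRUE) {
  lr <- compute_log_ratio(tumor, normal)
  if (correct) lr <- correct_log_ratio(lr)
  snp_cbaf <- NULL
  cbaf_bins <- lapply(lr$logr, function(v) rep(NA_real_, length(v)))
  if (!is.null(baf) && nrow(baf) > 0) {
    snp_cbaf <- mirror_smooth_baf(baf)
    cbaf_bins <- resample_cbaf(snp_cbaf, lr)
  }
  structure(list(logr = lr$logr, cbaf = cbaf_bins, snp_cbaf = snp_cbaf,
                 bin_width = lr$bin_width, chrom_lengths = lr$chrom_lengths),
            class = "joint_signal")
}

#' @export
print.joint_signal <- function(x, ...) {
  nb <- sum(vapply(x$logr, length, 0L))
  ns <- if (is.null(x$snp_cbaf)) 0L else nrow(x$snp_cbaf)
  cat(sprintf(
    "joint_signal: %d chromosome(s), %d bins of %d bp, %d SNPs%s\n",
    length(x$logr), nb, x$bin_width, ns,
    if (ns == 0L) " (log-ratio only)" else ""))
  invisible(x)
}
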