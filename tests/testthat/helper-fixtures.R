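# Fixture builders shared across test files.  BAM fixtures are written as
# SAM text and converted at test time; signals are constructed in code.

# Write a SAM file and convert to an indexed BAM.  `reads` is a data frame
# with qname, chrom, pos (1-based), mapq, cigar, seq.
make_bam <- function(reads, chrom_lengths, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("bamfx")
    dir.create(dir)
  }
  sam <- file.path(dir, "fx.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  reads <- reads[order(match(reads$chrom, names(chrom_lengths)),
                       reads$pos), , drop = FALSE]
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$chrom, as.integer(reads$pos),
                  as.integer(reads$mapq), reads$cigar, reads$seq,
                  strrep("I", nchar(reads$seq)))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# A read record covering positions [start0, start0 + len) with one base.
simple_read <- function(qname, chrom, start0, len, mapq = 60,
                        base = "A") {
  data.frame(qname = qname, chrom = chrom, pos = start0 + 1L, mapq = mapq,
             cigar = paste0(len, "M"), seq = strrep(base, len),
             stringsAsFactors = FALSE)
}

# Build a joint_signal directly from per-chromosome logr / cbaf vectors.
make_signal <- function(logr, cbaf = NULL, bin_width = 1000,
                        chrom_lengths = NULL) {
  if (!is.list(logr)) logr <- list(chr1 = logr)
  if (!is.null(cbaf) && !is.list(cbaf)) cbaf <- list(chr1 = cbaf)
  if (is.null(cbaf))
    cbaf <- lapply(logr, function(v) rep(NA_real_, length(v)))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(logr, length, 0L) * bin_width
    names(chrom_lengths) <- names(logr)
  }
  structure(list(logr = logr, cbaf = cbaf, snp_cbaf = NULL,
                 bin_width = as.integer(bin_width),
                 chrom_lengths = chrom_lengths),
            class = "joint_signal")
}

# Independent cBAF oracle: direct evaluation of the mirror/smooth formula
# with a sorting-based median on symmetric shrinking windows.
cbaf_oracle <- function(b, k = 9L) {
  med <- function(v) {
    v <- sort(v)
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
  }
  half <- (k - 1) %/% 2
  n <- length(b)
  vapply(seq_len(n), function(i) {
    h <- min(i - 1, n - i, half)
    win <- b[(i - h):(i + h)]
    H <- 1 - 2 * abs(0.5 - b[i])
    H * abs(0.5 - med(win)) + (1 - H) * med(abs(0.5 - win))
  }, 0)
}

# Per-base brute-force recurrence oracle over small chromosomes.
recurrence_oracle <- function(samples, chrom_len) {
  chroms <- unique(unlist(lapply(samples, function(s) s$chrom)))
  out <- lapply(chroms, function(ch) {
    counts <- integer(chrom_len)
    for (s in samples) {
      si <- s[s$chrom == ch, , drop = FALSE]
      covered <- logical(chrom_len)
      for (i in seq_len(nrow(si)))
        if (si$end[i] > si$start[i])
          covered[(si$start[i] + 1):si$end[i]] <- TRUE
      counts <- counts + covered
    }
    counts
  })
  names(out) <- chroms
  out
}
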