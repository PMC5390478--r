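# BAM front-end: binned read depth and per-SNP allele counts.
# Duplicate, secondary, supplementary and unmapped records are always
# excluded; mapping-quality filtering follows extraction_params.

bam_flag_filter <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isDuplicate = FALSE,
                         isSupplementaryAlignment = FALSE)
}

#' Bin read depth from a coordinate-sorted BAM file
#'
#' Divides each chromosome into bins of `params$bin_width` bp and counts the
#' reads overlapping each bin.  A read overlapping k bins increments each of
#' those k bins by one.
#'
#' @param bam_file Path to an indexed BAM file.
#' @param chrom_lengths Named vector of chromosome lengths; defaults to the
#'   BAM header.  Alignments on chromosomes absent from it are skipped with a
#'   warning.
#' @param params An [extraction_params()] object.
#' @return A [depth_track()].
#' @export
bin_read_depth <- function(bam_file, chrom_lengths = NULL,
                           params = extraction_params()) {
  hdr <- Rsamtools::scanBamHeader(bam_file)[[1]]$targets
  if (is.null(chrom_lengths)) chrom_lengths <- hdr
  sbp <- Rsamtools::ScanBamParam(flag = bam_flag_filter(),
                                 mapqFilter = params$min_mapping_quality)
  aln <- GenomicAlignments::readGAlignments(bam_file, param = sbp)
  ch <- as.character(GenomicAlignments::seqnames(aln))
  unknown <- setdiff(unique(ch), names(chrom_lengths))
  if (length(unknown)) {
    warning("skipping alignments on unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    keep <- !(ch %in% unknown)
    aln <- aln[keep]
    ch <- ch[keep]
  }
  bw <- params$bin_width
  s0 <- GenomicAlignments::start(aln) - 1L   # 0-based inclusive
  e0 <- GenomicAlignments::end(aln)          # 0-based exclusive
  counts <- lapply(names(chrom_lengths), function(chr) {
    n <- as.integer(ceiling(chrom_lengths[[chr]] / bw))
    sel <- ch == chr
    if (!any(sel)) return(integer(n))
    b1 <- pmax(s0[sel] %/% bw, 0L)
    b2 <- pmin((e0[sel] - 1L) %/% bw, n - 1L)
    len <- b2 - b1 + 1L
    idx <- rep.int(b1, len) + sequence(len)  # 1-based bin indices
    tabulate(idx, nbins = n)
  })
  names(counts) <- names(chrom_lengths)
  depth_track(counts, bw, chrom_lengths)
}

#' Read a known-SNP site list from VCF or 3-column TSV
#'
#' Only CHROM/POS are used from a VCF; TSV columns are (chrom, pos, id) with
#' pos 0-based.  VCF positions (1-based) are converted to 0-based on read.
#'
#' @param path `.vcf`/`.vcf.gz` file, or tab-separated text.
#' @return `data.frame` with `chrom` and 0-based `pos`, sorted.
#' @export
read_site_list <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr) - 1L,
                    stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 0L) < 2 |
                   is.na(suppressWarnings(
                     as.numeric(vapply(fields, `[`, "", 2L)))))
    if (length(bad))
      stop("malformed site record at line ", which(keep)[bad[1]],
           " of ", path)
    d <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    pos = as.integer(vapply(fields, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  }
  d[order(d$chrom, d$pos), , drop = FALSE]
}

# Nucleotide counts at given 0-based positions; returns one row per site
# with the two most frequent alleles and their counts.
pileup_alleles <- function(bam_file, sites, min_mapq) {
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos + 1L, width = 1L))
  sbp <- Rsamtools::ScanBamParam(flag = bam_flag_filter(), which = gr)
  pp <- Rsamtools::PileupParam(distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               min_mapq = min_mapq, min_base_quality = 0L,
                               max_depth = 100000L,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  p <- Rsamtools::pileup(bam_file, scanBamParam = sbp, pileupParam = pp)
  if (nrow(p) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      major = character(), minor = character(),
                      major_count = integer(), minor_count = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  key <- paste(p$seqnames, p$pos)
  out <- lapply(split(seq_len(nrow(p)), key), function(i) {
    pi <- p[i, , drop = FALSE]
    o <- order(pi$count, decreasing = TRUE)
    data.frame(chrom = as.character(pi$seqnames[1]),
               pos = pi$pos[1] - 1L,
               major = as.character(pi$nucleotide[o[1]]),
               minor = if (length(o) > 1)
                 as.character(pi$nucleotide[o[2]]) else NA_character_,
               major_count = pi$count[o[1]],
               minor_count = if (length(o) > 1) pi$count[o[2]] else 0L,
               depth = sum(pi$count), stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, out)
  d[order(d$chrom, d$pos), , drop = FALSE]
}

#' Call heterozygous SNPs in the normal sample at known sites
#'
#' A site is heterozygous when its normal-sample depth is at least
#' `het_min_depth` and its minor-allele fraction lies strictly inside
#' `het_fraction_window`.
#'
#' @param normal_bam Indexed BAM of the normal sample.
#' @param sites Site list: a path accepted by [read_site_list()] or a
#'   `data.frame` with `chrom` and 0-based `pos`.
#' @param params An [extraction_params()] object.
#' @return Sorted `data.frame` (chrom, pos, ref, alt) where ref/alt are the
#'   major/minor alleles observed in the normal sample.
#' @export
call_het_snps <- function(normal_bam, sites, params = extraction_params()) {
  if (is.character(sites)) sites <- read_site_list(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (nrow(sites) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  a <- pileup_alleles(normal_bam, sites, params$min_mapping_quality)
  frac <- a$minor_count / a$depth
  w <- params$het_fraction_window
  keep <- a$depth >= params$het_min_depth & !is.na(a$minor) &
    frac > w[1] & frac < w[2]
  d <- a[keep, c("chrom", "pos", "major", "minor"), drop = FALSE]
  names(d) <- c("chrom", "pos", "ref", "alt")
  rownames(d) <- NULL
  d
}

#' Compute tumor-sample B-allele fractions at heterozygous sites
#'
#' Counts reads supporting the ref and alt alleles (as defined by the normal
#' sample) at each heterozygous SNP in the tumor BAM; sites with zero tumor
#' coverage on those alleles are dropped.
#'
#' @param tumor_bam Indexed BAM of the tumor sample.
#' @param het_sites Output of [call_het_snps()].
#' @param params An [extraction_params()] object.
#' @return BAF `data.frame` (see [baf_track()]).
#' @export
compute_baf <- function(tumor_bam, het_sites, params = extraction_params()) {
  if (nrow(het_sites) == 0L)
    return(baf_track(character(), integer(), integer(), integer()))
  gr <- GenomicRanges::GRanges(het_sites$chrom,
                               IRanges::IRanges(het_sites$pos + 1L,
                                                width = 1L))
  sbp <- Rsamtools::ScanBamParam(flag = bam_flag_filter(), which = gr)
  pp <- Rsamtools::PileupParam(distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               min_mapq = params$min_mapping_quality,
                               min_base_quality = 0L, max_depth = 100000L,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  p <- Rsamtools::pileup(tumor_bam, scanBamParam = sbp, pileupParam = pp)
  site_key <- paste(het_sites$chrom, het_sites$pos)
  ref_n <- alt_n <- integer(nrow(het_sites))
  if (nrow(p) > 0L) {
    pk <- paste(p$seqnames, p$pos - 1L)
    idx <- match(pk, site_key)
    nuc <- as.character(p$nucleotide)
    isref <- !is.na(idx) & nuc == het_sites$ref[idx]
    isalt <- !is.na(idx) & nuc == het_sites$alt[idx]
    for (j in which(isref)) ref_n[idx[j]] <- ref_n[idx[j]] + p$count[j]
    for (j in which(isalt)) alt_n[idx[j]] <- alt_n[idx[j]] + p$count[j]
  }
  keep <- ref_n + alt_n >= 1L
  baf_track(het_sites$chrom[keep], het_sites$pos[keep],
            ref_n[keep], alt_n[keep])
}
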