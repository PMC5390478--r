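# Text formats: all tab-separated, 0-based half-open, LF, one '#' header.

write_tsv_header <- function(cols, path) {
  cat(paste0("#", paste(cols, collapse = "\t"), "\n"), file = path)
}

read_tsv_body <- function(path, col_names, col_classes) {
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#")) 1L else 0L
  d <- utils::read.table(path, sep = "\t", skip = skip, header = FALSE,
                         col.names = col_names, colClasses = col_classes,
                         comment.char = "", quote = "",
                         stringsAsFactors = FALSE)
  d
}

#' Write a depth track (or any per-bin numeric track) as bedGraph
#'
#' @param track A `depth_track`, or a `joint_signal` together with
#'   `signal = "logr"` or `"cbaf"` to export one of its components.
#' @param path Output file.
#' @param signal Which `joint_signal` component to write (ignored for depth
#'   tracks).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, signal = c("counts", "logr", "cbaf")) {
  signal <- match.arg(signal)
  if (inherits(track, "depth_track")) {
    values <- track$counts
  } else if (inherits(track, "joint_signal")) {
    values <- track[[signal]]
  } else stop("track must be a depth_track or joint_signal")
  bw <- track$bin_width
  rows <- lapply(names(values), function(ch) {
    v <- values[[ch]]
    n <- length(v)
    if (n == 0L) return(NULL)
    end <- pmin(seq_len(n) * as.numeric(bw), track$chrom_lengths[[ch]])
    data.frame(chrom = ch, start = (seq_len(n) - 1L) * as.numeric(bw),
               end = end, value = v, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d <- d[!is.na(d$value), , drop = FALSE]
  write_tsv_header(c("chrom", "start", "end", "value"), path)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a bedGraph file back into a depth track
#'
#' Expects the uniform bin grid this package writes; `bin_width` is inferred
#' from the first record.
#'
#' @param path bedGraph file.
#' @param chrom_lengths Optional named vector; inferred from the last bin end
#'   per chromosome when absent.
#' @return A `depth_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  d <- read_tsv_body(path, c("chrom", "start", "end", "value"),
                     c("character", "numeric", "numeric", "numeric"))
  if (nrow(d) == 0L) stop("empty bedGraph: ", path)
  bw <- d$end[1] - d$start[1]
  chroms <- unique(d$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      max(d$end[d$chrom == ch]), 0)
    names(chrom_lengths) <- chroms
  }
  counts <- lapply(chroms, function(ch) {
    n <- ceiling(chrom_lengths[[ch]] / bw)
    v <- rep(NA_real_, n)
    dd <- d[d$chrom == ch, ]
    v[dd$start %/% bw + 1L] <- dd$value
    v
  })
  names(counts) <- chroms
  depth_track(counts, bw, chrom_lengths)
}

#' Write a BAF table as 5-column TSV
#'
#' Columns: chrom, pos (0-based), ref_count, alt_count, baf.
#'
#' @param baf BAF `data.frame` (see [baf_track()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_baf <- function(baf, path) {
  write_tsv_header(c("chrom", "pos", "ref_count", "alt_count", "baf"), path)
  utils::write.table(
    baf[, c("chrom", "pos", "ref_count", "alt_count", "baf")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    append = TRUE)
  invisible(path)
}

#' Read a 5-column BAF TSV
#' @param path Input file.
#' @return BAF `data.frame` sorted by (chrom, pos).
#' @export
read_baf <- function(path) {
  d <- read_tsv_body(path, c("chrom", "pos", "ref_count", "alt_count", "baf"),
                     c("character", "integer", "integer", "integer",
                       "numeric"))
  d[order(d$chrom, d$pos), , drop = FALSE]
}

#' Write segments as a SEG-style table
#'
#' Columns: sample, chrom, start (0-based), end, n_bins, n_snps, mean_logr,
#' mean_cbaf; loadable in genome browsers.
#'
#' @param segments Segment `data.frame`.
#' @param path Output file.
#' @param sample Sample identifier for the first column.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample = "sample") {
  d <- data.frame(sample = sample, segments[, c("chrom", "start", "end",
                                                "n_bins", "n_snps")],
                  mean_logr = segments$mean_logr,
                  mean_cbaf = segments$mean_cbaf, stringsAsFactors = FALSE)
  write_tsv_header(names(d), path)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a SEG-style table written by [write_seg()]
#' @param path Input file.
#' @return Segment `data.frame` (sample column dropped).
#' @export
read_seg <- function(path) {
  d <- read_tsv_body(path, c("sample", "chrom", "start", "end", "n_bins",
                             "n_snps", "mean_logr", "mean_cbaf"),
                     c("character", "character", "numeric", "numeric",
                       "integer", "integer", "numeric", "numeric"))
  d[, -1, drop = FALSE]
}

#' Write genomic intervals as BED
#'
#' @param intervals `data.frame` with chrom, start, end and optionally
#'   name/score columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  write_tsv_header(cols, path)
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     append = TRUE)
  invisible(path)
}

#' Read a BED file (3-5 columns)
#' @param path Input file.
#' @return `data.frame` with chrom, start, end and any name/score columns.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#")) 1L else 0L
  d <- utils::read.table(path, sep = "\t", skip = skip, header = FALSE,
                         comment.char = "", quote = "",
                         stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "name", "score")[seq_len(ncol(d))]
  d
}
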