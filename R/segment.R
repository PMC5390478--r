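# Double sliding-window breakpoint detection at multiple scales.
#
# Windows are defined on the bin grid.  The log-ratio term averages
# non-missing bins and a boundary is skipped when more than half the bins of
# either window are missing.  The cBAF term averages the individual SNP
# observations falling inside each window (or the non-missing per-bin cBAF
# values when the signal was built without a SNP table) and is dropped when
# either window holds no observation.

#' Compound changepoint score of two adjacent windows
#'
#' `S = (dlogr/tau_logr)^2 + (dcbaf/tau_baf)^2` with `d*` the absolute
#' differences of the window means; a change is detected when `S > 1`, so in
#' the single-signal case `S > 1` coincides exactly with the mean difference
#' exceeding its threshold.  With `baf_mode = FALSE` the second term is zero.
#'
#' @param left,right Numeric vectors `c(logr_mean, cbaf_mean)` for the two
#'   windows (`cbaf_mean` may be `NA`).
#' @param tau_logr,tau_baf Thresholds on the two mean differences.
#' @param baf_mode Include the cBAF term?
#' @return The score, a single non-negative number (`NA` when the log-ratio
#'   means are unavailable).
#' @export
compound_score <- function(left, right, tau_logr, tau_baf, baf_mode = TRUE) {
  if (is.na(left[1]) || is.na(right[1])) return(NA_real_)
  s <- (abs(left[1] - right[1]) / tau_logr)^2
  if (baf_mode && !is.na(left[2]) && !is.na(right[2]))
    s <- s + (abs(left[2] - right[2]) / tau_baf)^2
  s
}

# Per-bin cBAF observation sums/counts for a chromosome: from the SNP table
# when available, otherwise one observation per non-missing cBAF bin.
cbaf_bin_obs <- function(signal, ch) {
  n <- length(signal$logr[[ch]])
  sums <- numeric(n)
  cnts <- numeric(n)
  s <- signal$snp_cbaf
  if (!is.null(s)) {
    s <- s[s$chrom == ch, , drop = FALSE]
    if (nrow(s) > 0L) {
      bin <- pmin(s$pos %/% signal$bin_width + 1L, n)
      agg <- rowsum(cbind(s$cbaf, 1), bin)
      idx <- as.integer(rownames(agg))
      sums[idx] <- agg[, 1]
      cnts[idx] <- agg[, 2]
    }
  } else if (!is.null(signal$cbaf[[ch]])) {
    v <- signal$cbaf[[ch]]
    ok <- !is.na(v)
    sums[ok] <- v[ok]
    cnts[ok] <- 1
  }
  list(sums = sums, cnts = cnts)
}

# All boundary scores for one chromosome at one window size.  Returns a data
# frame of boundary bin index b (boundary between bins b and b+1) and score.
chrom_scores <- function(logr, obs, window, tau_logr, tau_baf, baf_mode) {
  n <- length(logr)
  w <- window
  if (n < 2L * w) return(NULL)
  b <- w:(n - w)
  cs <- cumsum(ifelse(is.na(logr), 0, logr))
  cn <- cumsum(!is.na(logr))
  csum <- function(x, i) ifelse(i == 0L, 0, x[pmax(i, 1L)])
  nL <- csum(cn, b) - csum(cn, b - w)
  nR <- csum(cn, b + w) - csum(cn, b)
  mL <- (csum(cs, b) - csum(cs, b - w)) / nL
  mR <- (csum(cs, b + w) - csum(cs, b)) / nR
  valid <- nL >= w / 2 & nR >= w / 2 & nL > 0 & nR > 0
  s <- (abs(mL - mR) / tau_logr)^2
  if (baf_mode) {
    bs <- cumsum(obs$sums)
    bc <- cumsum(obs$cnts)
    oL <- csum(bc, b) - csum(bc, b - w)
    oR <- csum(bc, b + w) - csum(bc, b)
    has <- oL > 0 & oR > 0
    muL <- (csum(bs, b) - csum(bs, b - w)) / oL
    muR <- (csum(bs, b + w) - csum(bs, b)) / oR
    term <- ifelse(has, (abs(muL - muR) / tau_baf)^2, 0)
    s <- s + term
  }
  s[!valid] <- NA_real_
  data.frame(b = b, score = s)
}

#' Detect breakpoints with a single pass of the double sliding window
#'
#' Two adjacent non-overlapping windows of `window` bins are slid along each
#' chromosome; a breakpoint is placed where the windows touch when the
#' compound score exceeds 1 and is a local maximum of the score within one
#' window width on either side (so one true change yields one breakpoint).
#'
#' @param signal A `joint_signal`.
#' @param window Window size in bins.
#' @param tau_logr,tau_baf Score thresholds.
#' @param baf_mode Include the cBAF term?
#' @return `data.frame` with chrom, pos (0-based bp, a multiple of the bin
#'   width), score and scale (= `window`).
#' @export
detect_breakpoints <- function(signal, window, tau_logr, tau_baf,
                               baf_mode = TRUE) {
  bw <- signal$bin_width
  out <- lapply(names(signal$logr), function(ch) {
    sc <- chrom_scores(signal$logr[[ch]], cbaf_bin_obs(signal, ch),
                       window, tau_logr, tau_baf, baf_mode)
    if (is.null(sc)) return(NULL)
    s <- sc$score
    cand <- which(!is.na(s) & s > 1)
    if (!length(cand)) return(NULL)
    keep <- vapply(cand, function(i) {
      lo <- max(1L, i - window)
      hi <- min(length(s), i + window)
      left <- s[lo:i][-(i - lo + 1L)]
      right <- s[i:hi][-1L]
      all(is.na(left) | s[i] > left) && all(is.na(right) | s[i] >= right)
    }, TRUE)
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, pos = sc$b[cand[keep]] * as.numeric(bw),
               score = s[cand[keep]], scale = window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = numeric(),
                      score = numeric(), scale = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' The multi-scale window/threshold schedule
#'
#' Pass 1 uses `initial_window` and the initial thresholds; each later pass
#' grows the window by the factor 1.5 (`ceiling`, so growth is strict) and
#' multiplies both thresholds by `1/sqrt(1.5)` — the factor by which the
#' standard error of a window mean shrinks when the window grows 1.5-fold.
#' Passes run as long as both updated thresholds remain strictly greater
#' than their merge thresholds.
#'
#' @param params A [segmentation_params()] object.
#' @return `data.frame` with one row per pass: pass, window, tau_logr,
#'   tau_baf.
#' @export
threshold_schedule <- function(params) {
  w <- params$initial_window
  tl <- params$tau_logr
  tb <- params$tau_baf
  rows <- list()
  k <- 1L
  while (tl > params$tau_merge_logr &&
         (!params$baf_mode || tb > params$tau_merge_baf)) {
    rows[[k]] <- data.frame(pass = k, window = w, tau_logr = tl,
                            tau_baf = tb)
    w <- as.integer(ceiling(w * 1.5))
    tl <- tl / sqrt(1.5)
    tb <- tb / sqrt(1.5)
    k <- k + 1L
  }
  do.call(rbind, rows)
}

#' Multi-scale breakpoint detection with consensus
#'
#' Runs [detect_breakpoints()] once per pass of [threshold_schedule()].  All
#' pass-1 breakpoints are accepted; a breakpoint from a later pass is added
#' only if it lies farther than the current window size (in bp) from every
#' breakpoint already in the consensus list on the same chromosome.
#'
#' @param signal A `joint_signal`.
#' @param params A [segmentation_params()] object.
#' @return Consensus breakpoint `data.frame` (chrom, pos, score, scale,
#'   pass), sorted by (chrom, pos).
#' @export
multiscale_detect <- function(signal, params = segmentation_params()) {
  sched <- threshold_schedule(params)
  cons <- NULL
  for (k in seq_len(nrow(sched))) {
    bp <- detect_breakpoints(signal, sched$window[k], sched$tau_logr[k],
                             sched$tau_baf[k], params$baf_mode)
    if (nrow(bp) == 0L) next
    bp$pass <- k
    if (is.null(cons)) {
      cons <- bp
    } else if (k == 1L) {
      cons <- rbind(cons, bp)
    } else {
      wbp <- sched$window[k] * as.numeric(signal$bin_width)
      for (i in seq_len(nrow(bp))) {
        same <- cons$chrom == bp$chrom[i]
        if (!any(same) || all(abs(cons$pos[same] - bp$pos[i]) > wbp))
          cons <- rbind(cons, bp[i, ])
      }
    }
  }
  if (is.null(cons))
    cons <- data.frame(chrom = character(), pos = numeric(),
                       score = numeric(), scale = integer(),
                       pass = integer(), stringsAsFactors = FALSE)
  cons <- cons[order(cons$chrom, cons$pos), , drop = FALSE]
  rownames(cons) <- NULL
  cons
}

#' Build tiling segments from consensus breakpoints
#'
#' Two consecutive breakpoints delimit a segment; chromosome ends act as
#' implicit boundaries.  Each segment carries its mean log ratio over
#' non-missing bins and its mean cBAF over the SNP observations it contains.
#'
#' @param breakpoints Breakpoint `data.frame` (chrom, pos).
#' @param signal The `joint_signal` the breakpoints were detected on.
#' @return Segment `data.frame`: chrom, start, end (0-based half-open),
#'   n_bins (non-missing), n_snps, mean_logr, mean_cbaf.
#' @export
build_segments <- function(breakpoints, signal) {
  bw <- as.numeric(signal$bin_width)
  out <- lapply(names(signal$logr), function(ch) {
    L <- as.numeric(signal$chrom_lengths[[ch]])
    v <- signal$logr[[ch]]
    obs <- cbaf_bin_obs(signal, ch)
    bps <- sort(unique(breakpoints$pos[breakpoints$chrom == ch]))
    bps <- bps[bps > 0 & bps < L]
    cuts <- c(0, bps, L)
    do.call(rbind, lapply(seq_len(length(cuts) - 1L), function(i) {
      s <- cuts[i]
      e <- cuts[i + 1L]
      bins <- (s %/% bw + 1L):ceiling(e / bw)
      lv <- v[bins]
      nb <- sum(!is.na(lv))
      ns <- sum(obs$cnts[bins])
      data.frame(chrom = ch, start = s, end = e,
                 n_bins = nb, n_snps = as.integer(ns),
                 mean_logr = if (nb > 0) mean(lv, na.rm = TRUE) else NA_real_,
                 mean_cbaf = if (ns > 0) sum(obs$sums[bins]) / ns
                             else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Merge adjacent segments that are statistically indistinguishable
#'
#' Two consecutive segments merge when both the absolute difference of their
#' mean log ratios is below `tau_merge_logr` and the absolute difference of
#' their mean cBAF values is below `tau_merge_baf` (the BAF condition is
#' ignored in log-ratio-only mode, and holds vacuously when either mean cBAF
#' is unavailable).  Merging sweeps left to right repeatedly until a fixed
#' point; merged means are support-weighted.
#'
#' @param segments Segment `data.frame` from [build_segments()].
#' @param tau_merge_logr,tau_merge_baf Merge thresholds.
#' @param baf_mode Apply the BAF condition?
#' @return The merged segment `data.frame`.
#' @export
merge_segments <- function(segments, tau_merge_logr, tau_merge_baf,
                           baf_mode = TRUE) {
  merge_pair <- function(a, b) {
    wmean <- function(m1, n1, m2, n2) {
      if (n1 + n2 == 0) return(NA_real_)
      if (is.na(m1)) return(m2)
      if (is.na(m2)) return(m1)
      (m1 * n1 + m2 * n2) / (n1 + n2)
    }
    a$mean_logr <- wmean(a$mean_logr, a$n_bins, b$mean_logr, b$n_bins)
    a$mean_cbaf <- wmean(a$mean_cbaf, a$n_snps, b$mean_cbaf, b$n_snps)
    a$end <- b$end
    a$n_bins <- a$n_bins + b$n_bins
    a$n_snps <- a$n_snps + b$n_snps
    a
  }
  mergeable <- function(a, b) {
    d1 <- abs(a$mean_logr - b$mean_logr)
    c1 <- is.na(d1) || d1 < tau_merge_logr
    if (!baf_mode) return(c1)
    d2 <- abs(a$mean_cbaf - b$mean_cbaf)
    c1 && (is.na(d2) || d2 < tau_merge_baf)
  }
  out <- lapply(split(segments, segments$chrom), function(seg) {
    seg <- seg[order(seg$start), , drop = FALSE]
    rows <- lapply(seq_len(nrow(seg)), function(i) seg[i, ])
    repeat {
      changed <- FALSE
      i <- 1L
      while (i < length(rows)) {
        if (mergeable(rows[[i]], rows[[i + 1L]])) {
          rows[[i]] <- merge_pair(rows[[i]], rows[[i + 1L]])
          rows[[i + 1L]] <- NULL
          changed <- TRUE
        } else i <- i + 1L
      }
      if (!changed) break
    }
    do.call(rbind, rows)
  })
  d <- do.call(rbind, out)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}
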