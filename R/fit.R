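#' Segment a tumor/normal joint signal
#'
#' The main fitting function: runs multi-scale double sliding-window
#' breakpoint detection on the corrected log2-ratio and cBAF signals, builds
#' tiling segments between consensus breakpoints, and merges adjacent
#' segments whose means are indistinguishable.  The result is a
#' piecewise-constant fit of both signals.
#'
#' @param signal A [joint_signal()] object.
#' @param params A [segmentation_params()] object.  When the signal carries
#'   no BAF information, BAF mode is switched off automatically.
#' @param cnloh Optional [cnloh_params()]; when supplied (and BAF mode is on)
#'   segments are annotated with cnLOH flags.
#' @return An object of class `dsw_fit` with components `segments`,
#'   `breakpoints`, `schedule`, `params` and `signal`, supporting `print`,
#'   `summary`, `coef`, `fitted`, `residuals` and `plot`.
#' @export
dsw_segment <- function(signal, params = segmentation_params(),
                        cnloh = NULL) {
  stopifnot(inherits(signal, "joint_signal"))
  has_baf <- !is.null(signal$snp_cbaf) ||
    any(vapply(signal$cbaf, function(v) any(!is.na(v)), TRUE))
  if (params$baf_mode && !has_baf) {
    message("signal carries no BAF information; segmenting in ",
            "log-ratio-only mode")
    params$baf_mode <- FALSE
  }
  bp <- multiscale_detect(signal, params)
  seg <- build_segments(bp, signal)
  seg <- merge_segments(seg, params$tau_merge_logr, params$tau_merge_baf,
                        params$baf_mode)
  fit <- structure(list(segments = seg, breakpoints = bp,
                        schedule = threshold_schedule(params),
                        params = params, signal = signal),
                   class = "dsw_fit")
  if (!is.null(cnloh) && params$baf_mode)
    fit$segments <- call_cnloh(fit$segments, cnloh)
  fit
}

#' @export
print.dsw_fit <- function(x, ...) {
  cat(sprintf(paste0("Double sliding-window segmentation\n",
                     "  %d chromosome(s), %d bins of %d bp\n",
                     "  %d consensus breakpoint(s) over %d pass(es) ",
                     "(initial window %d bins)\n",
                     "  %d segment(s) after merging\n"),
              length(x$signal$logr),
              sum(vapply(x$signal$logr, length, 0L)), x$signal$bin_width,
              nrow(x$breakpoints), nrow(x$schedule),
              x$params$initial_window, nrow(x$segments)))
  if ("cnloh" %in% names(x$segments))
    cat(sprintf("  %d cnLOH segment(s)\n", sum(x$segments$cnloh)))
  invisible(x)
}

#' @export
summary.dsw_fit <- function(object, ...) {
  s <- object$segments
  per <- tapply(seq_len(nrow(s)), s$chrom, length)
  structure(list(n_segments = nrow(s), per_chromosome = per,
                 segments = s, params = object$params),
            class = "summary.dsw_fit")
}

#' @export
print.summary.dsw_fit <- function(x, ...) {
  cat(sprintf("%d segment(s):\n", x$n_segments))
  print(x$segments)
  invisible(x)
}

#' Segment table of a fit
#' @param object A `dsw_fit`.
#' @param ... Unused.
#' @return The segment `data.frame` (the piecewise-constant coefficients of
#'   the fit).
#' @export
coef.dsw_fit <- function(object, ...) object$segments

#' Per-bin fitted log ratio (segment means)
#' @param object A `dsw_fit`.
#' @param ... Unused.
#' @return Named list of per-chromosome numeric vectors on the bin grid.
#' @export
fitted.dsw_fit <- function(object, ...) {
  sig <- object$signal
  bw <- as.numeric(sig$bin_width)
  seg <- object$segments
  out <- lapply(names(sig$logr), function(ch) {
    v <- rep(NA_real_, length(sig$logr[[ch]]))
    for (i in which(seg$chrom == ch)) {
      bins <- (seg$start[i] %/% bw + 1L):ceiling(seg$end[i] / bw)
      v[bins] <- seg$mean_logr[i]
    }
    v
  })
  names(out) <- names(sig$logr)
  out
}

#' Per-bin log-ratio residuals about the segment means
#' @param object A `dsw_fit`.
#' @param ... Unused.
#' @return Named list of per-chromosome numeric vectors.
#' @export
residuals.dsw_fit <- function(object, ...) {
  f <- stats::fitted(object)
  out <- lapply(names(f), function(ch) object$signal$logr[[ch]] - f[[ch]])
  names(out) <- names(f)
  out
}

#' Plot a segmentation fit
#'
#' One panel per chromosome: per-bin log ratio (grey), fitted segment means
#' (red), and per-bin cBAF (blue, drawn on the [0, 0.5] scale at the bottom)
#' when available.
#'
#' @param x A `dsw_fit`.
#' @param chroms Chromosomes to draw (default: all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dsw_fit <- function(x, chroms = names(x$signal$logr), ...) {
  sig <- x$signal
  bw <- as.numeric(sig$bin_width)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    v <- sig$logr[[ch]]
    pos <- ((seq_along(v) - 0.5) * bw) / 1e6
    graphics::plot(pos, v, pch = ".", col = "grey40", xlab = "Mbp",
                   ylab = "log2 ratio", main = ch,
                   ylim = range(c(v, -1, 1), na.rm = TRUE), ...)
    cb <- sig$cbaf[[ch]]
    if (!is.null(cb) && any(!is.na(cb)))
      graphics::points(pos, cb + min(c(v, -1), na.rm = TRUE) - 0.6,
                       pch = ".", col = "steelblue")
    seg <- x$segments[x$segments$chrom == ch, , drop = FALSE]
    graphics::segments(seg$start / 1e6, seg$mean_logr, seg$end / 1e6,
                       seg$mean_logr, col = "red", lwd = 2)
    if ("cnloh" %in% names(seg) && any(seg$cnloh))
      graphics::rect(seg$start[seg$cnloh] / 1e6, -0.05,
                     seg$end[seg$cnloh] / 1e6, 0.05,
                     border = NA, col = grDevices::adjustcolor("orange", 0.4))
  }
  invisible(x)
}
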