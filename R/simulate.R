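# Tumor/normal simulator: read depth is generated from a first-order chain
# learned from a real (or synthetic) normal track, denoised into a baseline,
# and re-noised with Poisson draws; somatic events act multiplicatively on
# the baseline; allele counts at heterozygous SNPs are binomial with a
# success probability set by the haplotype copy numbers and the normal-cell
# contamination.

#' Learn the adjacent-pair depth distribution from a normal track
#'
#' Counts how often each ordered pair of consecutive read-depth values
#' occurs, chromosome by chromosome (never across a boundary), and derives
#' the conditional distribution of the next value given the current one plus
#' the marginal distribution of all observed values.
#'
#' @param normal_track A `depth_track` with at least 2 bins.
#' @return An object of class `pair_model` with components `pairs` (a table
#'   of ordered pair counts), `conditional` (per observed value: next values
#'   and their probabilities) and `marginal`.
#' @export
learn_pair_model <- function(normal_track) {
  vals <- unlist(lapply(normal_track$counts, function(v) v), use.names = FALSE)
  if (length(vals) < 2L) stop("need at least 2 bins to learn pair counts")
  from <- unlist(lapply(normal_track$counts, function(v)
    v[-length(v)]), use.names = FALSE)
  to <- unlist(lapply(normal_track$counts, function(v) v[-1L]),
               use.names = FALSE)
  ok <- !is.na(from) & !is.na(to)
  from <- from[ok]
  to <- to[ok]
  pair_tab <- table(from = from, to = to)
  cond <- lapply(split(to, from), function(nxt) {
    t <- table(nxt)
    v <- as.numeric(names(t))
    p <- as.numeric(t) / sum(t)
    list(values = v, prob = p, cdf = cumsum(p))
  })
  mt <- table(vals[!is.na(vals)])
  marginal <- list(values = as.numeric(names(mt)),
                   prob = as.numeric(mt) / sum(mt),
                   cdf = cumsum(as.numeric(mt) / sum(mt)))
  structure(list(pairs = pair_tab, conditional = cond, marginal = marginal),
            class = "pair_model")
}

# Inverse-transform draw from a discrete distribution given uniforms.
inv_draw <- function(dist, u) {
  dist$values[findInterval(u, dist$cdf, left.open = TRUE) + 1L]
}

#' Sample a read-depth sequence from a pair model
#'
#' The first value is drawn from the marginal; each subsequent value from the
#' conditional distribution given its predecessor, by inverse-transform
#' sampling on the conditional CDF.  A predecessor value never observed in
#' the training track falls back to the marginal.
#'
#' @param model A [learn_pair_model()] result.
#' @param n_bins Length of the sequence.
#' @param seed Optional integer seed.
#' @return Numeric vector of depths.
#' @export
sample_depth_chain <- function(model, n_bins, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_bins == 0L) return(numeric(0))
  u <- stats::runif(n_bins)
  out <- numeric(n_bins)
  out[1] <- inv_draw(model$marginal, u[1])
  for (i in seq_len(n_bins - 1L)) {
    cond <- model$conditional[[as.character(out[i])]]
    if (is.null(cond)) cond <- model$marginal
    out[i + 1L] <- inv_draw(cond, u[i + 1L])
  }
  out
}

#' Denoise a sampled depth chain into a baseline
#'
#' Median filter with symmetric shrinking windows at the ends.
#'
#' @param raw_chain Numeric vector of depths.
#' @param width Odd filter width in bins (default 9).
#' @return The smoothed baseline.
#' @export
build_baseline <- function(raw_chain, width = 9L) {
  shrinking_median(raw_chain, width)
}

#' Simulated normal read depth: Poisson noise around the baseline
#'
#' @param baseline Named list of per-chromosome baseline vectors, or a single
#'   numeric vector.
#' @param bin_width Bin width in bp.
#' @param noise `"poisson"` or `"none"` (rounded baseline).
#' @param seed Optional integer seed.
#' @return A `depth_track`.
#' @export
make_normal_rd <- function(baseline, bin_width, noise = "poisson",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(baseline)) baseline <- list(chr1 = baseline)
  counts <- lapply(baseline, function(b) {
    if (noise == "poisson") stats::rpois(length(b), b) else round(b)
  })
  depth_track(counts, bin_width)
}

#' Place random somatic events and build haplotype copy-number tracks
#'
#' Autosomes carry one maternal and one paternal copy, so two integer tracks
#' `cnA`/`cnB` are maintained per chromosome (1/1 outside events).  Events
#' are drawn uniformly over the requested types, with log-uniform sizes,
#' placed uniformly without overlap (bounded retries), snapped to bin
#' boundaries.  Deletions decrement one haplotype, amplifications increment
#' one, cnLOH sets one to 0 and the other to 2.
#'
#' @param params A [simulation_params()] object.
#' @param seed Optional integer seed.
#' @return List with `cn` (per chromosome, matrix-like list of `cnA`, `cnB`
#'   integer vectors per bin), `events` (the placed events) and `truth` (the
#'   tiling ground-truth segment list with per-segment cnA/cnB and label).
#' @export
generate_cn_tracks <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bw <- as.numeric(params$bin_width)
  nbins <- vapply(params$genome, function(L) as.integer(ceiling(L / bw)), 0L)
  cn <- lapply(nbins, function(n)
    list(cnA = rep(1L, n), cnB = rep(1L, n)))
  events <- NULL
  gap_bins <- as.integer(ceiling(params$min_event_gap / bw))
  # blocked bins: existing events padded by the gap, plus chromosome ends
  blocked <- lapply(nbins, function(n) {
    b <- logical(n)
    if (gap_bins > 0) {
      b[seq_len(min(gap_bins, n))] <- TRUE
      b[seq.int(max(1L, n - gap_bins + 1L), n)] <- TRUE
    }
    b
  })
  if (params$n_events > 0) {
    lsz <- log(params$event_size_range)
    for (e in seq_len(params$n_events)) {
      done <- FALSE
      for (try in seq_len(200L)) {
        size_bins <- max(1L, as.integer(round(
          exp(stats::runif(1, lsz[1], lsz[2])) / bw)))
        ch <- sample(names(params$genome), 1L,
                     prob = params$genome / sum(params$genome))
        n <- nbins[[ch]]
        if (size_bins >= n) next
        s <- sample.int(n - size_bins, 1L)  # first bin of event
        idx <- s:(s + size_bins - 1L)
        if (any(blocked[[ch]][idx])) next
        type <- sample(params$event_types, 1L)
        hap <- sample(c("A", "B"), 1L)
        if (type == "deletion") {
          if (hap == "A") cn[[ch]]$cnA[idx] <- 0L
          else cn[[ch]]$cnB[idx] <- 0L
        } else if (type == "amplification") {
          if (hap == "A") cn[[ch]]$cnA[idx] <- 2L
          else cn[[ch]]$cnB[idx] <- 2L
        } else {  # cnLOH: hap is the retained, duplicated haplotype
          if (hap == "A") {
            cn[[ch]]$cnA[idx] <- 2L
            cn[[ch]]$cnB[idx] <- 0L
          } else {
            cn[[ch]]$cnA[idx] <- 0L
            cn[[ch]]$cnB[idx] <- 2L
          }
        }
        pad <- max(0L, gap_bins)
        blocked[[ch]][max(1L, s - pad):min(n, s + size_bins - 1L + pad)] <-
          TRUE
        events <- rbind(events, data.frame(
          chrom = ch, start = (s - 1L) * bw, end = (s - 1L + size_bins) * bw,
          type = type, haplotype = hap, stringsAsFactors = FALSE))
        done <- TRUE
        break
      }
      if (!done)
        stop("could not place event ", e, " without overlap; ",
             "reduce n_events or event sizes")
    }
  }
  truth <- cn_truth_segments(cn, params)
  list(cn = cn, events = events, truth = truth)
}

# Collapse per-bin haplotype tracks into a tiling ground-truth segment list.
cn_truth_segments <- function(cn, params) {
  bw <- as.numeric(params$bin_width)
  rows <- lapply(names(cn), function(ch) {
    a <- cn[[ch]]$cnA
    b <- cn[[ch]]$cnB
    key <- paste(a, b)
    r <- rle(key)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, ends_bin[-length(ends_bin)])
    i1 <- starts_bin + 1L
    lab <- function(ai, bi) {
      tot <- ai + bi
      if (tot == 2 && min(ai, bi) == 0) "cnloh"
      else if (tot < 2) "deletion"
      else if (tot > 2) "amplification"
      else "neutral"
    }
    data.frame(chrom = ch, start = starts_bin * bw,
               end = pmin(ends_bin * bw, params$genome[[ch]]),
               cnA = a[i1], cnB = b[i1],
               label = mapply(lab, a[i1], b[i1]),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' Simulated tumor read depth under contamination
#'
#' Per-bin expected depth is `baseline * (c*2 + (1-c)*(cnA+cnB)) / 2`: a
#' fraction `c` of cells is diploid normal, the rest carry the event copy
#' numbers, and depth is normalized to the diploid baseline.  Poisson noise
#' as for the normal sample.
#'
#' @param baseline Named list of per-chromosome baseline vectors.
#' @param cn Haplotype copy-number tracks from [generate_cn_tracks()].
#' @param contamination Normal-cell fraction `c` in `[0, 1)`.
#' @param bin_width Bin width in bp.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Optional integer seed.
#' @return A `depth_track`.
#' @export
make_tumor_rd <- function(baseline, cn, contamination, bin_width,
                          noise = "poisson", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- contamination
  counts <- lapply(names(baseline), function(ch) {
    tot <- cn[[ch]]$cnA + cn[[ch]]$cnB
    mu <- baseline[[ch]] * (cc * 2 + (1 - cc) * tot) / 2
    if (noise == "poisson") stats::rpois(length(mu), mu) else round(mu)
  })
  names(counts) <- names(baseline)
  depth_track(counts, bin_width)
}

#' Place heterozygous SNP positions
#'
#' A homogeneous Poisson point process: exponential inter-arrival distances
#' with the configured mean spacing (default 1500 bp, i.e. 1 SNP per
#' 1.5 kbp), per chromosome; positions are sorted and deduplicated.
#'
#' @param params A [simulation_params()] object.
#' @param seed Optional integer seed.
#' @return `data.frame` with chrom and 0-based pos.
#' @export
place_het_snps <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(params$genome), function(ch) {
    L <- params$genome[[ch]]
    n_exp <- ceiling(L / params$snp_spacing * 1.3) + 10
    pos <- cumsum(stats::rexp(n_exp, rate = 1 / params$snp_spacing))
    while (pos[length(pos)] < L)
      pos <- c(pos, pos[length(pos)] +
                 cumsum(stats::rexp(n_exp, rate = 1 / params$snp_spacing)))
    pos <- unique(floor(pos[pos < L]))
    if (!length(pos)) return(NULL)
    data.frame(chrom = ch, pos = as.integer(pos), stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    d <- data.frame(chrom = character(), pos = integer(),
                    stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}

#' Simulate B-allele fractions at heterozygous SNPs
#'
#' Each SNP's B allele is assigned to haplotype A or B with probability 1/2.
#' The alt count is `Binomial(n, p)` with `n` the simulated normal read
#' depth at the SNP's bin and
#' `p = (c + (1-c)*cn_bhap) / (c*2 + (1-c)*(cnA+cnB))` — the fraction of
#' DNA copies carrying the B allele in the contaminated mixture.  SNPs with
#' `n = 0` (or no DNA at all in the mixture) are dropped.
#'
#' @param snps SNP positions from [place_het_snps()].
#' @param normal_rd Simulated normal `depth_track`.
#' @param cn Haplotype copy-number tracks.
#' @param contamination Normal-cell fraction.
#' @param seed Optional integer seed.
#' @return BAF `data.frame` with an extra `b_hap` column recording the
#'   haplotype carrying the B allele.
#' @export
simulate_baf <- function(snps, normal_rd, cn, contamination, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- contamination
  bw <- as.numeric(normal_rd$bin_width)
  rows <- lapply(names(normal_rd$counts), function(ch) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    bin <- pmin(s$pos %/% bw + 1L, length(normal_rd$counts[[ch]]))
    n <- normal_rd$counts[[ch]][bin]
    cnA <- cn[[ch]]$cnA[bin]
    cnB <- cn[[ch]]$cnB[bin]
    on_a <- stats::runif(nrow(s)) < 0.5
    cn_b <- ifelse(on_a, cnA, cnB)
    denom <- cc * 2 + (1 - cc) * (cnA + cnB)
    keep <- n > 0 & denom > 0
    if (!any(keep)) return(NULL)
    p <- (cc * 1 + (1 - cc) * cn_b[keep]) / denom[keep]
    alt <- stats::rbinom(sum(keep), n[keep], p)
    d <- baf_track(rep(ch, sum(keep)), s$pos[keep], n[keep] - alt, alt)
    d$b_hap <- ifelse(on_a[keep], "A", "B")
    d
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) {
    d <- baf_track(character(), integer(), integer(), integer())
    d$b_hap <- character(0)
  }
  rownames(d) <- NULL
  d
}

#' Synthetic normal read-depth track
#'
#' Builds a spatially correlated depth track to train the pair model on when
#' no real normal track is available: a slowly drifting mean (random walk,
#' reflected into a band around `mean_depth`) with Poisson observation
#' noise — mimicking the smooth coverage waves plus counting noise seen in
#' real whole-genome data.
#'
#' @param params A [simulation_params()] object.
#' @param seed Optional integer seed.
#' @return A `depth_track`.
#' @export
synthetic_normal_track <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bw <- as.numeric(params$bin_width)
  md <- params$mean_depth
  counts <- lapply(params$genome, function(L) {
    n <- as.integer(ceiling(L / bw))
    drift <- cumsum(stats::rnorm(n, 0, md * 0.005))
    band <- md * 0.15
    drift <- band * sin(drift / band)  # keep the wave inside +/- band
    stats::rpois(n, pmax(md + drift, 1))
  })
  depth_track(counts, params$bin_width, params$genome)
}

#' Run the full tumor/normal simulation
#'
#' Learns the pair model from the supplied (or synthetic) normal track,
#' samples a fresh depth chain, denoises it into the baseline, draws the
#' simulated normal and tumor depth tracks, places events and heterozygous
#' SNPs, and simulates BAF values — returning the four outputs plus ground
#' truth.
#'
#' @param params A [simulation_params()] object.
#' @param normal_track Optional real normal `depth_track` to learn from.
#' @param seed Optional integer seed (fixes all randomness; identical
#'   params + seed give identical outputs).
#' @return An object of class `tn_simulation`: list with `normal`, `tumor`
#'   (`depth_track`s), `baf` (BAF `data.frame`), `truth` (ground-truth
#'   segments), `events`, `cn` and `params`.
#' @export
simulate_tumor_normal <- function(params = simulation_params(),
                                  normal_track = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(normal_track)) normal_track <- synthetic_normal_track(params)
  model <- learn_pair_model(normal_track)
  bw <- as.numeric(params$bin_width)
  baseline <- lapply(params$genome, function(L)
    build_baseline(sample_depth_chain(model, as.integer(ceiling(L / bw))),
                   params$median_filter_width))
  normal <- make_normal_rd(baseline, params$bin_width, params$depth_noise)
  tracks <- generate_cn_tracks(params)
  tumor <- make_tumor_rd(baseline, tracks$cn, params$contamination,
                         params$bin_width, params$depth_noise)
  snps <- place_het_snps(params)
  baf <- simulate_baf(snps, normal, tracks$cn, params$contamination)
  structure(list(normal = normal, tumor = tumor, baf = baf,
                 truth = tracks$truth, events = tracks$events,
                 cn = tracks$cn, params = params),
            class = "tn_simulation")
}

#' @export
print.tn_simulation <- function(x, ...) {
  cat(sprintf(paste0("tumor/normal simulation: %d chromosome(s), ",
                     "%d bins, %d SNPs, %d event(s), contamination %.2f\n"),
              length(x$params$genome),
              sum(vapply(x$normal$counts, length, 0L)), nrow(x$baf),
              if (is.null(x$events)) 0L else nrow(x$events),
              x$params$contamination))
  invisible(x)
}

#' Ground-truth breakpoint positions of a simulation
#'
#' Internal boundaries of the truth segment list (chromosome ends excluded).
#'
#' @param sim A `tn_simulation` (or its `truth` segment `data.frame`).
#' @return `data.frame` with chrom and pos.
#' @export
truth_breakpoints <- function(sim) {
  truth <- if (inherits(sim, "tn_simulation")) sim$truth else sim
  rows <- lapply(split(truth, truth$chrom), function(tr) {
    p <- sort(unique(c(tr$start, tr$end)))
    p <- p[p > min(tr$start) & p < max(tr$end)]
    if (!length(p)) return(NULL)
    data.frame(chrom = tr$chrom[1], pos = p, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    d <- data.frame(chrom = character(), pos = numeric(),
                    stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}
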