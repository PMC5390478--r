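# Double sliding-window detection, the multi-scale schedule, segment
# construction and merging.

test_that("compound score normalizes each squared difference by tau^2", {
  expect_equal(compound_score(c(0.5, 0.1), c(0.5, 0.1), 0.1, 0.1), 0)
  # difference exactly at threshold sits on the S = 1 boundary
  expect_equal(compound_score(c(0.1, NA), c(0.2, NA), 0.1, 0.1), 1)
  expect_equal(compound_score(c(0, NA), c(0.2, NA), 0.1, 0.1), 4)
  # both terms add
  expect_equal(compound_score(c(0, 0), c(0.1, 0.2), 0.1, 0.1), 1 + 4)
  # BAF-less mode drops the second term
  expect_equal(compound_score(c(0, 0), c(0, 0.2), 0.1, 0.1,
                              baf_mode = FALSE), 0)
  expect_true(is.na(compound_score(c(NA, 0), c(0, 0), 0.1, 0.1)))
})

test_that("a clean step yields exactly one breakpoint where windows touch", {
  sig <- make_signal(c(rep(0, 100), rep(1, 100)))
  bp <- detect_breakpoints(sig, window = 10, tau_logr = 0.1, tau_baf = 0.1,
                           baf_mode = FALSE)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$pos, 100 * 1000)

  # constant signal: nothing
  expect_equal(nrow(detect_breakpoints(make_signal(rep(0.3, 200)), 10,
                                       0.1, 0.1, baf_mode = FALSE)), 0)
})

test_that("a step in cBAF alone is detected through the second score term", {
  sig <- make_signal(rep(0, 200), c(rep(0, 100), rep(0.45, 100)))
  bp <- detect_breakpoints(sig, 10, tau_logr = 0.1, tau_baf = 0.1)
  expect_equal(bp$pos, 100 * 1000)
  # and is invisible in BAF-less mode
  expect_equal(nrow(detect_breakpoints(sig, 10, 0.1, 0.1,
                                       baf_mode = FALSE)), 0)
})

test_that("boundaries with mostly missing windows are skipped", {
  v <- c(rep(0, 100), rep(1, 100))
  v[91:100] <- NA  # left window at the step boundary now fully missing
  sig <- make_signal(v)
  bp <- detect_breakpoints(sig, 10, 0.1, 0.1, baf_mode = FALSE)
  # the step is still found nearby, at a boundary with enough data
  expect_true(all(abs(bp$pos - 1e5) <= 10 * 1000))
  expect_false(1e5 %in% bp$pos)
})

test_that("the threshold schedule decays by 1/sqrt(1.5) until a merge
           threshold is reached", {
  p <- segmentation_params(initial_window = 10, tau_logr = 0.4,
                           tau_baf = 0.15, tau_merge_logr = 0.1,
                           tau_merge_baf = 0.05, baf_mode = FALSE)
  sched <- threshold_schedule(p)
  expect_equal(nrow(sched), 7)  # 8th threshold 0.0968 <= 0.1 never runs
  expect_equal(sched$tau_logr, 0.4 * 1.5^(-(1:7 - 1) / 2))
  expect_equal(sched$window, c(10, 15, 23, 35, 53, 80, 120))
  # with the BAF condition active the BAF threshold stops the loop earlier
  p2 <- segmentation_params(initial_window = 10, tau_logr = 0.4,
                            tau_baf = 0.15, tau_merge_logr = 0.1,
                            tau_merge_baf = 0.05, baf_mode = TRUE)
  expect_equal(nrow(threshold_schedule(p2)), 6)
})

test_that("multiscale consensus keeps one copy of a re-found breakpoint and
           adds sub-threshold steps found at larger scales", {
  p <- segmentation_params(initial_window = 10, tau_logr = 0.4,
                           tau_baf = 0.15, tau_merge_logr = 0.1,
                           tau_merge_baf = 0.05, baf_mode = FALSE)
  # steps of 1.2*tau (pass 1) and 0.9*tau (needs one tau decay)
  sig <- make_signal(c(rep(0, 60), rep(0.48, 60), rep(0.48 + 0.36, 60)))
  bp <- multiscale_detect(sig, p)
  expect_equal(bp$pos, c(60, 120) * 1000)
  expect_equal(bp$pass[bp$pos == 60000], 1)
  expect_gt(bp$pass[bp$pos == 120000], 1)

  # one large step: re-detected at every pass, kept once
  sig2 <- make_signal(c(rep(0, 300), rep(1, 300)))
  bp2 <- multiscale_detect(sig2, p)
  expect_equal(bp2$pos, 300 * 1000)
})

test_that("lowering tau_logr never removes a pass-1 breakpoint", {
  set.seed(21)
  v <- rep(c(0, 0.6, 0.1, 0.9), each = 50) + rnorm(200, 0, 0.05)
  sig <- make_signal(v)
  hi <- detect_breakpoints(sig, 10, 0.3, 0.1, baf_mode = FALSE)
  lo <- detect_breakpoints(sig, 10, 0.15, 0.1, baf_mode = FALSE)
  expect_true(all(hi$pos %in% lo$pos))
})

test_that("segments tile the chromosome between consensus breakpoints", {
  sig <- make_signal(list(chrA = c(rep(0.9, 10), rep(1.1, 10), NA,
                                   rep(1, 9))),
                     bin_width = 1000)
  # no breakpoints: one whole-chromosome segment
  none <- build_segments(data.frame(chrom = character(), pos = numeric()),
                         sig)
  expect_equal(nrow(none), 1)
  expect_equal(c(none$start, none$end), c(0, 30000))

  seg <- build_segments(data.frame(chrom = "chrA", pos = 20000), sig)
  expect_equal(seg$start, c(0, 20000))
  expect_equal(seg$end, c(20000, 30000))
  expect_equal(seg$mean_logr, c(1, 1))
  expect_equal(seg$n_bins, c(20, 9))  # the missing bin is not support

  # tiling invariant on a random breakpoint set
  bps <- data.frame(chrom = "chrA", pos = c(5000, 12000, 21000))
  seg2 <- build_segments(bps, sig)
  expect_equal(seg2$start, c(0, head(seg2$end, -1)))
  expect_equal(seg2$end[nrow(seg2)], 30000)
})

test_that("merging joins indistinguishable neighbours with support-weighted
           means and stops at a fixed point", {
  seg <- data.frame(chrom = "chr1", start = c(0, 1e4), end = c(1e4, 2e4),
                    n_bins = c(10L, 30L), n_snps = c(10L, 30L),
                    mean_logr = c(0.50, 0.52), mean_cbaf = c(0.10, 0.11),
                    stringsAsFactors = FALSE)
  m <- merge_segments(seg, 0.1, 0.05)
  expect_equal(nrow(m), 1)
  expect_equal(m$mean_logr, (0.50 * 10 + 0.52 * 30) / 40)
  expect_equal(m$mean_cbaf, (0.10 * 10 + 0.11 * 30) / 40)
  expect_equal(m$n_bins, 40L)

  # a 0.2 log-ratio gap survives a 0.1 merge threshold
  seg$mean_logr <- c(0.5, 0.7)
  expect_equal(nrow(merge_segments(seg, 0.1, 0.05)), 2)
  # ... and both conditions must hold
  seg$mean_logr <- c(0.5, 0.52)
  seg$mean_cbaf <- c(0.1, 0.4)
  expect_equal(nrow(merge_segments(seg, 0.1, 0.05)), 2)
  expect_equal(nrow(merge_segments(seg, 0.1, 0.05, baf_mode = FALSE)), 1)

  # three identical segments collapse transitively to one
  seg3 <- data.frame(chrom = "chr1", start = c(0, 1e4, 2e4),
                     end = c(1e4, 2e4, 3e4), n_bins = rep(10L, 3),
                     n_snps = rep(10L, 3), mean_logr = rep(0.3, 3),
                     mean_cbaf = rep(0.2, 3), stringsAsFactors = FALSE)
  expect_equal(nrow(merge_segments(seg3, 0.1, 0.05)), 1)
})

test_that("after merging no adjacent pair satisfies both merge conditions", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 12
    seg <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e4,
                      end = (1:n) * 1e4, n_bins = rep(10L, n),
                      n_snps = rep(10L, n),
                      mean_logr = sample(c(0, 0.05, 0.3, 0.6), n, TRUE),
                      mean_cbaf = sample(c(0, 0.02, 0.25), n, TRUE),
                      stringsAsFactors = FALSE)
    m <- merge_segments(seg, 0.1, 0.05)
    if (nrow(m) > 1) {
      d1 <- abs(diff(m$mean_logr))
      d2 <- abs(diff(m$mean_cbaf))
      expect_true(all(d1 >= 0.1 | d2 >= 0.05))
    }
    expect_equal(m$start, c(0, head(m$end, -1)))  # still tiling
  }
})

test_that("noiseless piecewise-constant signals are recovered exactly", {
  p <- segmentation_params(initial_window = 10, tau_logr = 0.4,
                           tau_baf = 0.15, tau_merge_logr = 0.1,
                           tau_merge_baf = 0.05, baf_mode = FALSE)
  set.seed(44)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    lens <- sample(25:80, k, replace = TRUE)
    means <- cumsum(c(0, sample(c(-1, 1), k - 1, TRUE) *
                        runif(k - 1, 0.45, 1.5)))
    v <- rep(means, lens)
    sig <- make_signal(v)
    bp <- multiscale_detect(sig, p)
    expect_equal(bp$pos, cumsum(lens)[-k] * 1000)
  }
})
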