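# The tumor/normal simulator: pair model, depth chain, events, BAF.

test_that("pair counts equal a brute-force dictionary of adjacent pairs", {
  tr <- depth_track(list(c1 = c(5, 5, 7)), 1000)
  m <- learn_pair_model(tr)
  expect_equal(as.integer(m$pairs["5", "5"]), 1L)
  expect_equal(as.integer(m$pairs["5", "7"]), 1L)

  # constant track: one self-pair with conditional mass 1
  mc <- learn_pair_model(depth_track(list(c1 = rep(9, 20)), 1000))
  expect_equal(mc$conditional[["9"]]$prob, 1)
  expect_equal(mc$conditional[["9"]]$values, 9)

  set.seed(3)
  v <- sample(1:6, 400, TRUE)
  m2 <- learn_pair_model(depth_track(list(c1 = v), 1000))
  dict <- table(paste(v[-length(v)], v[-1]))
  for (key in names(dict)) {
    ft <- strsplit(key, " ")[[1]]
    expect_equal(as.integer(m2$pairs[ft[1], ft[2]]),
                 as.integer(dict[[key]]))
  }
  expect_error(learn_pair_model(depth_track(list(c1 = 5), 1000)),
               "2 bins")
})

test_that("pair counting never crosses a chromosome boundary", {
  m <- learn_pair_model(depth_track(list(a = c(1, 1), b = c(2, 2)), 1000))
  expect_true(is.na(m$pairs["1", "2"]) || m$pairs["1", "2"] == 0)
})

test_that("depth chain sampling is deterministic and respects degenerate
           models", {
  tr <- depth_track(list(c1 = rep(5, 10)), 1000)
  m <- learn_pair_model(tr)
  expect_equal(sample_depth_chain(m, 20, seed = 1), rep(5, 20))
  long1 <- sample_depth_chain(m, 50, seed = 9)
  long2 <- sample_depth_chain(m, 50, seed = 9)
  expect_identical(long1, long2)
})

test_that("the sampled chain reaches the stationary distribution of a 3-state
           toy model", {
  P <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.3, 0.3, 0.4))
  states <- c(10, 20, 30)
  model <- structure(list(
    conditional = stats::setNames(lapply(1:3, function(i)
      list(values = states, prob = P[i, ], cdf = cumsum(P[i, ]))),
      as.character(states)),
    marginal = list(values = states, prob = rep(1 / 3, 3),
                    cdf = cumsum(rep(1 / 3, 3)))), class = "pair_model")
  # independent oracle: stationary distribution by power iteration
  pi0 <- rep(1 / 3, 3)
  for (i in 1:200) pi0 <- as.numeric(pi0 %*% P)
  chain <- sample_depth_chain(model, 3e4, seed = 5)
  freq <- as.numeric(table(factor(chain, levels = states))) / length(chain)
  expect_true(all(abs(freq - pi0) < 0.02))
})

test_that("the baseline median filter removes isolated spikes", {
  expect_equal(build_baseline(rep(7, 30)), rep(7, 30))
  spiky <- rep(100, 30)
  spiky[15] <- 500
  expect_equal(build_baseline(spiky), rep(100, 30))
  x <- c(3, 9, 4, 8)
  expect_equal(build_baseline(x, width = 1), x)
})

test_that("normal depth is Poisson around the baseline", {
  z <- make_normal_rd(list(c1 = rep(0, 100)), 1000, seed = 1)
  expect_true(all(z$counts$c1 == 0))
  n <- 1e5
  y <- make_normal_rd(list(c1 = rep(100, n)), 1000, seed = 2)$counts$c1
  expect_lt(abs(mean(y) - 100), 3 * sqrt(100 / n))
  expect_lt(abs(var(y) / mean(y) - 1), 0.05)  # dispersion ~ 1
  # noiseless mode rounds the baseline
  exact <- make_normal_rd(list(c1 = c(10.4, 10.6)), 1000, noise = "none")
  expect_equal(exact$counts$c1, c(10, 11))
})

test_that("event placement produces consistent haplotype tracks and truth", {
  p0 <- simulation_params(genome = c(c1 = 2e6), n_events = 0)
  t0 <- generate_cn_tracks(p0, seed = 1)
  expect_true(all(t0$cn$c1$cnA == 1) && all(t0$cn$c1$cnB == 1))
  expect_equal(t0$truth$label, "neutral")

  p1 <- simulation_params(genome = c(c1 = 10e6), n_events = 1,
                          event_size_range = c(1e6, 2e6),
                          event_types = "cnloh")
  t1 <- generate_cn_tracks(p1, seed = 2)
  ev <- t1$events
  idx <- (ev$start / 2000 + 1):(ev$end / 2000)
  tot <- t1$cn$c1$cnA + t1$cn$c1$cnB
  expect_true(all(tot[idx] == 2))
  expect_true(all(pmin(t1$cn$c1$cnA, t1$cn$c1$cnB)[idx] == 0))
  expect_true(all(t1$cn$c1$cnA[-idx] == 1))

  # the truth segment list reconstructs the tracks exactly
  reA <- integer(length(tot))
  reB <- integer(length(tot))
  for (i in seq_len(nrow(t1$truth))) {
    bins <- (t1$truth$start[i] / 2000 + 1):ceiling(t1$truth$end[i] / 2000)
    reA[bins] <- t1$truth$cnA[i]
    reB[bins] <- t1$truth$cnB[i]
  }
  expect_equal(reA, t1$cn$c1$cnA)
  expect_equal(reB, t1$cn$c1$cnB)

  # infeasible event loads fail loudly
  p_bad <- simulation_params(genome = c(c1 = 3e6), n_events = 10,
                             event_size_range = c(2e6, 2.5e6))
  expect_error(generate_cn_tracks(p_bad, seed = 3), "overlap")
})

test_that("tumor depth follows the contamination mixture formula", {
  n <- 50
  base <- list(c1 = rep(100, n))
  diploid <- list(c1 = list(cnA = rep(1L, n), cnB = rep(1L, n)))
  tetra <- list(c1 = list(cnA = rep(2L, n), cnB = rep(2L, n)))
  zero <- list(c1 = list(cnA = rep(0L, n), cnB = rep(0L, n)))
  expect_equal(make_tumor_rd(base, diploid, 0.7, 1000,
                             noise = "none")$counts$c1, rep(100, n))
  expect_equal(make_tumor_rd(base, tetra, 0, 1000,
                             noise = "none")$counts$c1, rep(200, n))
  expect_equal(make_tumor_rd(base, zero, 0.5, 1000,
                             noise = "none")$counts$c1, rep(50, n))
})

test_that("tumor/normal depth ratio converges to the mixture factor", {
  n <- 2e4
  base <- list(c1 = rep(80, n))
  cn21 <- list(c1 = list(cnA = rep(2L, n), cnB = rep(1L, n)))
  set.seed(10)
  tum <- make_tumor_rd(base, cn21, 0.2, 1000)
  nor <- make_normal_rd(base, 1000)
  expected <- (0.2 * 2 + 0.8 * 3) / 2
  ratio <- sum(tum$counts$c1) / sum(nor$counts$c1)
  se <- expected * sqrt(1 / (80 * n) + expected / (80 * n * expected))
  expect_lt(abs(ratio - expected), 3 * se)
})

test_that("SNP placement is a 1/1500 bp Poisson process", {
  p <- simulation_params(genome = c(c1 = 15e6))
  snps <- place_het_snps(p, seed = 4)
  n_expected <- 15e6 / 1500
  expect_lt(abs(nrow(snps) - n_expected), 3 * sqrt(n_expected))
  expect_true(!is.unsorted(snps$pos))
  expect_true(all(snps$pos >= 0 & snps$pos < 15e6))
  expect_identical(snps, place_het_snps(p, seed = 4))
})

test_that("simulated BAF follows the binomial mixture model", {
  n <- 4000
  nr <- depth_track(list(c1 = rep(100L, n)), 1500)
  snps <- data.frame(chrom = "c1", pos = seq(0, by = 1500, length.out = n))
  diploid <- list(c1 = list(cnA = rep(1L, n), cnB = rep(1L, n)))
  b <- simulate_baf(snps, nr, diploid, 0.3, seed = 6)
  expect_lt(abs(mean(b$baf) - 0.5), 3 * sd(b$baf) / sqrt(nrow(b)))

  # pure-tumor cnLOH: every BAF is exactly 0 or 1 by haplotype
  loh <- list(c1 = list(cnA = rep(2L, n), cnB = rep(0L, n)))
  b2 <- simulate_baf(snps, nr, loh, 0, seed = 7)
  expect_true(all(b2$baf[b2$b_hap == "A"] == 1))
  expect_true(all(b2$baf[b2$b_hap == "B"] == 0))

  # hemizygous deletion at 50% contamination: p = 2/3 on the retained copy
  del <- list(c1 = list(cnA = rep(1L, n), cnB = rep(0L, n)))
  b3 <- simulate_baf(snps, nr, del, 0.5, seed = 8)
  kept <- b3$baf[b3$b_hap == "A"]
  expect_lt(abs(mean(kept) - 2 / 3), 3 * sd(kept) / sqrt(length(kept)))
})

test_that("the full simulation is reproducible from its seed", {
  p <- simulation_params(genome = c(c1 = 2e6), n_events = 1,
                         event_size_range = c(2e5, 5e5),
                         contamination = 0.2)
  s1 <- simulate_tumor_normal(p, seed = 99)
  s2 <- simulate_tumor_normal(p, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_tumor_normal(p, seed = 100)
  expect_false(identical(s1$baf, s3$baf))
})
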