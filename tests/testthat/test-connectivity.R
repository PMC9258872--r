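test_that("cross-correlogram bins lags as specified", {
  ccg <- crossCorrelogram(c(100, 200), c(103, 203))
  expect_length(ccgCounts(ccg), 30)
  peakBin <- which.max(ccgCounts(ccg))
  expect_equal(sum(ccgCounts(ccg)), 2)
  # both lags are +3 ms: the bin covering 3 ms has left edge 2.6
  expect_true(ccgLags(ccg)[peakBin] - 0.65 <= 3 &&
              ccgLags(ccg)[peakBin] + 0.65 > 3)
  # comparison spikes outside the window leave all-zero counts
  ccg0 <- crossCorrelogram(c(100), c(500))
  expect_true(all(ccgCounts(ccg0) == 0))
  expect_error(crossCorrelogram(numeric(), c(1)), "non-empty")
})

test_that("correlogram counts equal the brute-force pair loop", {
  set.seed(21)
  for (i in 1:8) {
    ref <- sort(runif(sample(5:50, 1), 0, 500))
    cmp <- sort(runif(sample(5:50, 1), 0, 500))
    expect_equal(ccgCounts(crossCorrelogram(ref, cmp)), bruteCcg(ref, cmp))
    # time-reversal: CCG(i->j) at lag tau equals CCG(j->i) at -tau
    # (mirrored bins; continuous times make edge hits a null event)
    fw <- ccgCounts(crossCorrelogram(ref, cmp))
    bw <- ccgCounts(crossCorrelogram(cmp, ref))
    expect_equal(fw[16:30], rev(bw[1:15]))
  }
})

test_that("jittered trains preserve counts and are uniformly displaced", {
  tr <- sort(runif(500, 0, 5000))
  j <- jitterTrain(tr, 5, seed = 1)
  expect_length(j, 500)
  expect_false(is.unsorted(j))
  expect_identical(jitterTrain(tr, 0), tr)
  # shift distribution uniform on [-5, 5]
  set.seed(2)
  big <- seq(0, 1e5, by = 10)
  shifts <- sort(jitterTrain(big, 5, seed = 3)) - big
  ks <- suppressWarnings(ks.test(shifts, "punif", -5, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("edge classification applies the stated standardization", {
  counts <- rep(10L, 30)
  counts[17] <- 30L   # peak at lag ~2 ms
  ccg <- new("Correlogram", lags = -19.5 + 1.3 * (1:30 - 0.5),
             counts = counts, binWidth = 1.3, nRefSpikes = 100L)
  band <- list(peak_mean = 10, peak_sd = 4, trough_mean = 10, trough_sd = 4,
               grand_mean = 10, band97_peak_offset = 3,
               band97_trough_offset = -3, n_surrogates = 100)
  e <- classifyEdge(ccg, band)
  expect_equal(e$strength_exc, (30 - 10) / 4)   # = 5
  expect_equal(e$sign, "excitatory")
  expect_gt(e$peak_lag_ms, 0)
  # degenerate null: flagged, not classified
  band0 <- band
  band0$peak_sd <- 0
  band0$trough_sd <- 0
  expect_warning(e0 <- classifyEdge(ccg, band0), "degenerate")
  expect_equal(e0$sign, "none")
})

test_that("independent Poisson pairs are rarely classified as connected", {
  fp <- c(excitatory = 0, inhibitory = 0)
  nPairs <- 60
  for (s in seq_len(nPairs)) {
    r <- poissonRaster(2, 20000, rate = 5, seed = 3000 + s)
    tr <- spikeTrains(r)
    e <- classifyEdge(crossCorrelogram(tr[[1]], tr[[2]]),
                      surrogateBand(tr[[1]], tr[[2]], seed = s))
    if (e$sign != "none") fp[e$sign] <- fp[e$sign] + 1
  }
  expect_lte(fp[["excitatory"]] / nPairs, 0.03)
  expect_lte(fp[["inhibitory"]] / nPairs, 0.03)
})

test_that("an embedded monosynaptic coupling is detected as excitatory", {
  hits <- 0
  for (s in 1:10) {
    r <- coupledRaster(2, 60000, rate = 5,
                       coupling = data.frame(pre = 0, post = 1,
                                             lag_ms = 2, prob = 0.3),
                       seed = s)
    tr <- spikeTrains(r)
    e <- classifyEdge(crossCorrelogram(tr[[1]], tr[[2]]),
                      surrogateBand(tr[[1]], tr[[2]], seed = s))
    if (e$sign == "excitatory" && e$peak_lag_ms > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("functional network summary counts significant pairs correctly", {
  cpl <- data.frame(pre = 0, post = 1, lag_ms = 2, prob = 0.5)
  r <- coupledRaster(4, 60000, rate = 5, coupling = cpl, seed = 8)
  fn <- inferFunctionalNetwork(r, seed = 2)
  edges <- functionalEdges(fn)
  expect_equal(nrow(edges), 12)
  p <- connectionProbability(fn)
  expect_equal(unname(p["excitatory"]),
               sum(edges$significant & edges$sign == "excitatory") / 12)
  e01 <- edges[edges$pre == 0 & edges$post == 1, ]
  expect_equal(e01$sign, "excitatory")
  m <- strengthMatrix(fn)
  expect_equal(dim(m), c(4, 4))
  expect_equal(m["0", "1"], e01$strength_exc)
})

test_that("cosine similarity and its Z-score behave at the fixed points", {
  a <- matrix(rnorm(16), 4)
  expect_equal(cosineSimilarity(a, a), 1)
  b <- c(1, 0, 0, 0)
  expect_equal(cosineSimilarity(b, c(0, 1, 0, 0)), 0)
  expect_error(cosineSimilarity(b * 0, b), "zero-norm")
  z <- similarityZscore(0.5, c(0.5, 0.4, 0.6, 0.5))
  expect_equal(z$z, 0)
  expect_error(similarityZscore(0.5, c(0.3, 0.3)), "degenerate")
})
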