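test_that("Poisson rasters have the requested rate and exponential ISIs", {
  r <- poissonRaster(10, 100000, rate = 5, seed = 1)
  counts <- tabulate(r@neuron + 1L, 10)
  expect_true(all(abs(counts - 500) < 4 * sqrt(500)))
  expect_identical(spikeEvents(r),
                   spikeEvents(poissonRaster(10, 100000, rate = 5, seed = 1)))
  # interspike intervals pass an exponential goodness-of-fit test
  big <- poissonRaster(1, 2e6, rate = 5, seed = 2)
  isi <- diff(spikeTrains(big)[[1]])
  ks <- suppressWarnings(ks.test(isi, "pexp", 5 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("oscillator-locked rasters span the coherence range", {
  r0 <- synchronizedRaster(6, 20000, period = 100, jitterSd = 0, seed = 1)
  expect_equal(meanPhaseCoherence(r0)$mpc, 1)
  # far beyond the period, jitter returns MPC to the independent baseline
  base <- mean(vapply(1:5, function(s)
    meanPhaseCoherence(poissonRaster(6, 20000, rate = 10, seed = s))$mpc,
    numeric(1)))
  far <- mean(vapply(1:5, function(s)
    meanPhaseCoherence(synchronizedRaster(6, 20000, period = 100,
                                          jitterSd = 300,
                                          seed = s))$mpc, numeric(1)))
  expect_lt(abs(far - base), 0.1)
  # MPC decreases monotonically along a jitter grid (mean over 5 seeds)
  grid <- c(0, 2, 10, 40)
  mj <- vapply(grid, function(j) mean(vapply(1:5, function(s)
    meanPhaseCoherence(synchronizedRaster(6, 20000, period = 100,
                                          jitterSd = j,
                                          seed = s))$mpc, numeric(1))),
    numeric(1))
  expect_true(all(diff(mj) < 0))
})

test_that("coupled rasters carry the requested monosynaptic structure", {
  cpl <- data.frame(pre = 0, post = 1, lag_ms = 2, prob = 1)
  r <- coupledRaster(2, 30000, rate = 5, coupling = cpl, seed = 3)
  tr <- spikeTrains(r)
  ccg <- crossCorrelogram(tr[[1]], tr[[2]])
  peak <- which.max(ccgCounts(ccg))
  expect_true(ccgLags(ccg)[peak] - 0.65 <= 2 && ccgLags(ccg)[peak] + 0.65 > 2)
  # transmission probability recovered from excess coincidences
  cpl2 <- data.frame(pre = 0, post = 1, lag_ms = 2, prob = 0.4)
  r2 <- coupledRaster(2, 120000, rate = 5, coupling = cpl2, seed = 4)
  tr2 <- spikeTrains(r2)
  nRef <- length(tr2[[1]])
  cc <- ccgCounts(crossCorrelogram(tr2[[1]], tr2[[2]]))
  baseline <- mean(cc[c(1:14, 21:30)])
  excess <- (max(cc[16:19]) - baseline) / nRef
  expect_lt(abs(excess - 0.4), 4 * sqrt(0.4 * 0.6 / nRef) + 0.03)
  # zero probability: independent pair, no consistent excess
  r0 <- coupledRaster(2, 30000, rate = 5,
                      coupling = data.frame(pre = 0, post = 1, lag_ms = 2,
                                            prob = 0),
                      seed = 5)
  tr0 <- spikeTrains(r0)
  e <- classifyEdge(crossCorrelogram(tr0[[1]], tr0[[2]]),
                    surrogateBand(tr0[[1]], tr0[[2]], seed = 6))
  expect_equal(e$sign, "none")
  expect_error(coupledRaster(2, 1000, coupling = data.frame(
    pre = 0, post = 1, lag_ms = -2, prob = 0.5)), "non-negative")
})
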