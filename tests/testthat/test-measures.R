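test_that("spike binning is binary 1-ms occupancy", {
  r <- SpikeRaster(neuron = c(0L, 0L, 1L), time = c(0.5, 0.7, 3.2),
                   nNeurons = 2, duration = 10)
  m <- binSpikes(r)
  expect_equal(dim(m), c(2, 10))
  expect_equal(unname(m[1, 1]), 1L)  # spike at 0.5 ms lands in bin 0
  expect_equal(sum(m[1, ]), 1L)      # two spikes in one bin collapse to 1
  expect_equal(unname(m[2, 4]), 1L)
  empty <- SpikeRaster(integer(), numeric(), nNeurons = 3, duration = 5)
  expect_true(all(binSpikes(empty) == 0L))
  expect_error(binSpikes(r, interval = c(2, 2)), "empty interval")
})

test_that("integration matches its defining identities", {
  one <- matrix(c(0L, 1L, 1L, 0L), 1)
  expect_equal(integrationMeasure(one), 0)           # N = 1
  u4 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))  # all four patterns once
  expect_equal(integrationMeasure(u4), 0)            # H(X)=2, margins 1+1
  dup <- rbind(c(0L, 1L, 1L, 0L), c(0L, 1L, 1L, 0L)) # identical rows
  h1 <- -0.5 * log2(0.5) * 2
  expect_equal(integrationMeasure(dup), h1)
})

test_that("complexity matches its defining identities and both routes agree", {
  u4 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  expect_equal(complexityMeasure(u4), 0)             # independent rows
  sync <- rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L))
  expect_equal(complexityMeasure(sync), 1)           # {00, 11} equiprobable
  expect_equal(complexityMeasure(matrix(0:1, 1)), 0) # N = 1 convention
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rbinom(8 * 500, 1, 0.3), nrow = 8)
    expect_equal(complexityMeasure(m), complexityMeasure(m, direct = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("entropy measures agree with exhaustive enumeration on small matrices", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rbinom(3 * 6, 1, runif(1, 0.2, 0.8)), nrow = 3)
    expect_equal(integrationMeasure(m), bruteIntegration(m), tolerance = 1e-12)
    expect_equal(complexityMeasure(m), bruteComplexity(m), tolerance = 1e-12)
  }
})

test_that("pairwise phase coherence follows the phasor definition", {
  # always the same relative phase: coherence 1
  ref <- seq(0, 1000, by = 10)
  expect_equal(pairPhaseCoherence(ref, ref[-length(ref)] + 3), 1)
  # worked example: phases 0.2 and 0.5
  sig <- pairPhaseCoherence(c(0, 10, 20), c(2, 15))
  expect_equal(sig, Mod((exp(2i * pi * 0.2) + exp(2i * pi * 0.5)) / 2))
  expect_equal(sig, 0.5878, tolerance = 1e-4)
  # random phases: coherence near 0 for many spikes
  set.seed(3)
  cmp <- sort(runif(4000, 0, 10000))
  expect_lt(pairPhaseCoherence(seq(0, 10000, by = 10), cmp), 0.05)
  # agreement with the brute-force oracle on irregular trains
  for (s in 1:5) {
    set.seed(s)
    r <- sort(runif(40, 0, 1000))
    cc <- sort(runif(60, 0, 1000))
    expect_equal(pairPhaseCoherence(r, cc), bruteMpc(r, cc),
                 tolerance = 1e-12)
  }
})

test_that("network MPC averages ordered pairs and ignores empty ones", {
  r <- synchronizedRaster(4, 5000, period = 100, jitterSd = 0, seed = 1)
  m <- meanPhaseCoherence(r)
  expect_equal(m$mpc, 1)
  expect_equal(m$n_pairs, 12)      # all ordered pairs contribute
  # invariance to global time translation
  ev <- spikeEvents(r)
  r2 <- SpikeRaster(ev$neuron_id, ev$time_ms + 37.5, 4, 5037.5)
  expect_equal(meanPhaseCoherence(r2)$mpc, m$mpc, tolerance = 1e-12)
})

test_that("rate statistics capture the distribution shape", {
  r <- SpikeRaster(neuron = 0:9, time = rep(500, 10), nNeurons = 10,
                   duration = 1000)
  rs <- rateStats(r)
  expect_true(all(rs$rates == 1))
  expect_equal(rs$skewness, 0)
  empty <- SpikeRaster(integer(), numeric(), nNeurons = 5, duration = 1000)
  expect_true(all(rateStats(empty)$rates == 0))
  rl <- poissonRaster(200, 60000, rateLogMean = 1, rateLogSd = 0.8, seed = 2)
  expect_gt(rateStats(rl)$skewness, 0.5)
})

test_that("measure suite is seeded, subsampled and averaged over intervals", {
  r <- poissonRaster(80, 20000, rate = 5, seed = 4)
  m1 <- measureSuite(r, nSub = 20, seed = 9)
  m2 <- measureSuite(r, nSub = 20, seed = 9)
  expect_identical(m1[c("mean_rate", "mpc", "integration", "complexity")],
                   m2[c("mean_rate", "mpc", "integration", "complexity")])
  expect_length(m1$ids, 20)
  expect_equal(nrow(m1$per_interval), 3)
  # degenerate subsample: all neurons used
  m3 <- measureSuite(r, nSub = 500, seed = 1)
  expect_length(m3$ids, 80)
  expect_error(measureSuite(r, nIntervals = 5, intervalLen = 6000),
               "too short")
  # independent Poisson neurons: complexity close to zero (plug-in bias only)
  expect_lt(m1$complexity, 0.15)
  expect_gt(m1$complexity, -1e-9)
})
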