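test_that("trend test reproduces hand-computed correlations", {
  expect_equal(correlationTest(c(1, 2, 3), c(0, 1, 2))$r, 1)
  ct <- correlationTest(c(1, 2, 4), c(0, 1, 2))
  expect_equal(ct$r, 0.9819805, tolerance = 1e-6)
  expect_error(correlationTest(c(2, 2, 2), c(0, 1, 2)), "zero variance")
  expect_error(correlationTest(c(1, 2), c(0, 1)), "3 points")
})

test_that("rate preservation recovers scaling between conditions", {
  set.seed(8)
  ref <- runif(50, 1, 10)
  p <- ratePreservation(ref, ref)
  expect_equal(p$slope, 1)
  expect_equal(p$r, 1)
  half <- ratePreservation(ref, 0.5 * ref)
  expect_equal(half$slope, 0.5)
  expect_equal(half$r, 1)
  expect_error(ratePreservation(ref, rep(1, 50)), "zero-variance")
})

test_that("series runs reuse one topology per seed and are reproducible", {
  levs <- data.frame(series = "A", lev = 1:2, label = c("L1", "L2"),
                     level = 1:2,
                     P_NMDA = c(1.64, 1.07), P_GABA = c(3.98, 9.41),
                     P_AMPA = 1.22, g_Ks = 0.97)
  res <- runSeries(levs, nNetworks = 2, duration = 5000, seed = 11,
                   dt = 0.1, nExc = 240, nInh = 60,
                   nSub = 40, nIntervals = 1, intervalLen = 3000)
  expect_equal(nrow(res$measures), 4)       # levels x networks
  expect_setequal(res$measures$label, c("L1", "L2"))
  expect_equal(dim(res$rates[[1]]), c(300, 2))
  # same base seed: identical result
  res2 <- runSeries(levs, nNetworks = 2, duration = 5000, seed = 11,
                    dt = 0.1, nExc = 240, nInh = 60,
                    nSub = 40, nIntervals = 1, intervalLen = 3000)
  expect_equal(res$measures, res2$measures)
  expect_error(runSeries(levs[0, ], nNetworks = 1), "empty level table")
})

test_that("cross-level similarity is 1 on the diagonal and symmetric", {
  # two levels sharing most coupling structure, via synthetic rasters
  cpl <- data.frame(pre = c(0, 2), post = c(1, 3), lag_ms = 2, prob = 0.6)
  mkFn <- function(seed)
    inferFunctionalNetwork(coupledRaster(5, 40000, rate = 5, coupling = cpl,
                                         seed = seed),
                           seed = 1, eligible = 0:4)
  fnA <- mkFn(1); fnB <- mkFn(2)
  res <- list(levels = data.frame(label = c("L1", "L2")),
              rates = list(1),
              networks = list(L1 = list(fnA), L2 = list(fnB)))
  cs <- crossLevelSimilarity(res)
  expect_equal(unname(diag(cs$cosine)), c(1, 1))
  expect_equal(cs$cosine[1, 2], cs$cosine[2, 1])
  expect_true(cs$cosine[1, 2] > 0 && cs$cosine[1, 2] <= 1)
})

test_that("paired level tests compare each level to the reference", {
  m <- expand.grid(network = 1:6, label = c("L1", "L2", "L3"))
  m$mean_rate_hz <- ifelse(m$label == "L1", 10,
                           ifelse(m$label == "L2", 8, 10)) +
    0.1 * m$network + ifelse(m$label == "L2", 0.05 * m$network, 0)
  res <- list(measures = m)
  out <- pairedLevelTests(res, reference = "L1", alpha = 0.0167)
  expect_equal(nrow(out), 2)
  expect_lt(out$diff[out$label == "L2"], 0)
  expect_true(out$significant[out$label == "L2"])
  expect_false(out$significant[out$label == "L3"])
})
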