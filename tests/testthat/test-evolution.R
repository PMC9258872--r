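quadCost <- function(target) function(p) sum((p - target)^2)

test_that("the fitting cost is the summed squared relative error", {
  t0 <- list(mean_rate = 10, mpc = 0.3, integration = 2, complexity = 1)
  expect_equal(measureCost(t0, t0)$L, 0)
  sim2 <- lapply(t0, function(x) 2 * x)
  expect_equal(measureCost(sim2, t0)$L, 4)
  sim1 <- t0
  sim1$mean_rate <- 8
  cc <- measureCost(sim1, t0)
  expect_equal(cc$L, 0.04)
  expect_equal(unname(cc$breakdown["mean_rate"]), 0.04)
  bad <- t0
  bad$mpc <- 0
  expect_error(measureCost(t0, bad), "non-zero")
})

test_that("population seeding produces 30 positive agents reproducibly", {
  ev <- quadCost(c(1.3, 6, 1.1, 0.8))
  p1 <- seedPopulation(ev, 0, seed = 5)
  p2 <- seedPopulation(ev, 0, seed = 5)
  expect_equal(nrow(p1@agents), 30)
  expect_identical(p1@agents, p2@agents)
  expect_true(all(p1@agents > 0))
  # level 6 anchors at the wake fit shifted by the reported synaptic effects
  wake <- c(P_NMDA = 1.6, P_GABA = 4, P_AMPA = 1.2, g_Ks = 1)
  p6 <- seedPopulation(ev, 6, neighbour = wake, seed = 2)
  expect_equal(nrow(p6@agents), 30)
  # anchored values are within (5% anchor jitter) x (10% refresh) of
  # 0.8 x NMDA and 1.4 x GABA for the 20 kept agents
  kept <- p6@agents[1:20, ]
  expect_true(all(kept[, "P_NMDA"] > 1.6 * 0.8 * 0.94 * 0.89 &
                  kept[, "P_NMDA"] < 1.6 * 0.8 * 1.06 * 1.11))
  expect_true(all(kept[, "P_GABA"] > 4 * 1.4 * 0.94 * 0.89 &
                  kept[, "P_GABA"] < 4 * 1.4 * 1.06 * 1.11))
  expect_error(seedPopulation(ev, 3), "level")
  expect_error(seedPopulation(ev, 2), "neighbouring")
  p2l <- seedPopulation(ev, 2, neighbour = p6, seed = 3)
  expect_equal(nrow(p2l@agents), 30)
})

test_that("the offspring formula degenerates as stated", {
  ev <- quadCost(c(1, 1, 1, 1))
  pop <- seedPopulation(ev, 0, seed = 1)
  # CR = 0: offspring clone their base agent (already in the population)
  g0 <- deGeneration(pop, ev, CR = 0, seed = 4)
  surv <- g0@agents[1:20, , drop = FALSE]
  off <- g0@agents[21:30, , drop = FALSE]
  for (k in seq_len(nrow(off)))
    expect_true(any(apply(surv, 1, function(a) all(a == off[k, ]))))
  # dwMax = 0 with CR = 1: offspring clone some survivor b
  g1 <- deGeneration(pop, ev, CR = 1, dwMax = 0, seed = 5)
  off1 <- g1@agents[21:30, , drop = FALSE]
  for (k in seq_len(nrow(off1)))
    expect_true(any(apply(g1@agents[1:20, ], 1,
                          function(a) all(a == off1[k, ]))))
  # frozen parameters never change in offspring
  g2 <- deGeneration(pop, ev, free = c("P_NMDA", "P_GABA"), seed = 6)
  offFrozen <- g2@agents[21:30, c("P_AMPA", "g_Ks"), drop = FALSE]
  survVals <- unique(as.vector(pop@agents[, c("P_AMPA", "g_Ks")]))
  expect_true(all(offFrozen %in% survVals))
})

test_that("evolution recovers a known optimum and never loses its best", {
  target <- c(P_NMDA = 1.3, P_GABA = 6.0, P_AMPA = 1.1, g_Ks = 0.8)
  ev <- quadCost(target)
  pop <- seedPopulation(ev, 0, seed = 3)
  for (g in 1:200) pop <- deGeneration(pop, ev, seed = g + 10)
  expect_lt(max(abs(bestAgent(pop)$params - target)), 1e-2)
  hist <- costHistory(pop)
  expect_true(all(diff(hist) <= 1e-12))       # elitism
  # convergence improves with generations across seeds
  errAt <- function(seed, gens) {
    p <- seedPopulation(ev, 0, seed = seed)
    for (g in seq_len(gens)) p <- deGeneration(p, ev, seed = seed * 317 + g)
    min(p@cost)
  }
  early <- vapply(1:6, errAt, numeric(1), gens = 10)
  late <- vapply(1:6, errAt, numeric(1), gens = 80)
  expect_lt(median(late), median(early))
})

test_that("fitLevel respects the series' free parameters and stops on stagnation", {
  target <- c(P_NMDA = 1.2, P_GABA = 7.0, P_AMPA = 1.3, g_Ks = 0.9)
  ev <- quadCost(target)
  wake <- c(P_NMDA = 1.5, P_GABA = 5, P_AMPA = 1.4, g_Ks = 1.1)
  fitA <- fitLevel(ev, level = 6, series = "A", neighbour = wake,
                   stagnation = 25, maxGenerations = 300, seed = 2)
  expect_true(fitA$converged)
  expect_true(all(diff(fitA$history) <= 1e-12))
  # A-series: P_AMPA and g_Ks frozen at their seeded (wake-derived) values;
  # only P_NMDA and P_GABA approach the target
  expect_lt(abs(fitA$best$params[["P_NMDA"]] - 1.2), 0.05)
  expect_lt(abs(fitA$best$params[["P_GABA"]] - 7.0), 0.2)
  seeded <- seedPopulation(ev, 6, neighbour = wake, seed = deriveSeed(2, 1))
  expect_true(fitA$best$params[["P_AMPA"]] %in% seeded@agents[, "P_AMPA"])
  expect_true(fitA$best$params[["g_Ks"]] %in% seeded@agents[, "g_Ks"])
  # B-series also frees g_Ks
  fitB <- fitLevel(ev, level = 6, series = "B", neighbour = wake,
                   stagnation = 25, maxGenerations = 400, seed = 2)
  expect_lt(abs(fitB$best$params[["g_Ks"]] - 0.9), 0.05)
})

test_that("a simulator-backed fit recovers parameter directions on a mock", {
  # analytic stand-in for the simulator: measures are monotone functions of
  # the parameters, so the fitted optimum is identifiable
  mockMeasures <- function(p)
    list(mean_rate = 10 * p[["P_NMDA"]] / p[["P_GABA"]] - p[["g_Ks"]],
         mpc = 0.2 + 0.05 * p[["P_GABA"]] / p[["P_NMDA"]],
         integration = 2 * p[["P_NMDA"]] * p[["P_AMPA"]],
         complexity = 1 + 0.3 * p[["P_NMDA"]] - 0.1 * p[["g_Ks"]])
  truth <- c(P_NMDA = 1.4, P_GABA = 5.5, P_AMPA = 1.2, g_Ks = 0.9)
  target <- mockMeasures(truth)
  ev <- function(p) measureCost(mockMeasures(p), target)
  fit <- fitLevel(ev, level = 0, stagnation = 60, maxGenerations = 500,
                  seed = 7)
  expect_lt(fit$best$cost, 1e-4)
})
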