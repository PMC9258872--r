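test_that("lognormal weight sampling matches its stated parameters", {
  expect_length(sampleLognormalWeights(count = 0), 0)
  expect_error(sampleLognormalWeights(theta = 0, count = 5), "positive")
  w1 <- sampleLognormalWeights(count = 100, seed = 7)
  expect_identical(w1, sampleLognormalWeights(count = 100, seed = 7))
  expect_true(all(w1 > 0))
  w <- sampleLognormalWeights(count = 5000, seed = 1)
  expect_lt(abs(mean(log(w)) + 20), 3 * 9.4 / sqrt(5000))
  expect_lt(abs(log(median(w)) + 20), 0.5)
})

test_that("network construction is a seeded directed Erdos-Renyi graph", {
  net <- buildNetwork(800, 200, pConn = 0.1, seed = 3)
  net2 <- buildNetwork(800, 200, pConn = 0.1, seed = 3)
  expect_identical(edgeTable(net), edgeTable(net2))
  m <- 1000 * 999 * 0.1
  expect_lt(abs(nEdges(net) - m), 4 * sqrt(m * 0.9))
  expect_true(all(net@pre != net@post))
  expect_true(all(net@weight > 0))
  # 4:1 excitatory-inhibitory ratio is the default population
  expect_equal(formals(buildNetwork)$nExc / formals(buildNetwork)$nInh, 4)
  et <- edgeTable(net)
  expect_setequal(unique(et$class), c("exc", "inh"))
})

test_that("synaptic current follows the double-exponential kernel", {
  expect_equal(synapticCurrent("AMPA", 1, 0, -60), 0)  # cancels at onset
  # NMDA magnesium-block gate is 0.5 at -10 mV
  iN <- synapticCurrent("NMDA", 2, 1, -10, P = 1, v_half = 1)
  kernel <- exp(-1 / 200) - exp(-1 / 0.2)
  expect_equal(iN, 0.5 * 2 * kernel * (-10 - 0))
  # AMPA kernel peak at (tau_s tau_f / (tau_s - tau_f)) ln(tau_s / tau_f)
  tgrid <- seq(0.01, 3, by = 1e-4)
  kern <- exp(-tgrid / 3) - exp(-tgrid / 0.2)
  tstar <- (3 * 0.2 / 2.8) * log(3 / 0.2)
  expect_lt(abs(tgrid[which.max(kern)] - tstar), 1e-3)
  expect_equal(tstar, 0.580, tolerance = 1e-3)
  expect_error(synapticCurrent("GLY", 1, 1, -60), "unknown receptor")
  expect_error(synapticCurrent("AMPA", 1, -1, -60), "non-negative")
  expect_error(synapticCurrent("AMPA", 1, 1, -60, v_half = 0.2), "v_half")
})

test_that("event-driven accumulators equal direct kernel summation", {
  # passive cell: dV/dt = -I_AMPA(t), with I_AMPA the closed-form kernel sum
  p <- neuronParams(g_Na = 0, g_Kd = 0, g_Ks = 0, g_L = 0, I_DC = 0)
  syn <- synapseParams(P_AMPA = 1.5, P_NMDA = 0, P_GABA = 0)
  ev <- c(5, 6.2, 14)
  w <- c(0.05, 0.02, 0.08)
  tr <- simulateNeuron(p, duration = 30, dt = 0.05, eventTimes = ev,
                       eventWeights = w, synapse = syn,
                       init = c(-70, 0.5, 0.5, 0.5), recordTrace = TRUE)$trace
  # R oracle: RK4 on the same ODE with explicit kernel summation
  Isyn <- function(t, V) {
    tot <- 0
    for (k in seq_along(ev)) {
      if (t >= ev[k]) {
        tot <- tot + synapticCurrent("AMPA", w[k], t - ev[k], V,
                                     P = 1.5, synapse = syn)
      }
    }
    tot
  }
  V <- -70
  vs <- V
  for (i in 1:600) {
    t <- (i - 1) * 0.05
    f <- function(tt, v) -Isyn(tt, v)
    k1 <- f(t, V)
    k2 <- f(t + 0.025, V + 0.025 * k1)
    k3 <- f(t + 0.025, V + 0.025 * k2)
    k4 <- f(t + 0.05, V + 0.05 * k3)
    V <- V + 0.05 / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    vs <- c(vs, V)
  }
  expect_lt(max(abs(tr - vs)) / max(abs(vs - (-70))), 1e-9)
})

test_that("suprathreshold-synapse threshold is reproducible and consistent", {
  fs <- fractionSuprathreshold(tol = 1e-3)
  fs2 <- fractionSuprathreshold(tol = 1e-3)
  expect_identical(fs$threshold, fs2$threshold)
  # analytic tail probability equals the Gaussian tail of log-weights
  expect_equal(fs$analytic_fraction,
               1 - pnorm((log(fs$threshold) + 20) / 9.4))
  # tighter tolerance agrees to within the coarser one
  fs3 <- fractionSuprathreshold(tol = 1e-4)
  expect_lt(abs(log(fs3$threshold / fs$threshold)), 2e-3)
  w <- sampleLognormalWeights(count = 20000, seed = 5)
  fsw <- fractionSuprathreshold(tol = 1e-3, weights = w)
  expect_equal(fsw$empirical_fraction, mean(w > fsw$threshold))
  expect_lt(abs(fsw$empirical_fraction - fsw$analytic_fraction), 0.01)
})
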