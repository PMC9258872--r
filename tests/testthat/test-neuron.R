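test_that("gating kinetics hit their sigmoid midpoints and time constants", {
  g <- gateKinetics(-30)
  expect_equal(g$m_inf, 0.5)
  expect_equal(g$n_inf, 0.5)
  expect_equal(gateKinetics(-53)$h_inf, 0.5)
  expect_equal(gateKinetics(-39)$z_inf, 0.5)
  expect_equal(gateKinetics(-40.5)$tau_h, 0.37 + 2.78 / 2)
  expect_equal(gateKinetics(10)$tau_z, 75)
  grid <- gateKinetics(seq(-120, 60, by = 1))
  for (k in c("m_inf", "h_inf", "n_inf", "z_inf"))
    expect_true(all(grid[[k]] > 0 & grid[[k]] < 1))
  for (k in c("tau_h", "tau_n", "tau_z"))
    expect_true(all(grid[[k]] > 0))
  expect_error(gateKinetics(NaN), "finite")
})

test_that("membrane RHS has the stated null, leak and resting balances", {
  p0 <- neuronParams(g_Na = 0, g_Kd = 0, g_Ks = 0, g_L = 0, I_DC = 0)
  d <- membraneRhs(c(V = -55, h = 0.5, n = 0.5, z = 0.5), p0)
  expect_equal(unname(d["V"]), 0)
  pl <- neuronParams(g_Na = 0, g_Kd = 0, g_Ks = 0, g_L = 0.3, I_DC = 0)
  d <- membraneRhs(c(V = pl$E_L, h = 0.5, n = 0.5, z = 0.5), pl)
  expect_equal(unname(d["V"]), 0)

  # default biophysics with the M-current on: a stable subthreshold rest
  p <- neuronParams(g_Ks = 0.98)
  rest <- restingState(p)
  expect_lt(rest$V, -40)
  d <- membraneRhs(c(V = rest$V, h = rest$h, n = rest$n, z = rest$z), p)
  expect_lt(abs(d[["V"]]), 1e-6)
  # stability: the steady-state current balance decreases through the root
  f <- function(V) {
    g <- gateKinetics(V)
    membraneRhs(c(V = V, h = g$h_inf, n = g$n_inf, z = g$z_inf), p)[["V"]]
  }
  expect_gt(f(rest$V - 1), 0)
  expect_lt(f(rest$V + 1), 0)
})

test_that("rk4Step is classical fourth order and respects fixed points", {
  y1 <- rk4Step(c(y = 1), 0.1, function(t, s) -s)
  expect_lt(abs(y1[["y"]] - exp(-0.1)), 1e-7)

  # global error at fixed horizon drops ~16x when dt halves
  run <- function(dt) {
    y <- c(y = 1)
    for (i in seq_len(round(1 / dt))) y <- rk4Step(y, dt, function(t, s) -s)
    abs(y[["y"]] - exp(-1))
  }
  ratio <- run(0.1) / run(0.05)
  expect_gt(ratio, 12)
  expect_lt(ratio, 20)

  # a fixed point maps to itself
  p <- neuronParams(g_Ks = 0.98)
  rest <- restingState(p)
  st <- c(V = rest$V, h = rest$h, n = rest$n, z = rest$z)
  st2 <- rk4Step(st, 0.05, function(t, s) membraneRhs(s, p),
                 clipGates = c("h", "n", "z"))
  expect_lt(sqrt(sum((st2 - st)^2)), 1e-10)

  expect_error(rk4Step(c(h = 0.5), 1e3,
                       function(t, s) c(h = 1e9),
                       clipGates = "h"), "instability")
})

test_that("compiled integrator matches the R reference solution", {
  p <- neuronParams(g_Ks = 0.98)
  st <- c(V = -55, h = 0.6, n = 0.3, z = 0.1)
  tr <- simulateNeuron(p, duration = 50, dt = 0.05, init = st,
                       recordTrace = TRUE)$trace
  s <- st
  vs <- s[["V"]]
  for (i in 1:1000) {
    s <- rk4Step(s, 0.05, function(t, x) membraneRhs(x, p),
                 clipGates = c("h", "n", "z"))
    vs <- c(vs, s[["V"]])
  }
  expect_lt(max(abs(tr - vs)), 1e-4)
})

test_that("solution is converged in dt for a periodically firing cell", {
  p <- neuronParams(g_Ks = 0.98)
  rest <- restingState(p)
  init <- c(rest$V, rest$h, rest$n, rest$z)
  s1 <- simulateNeuron(p, duration = 1000, dt = 0.05, I_extra = 3, init = init)
  s2 <- simulateNeuron(p, duration = 1000, dt = 0.01, I_extra = 3, init = init)
  expect_equal(length(s1$spikes), length(s2$spikes))
  expect_lt(max(abs(s1$spikes - s2$spikes)), 0.5)
})

test_that("gates stay in [0, 1] over a long noisy firing run", {
  p <- neuronParams(g_Ks = 0.98)
  # 1e6 steps at dt = 0.05 with noise pulses and steady firing: the engine
  # signals an error if any gate leaves [0, 1] by more than round-off
  s <- simulateNeuron(p, duration = 50000, dt = 0.05, I_extra = 2.5,
                      pulseTimes = seq(500, 49500, by = 500),
                      pulseAmplitude = 16)
  expect_true(all(is.finite(s$final_state)))
  expect_true(all(s$final_state[2:4] >= 0 & s$final_state[2:4] <= 1))
  expect_gt(length(s$spikes), 100)
})

test_that("f-I curve: subthreshold silence, growth with I, suppression by g_Ks", {
  p <- neuronParams(g_Ks = 0.98)
  fi <- fiCurve(p, c(0, 1.5, 2.5, 4), duration = 1500, discard = 500)
  expect_equal(fi$rate_hz[1], 0)              # below rheobase
  expect_true(all(diff(fi$rate_hz) >= 0))     # non-decreasing over this range
  # the M-current is hyperpolarizing: rate never increases with g_Ks
  for (I in c(2, 4)) {
    rates <- vapply(c(0, 0.5, 1, 1.5), function(g)
      fiCurve(neuronParams(g_Ks = g), I,
              duration = 1500, discard = 500)$rate_hz, numeric(1))
    expect_true(all(diff(rates) <= 0))
  }
})

test_that("M-current switches excitability from Type 1 to Type 2", {
  rb0 <- rheobase(neuronParams(g_Ks = 0), upper = 2, tol = 1e-4,
                  duration = 4000)
  rb15 <- rheobase(neuronParams(g_Ks = 1.5), upper = 6, tol = 1e-4,
                   duration = 4000)
  # continuous onset: arbitrarily low firing at rheobase
  expect_lt(rb0$onset_hz, 1)
  # discontinuous onset: firing starts at a non-zero frequency
  expect_gt(rb15$onset_hz, 2)
  expect_gt(rb15$I, rb0$I)
})
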