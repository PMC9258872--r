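#' Biophysical parameters of a model cortical neuron
#'
#' Conductance densities, reversal potentials and input settings of the
#' single-compartment Hodgkin-Huxley model used throughout the package: fast
#' sodium, delayed-rectifier potassium, slow M-type potassium (the
#' acetylcholine-modulated current, conductance \code{g_Ks}) and leak. The
#' membrane equation also receives a constant bias current \code{I_DC} and
#' brief Poisson noise pulses.
#'
#' \code{g_Ks} indexes (inverse) cholinergic tone: 0 mS/cm^2 corresponds to
#' high acetylcholine, 1.5 mS/cm^2 to a low-acetylcholine state.
#'
#' @param g_Na,g_Kd,g_Ks,g_L maximal conductance densities (mS/cm^2).
#' @param E_Na,E_K,E_L reversal potentials (mV).
#' @param C_m membrane capacitance (uF/cm^2).
#' @param I_DC constant bias current (uA/cm^2).
#' @param noise_rate mean Poisson pulse frequency per neuron (Hz).
#' @param noise_duration pulse duration (ms).
#' @param noise_amplitude pulse amplitude (uA/cm^2).
#' @return named list of class \code{"NeuronParams"}.
#' @examples
#' p <- neuronParams()
#' p$I_DC
#' @export
neuronParams <- function(g_Na = 24, g_Kd = 3, g_Ks = 0, g_L = 0.05,
                         E_Na = 55, E_K = -90, E_L = -60,
                         C_m = 1, I_DC = -0.77,
                         noise_rate = 0.1, noise_duration = 2,
                         noise_amplitude = 16) {
  p <- list(g_Na = g_Na, g_Kd = g_Kd, g_Ks = g_Ks, g_L = g_L,
            E_Na = E_Na, E_K = E_K, E_L = E_L, C_m = C_m, I_DC = I_DC,
            noise_rate = noise_rate, noise_duration = noise_duration,
            noise_amplitude = noise_amplitude)
  if (any(unlist(p[c("g_Na", "g_Kd", "g_Ks", "g_L")]) < 0))
    stop("conductances must be non-negative")
  if (C_m <= 0) stop("C_m must be positive")
  class(p) <- c("NeuronParams", "list")
  p
}

#' Receptor kinetics and scaling of the synapse model
#'
#' Double-exponential synaptic kernels share a fast time constant of 0.2 ms;
#' slow decay constants are 3 ms (AMPA), 200 ms (NMDA) and 5.5 ms (GABA-A).
#' Excitatory currents reverse at 0 mV, inhibitory at -75 mV. The
#' \code{P_AMPA}, \code{P_NMDA}, \code{P_GABA} factors scale receptor
#' efficacy per anesthetic condition.
#'
#' @param tau_fast shared fast (rise) time constant, ms.
#' @param tau_ampa_slow,tau_nmda_slow,tau_gaba_slow slow (decay) time
#'   constants, ms.
#' @param E_exc,E_inh excitatory / inhibitory reversal potentials, mV.
#' @param P_AMPA,P_NMDA,P_GABA receptor efficacy scaling factors.
#' @return named list of class \code{"SynapseParams"}.
#' @export
synapseParams <- function(tau_fast = 0.2, tau_ampa_slow = 3.0,
                          tau_nmda_slow = 200.0, tau_gaba_slow = 5.5,
                          E_exc = 0, E_inh = -75,
                          P_AMPA = 1, P_NMDA = 1, P_GABA = 1) {
  p <- list(tau_fast = tau_fast, tau_ampa_slow = tau_ampa_slow,
            tau_nmda_slow = tau_nmda_slow, tau_gaba_slow = tau_gaba_slow,
            E_exc = E_exc, E_inh = E_inh,
            P_AMPA = P_AMPA, P_NMDA = P_NMDA, P_GABA = P_GABA)
  if (any(unlist(p[1:4]) <= 0)) stop("time constants must be positive")
  class(p) <- c("SynapseParams", "list")
  p
}

#' Gating-variable kinetics at a given voltage
#'
#' Steady-state activations of the transient sodium gate (instantaneous,
#' \code{m_inf}), sodium inactivation (\code{h_inf}), delayed-rectifier
#' activation (\code{n_inf}) and M-current activation (\code{z_inf}), plus
#' the voltage-dependent time constants \code{tau_h}, \code{tau_n} and the
#' constant \code{tau_z} = 75 ms.
#'
#' @param V membrane voltage (mV), finite scalar or vector.
#' @return list with components m_inf, h_inf, n_inf, z_inf (dimensionless)
#'   and tau_h, tau_n, tau_z (ms).
#' @examples
#' gateKinetics(-30)$m_inf  # sigmoid midpoint: 0.5
#' @export
gateKinetics <- function(V) {
  if (any(!is.finite(V))) stop("V must be finite")
  list(m_inf = 1 / (1 + exp(-(V + 30) / 9.5)),
       h_inf = 1 / (1 + exp((V + 53) / 7.0)),
       n_inf = 1 / (1 + exp(-(V + 30) / 10)),
       z_inf = 1 / (1 + exp(-(V + 39) / 5.0)),
       tau_h = 0.37 + 2.78 / (1 + exp((V + 40.5) / 5.0)),
       tau_n = 0.37 + 1.85 / (1 + exp((V + 27) / 15)),
       tau_z = rep(75, length(V)))
}

#' Membrane equation right-hand side
#'
#' Time derivative of the neuron state (V, h, n, z) given the synaptic and
#' noise currents. The sodium activation gate is instantaneous
#' (\code{m = m_inf(V)}). \code{I_syn} enters with a negative sign, so a
#' negative excitatory synaptic current (driving force below the excitatory
#' reversal) depolarizes the cell.
#'
#' @param state named numeric vector with elements V, h, n, z.
#' @param params a \code{\link{neuronParams}} list.
#' @param I_syn synaptic current (uA/cm^2), subtracted from the membrane
#'   balance.
#' @param I_noise noise current (uA/cm^2), added.
#' @return named numeric vector (dV, dh, dn, dz) per ms.
#' @export
membraneRhs <- function(state, params, I_syn = 0, I_noise = 0) {
  V <- state[["V"]]; h <- state[["h"]]; n <- state[["n"]]; z <- state[["z"]]
  if (any(c(h, n, z) < -1e-12) || any(c(h, n, z) > 1 + 1e-12))
    stop("gating variables outside [0, 1]")
  g <- gateKinetics(V)
  dV <- (-params$g_Na * g$m_inf^3 * h * (V - params$E_Na) -
           params$g_Kd * n^4 * (V - params$E_K) -
           params$g_Ks * z * (V - params$E_K) -
           params$g_L * (V - params$E_L) +
           I_noise - I_syn + params$I_DC) / params$C_m
  c(V = dV,
    h = (g$h_inf - h) / g$tau_h,
    n = (g$n_inf - n) / g$tau_n,
    z = (g$z_inf - z) / g$tau_z)
}

#' One classical Runge-Kutta (RK4) step
#'
#' Generic fourth-order step for an autonomous-or-not ODE system. When
#' applied to the neuron state, gating variables that exit [0, 1] by less
#' than 1e-9 are clipped back; larger excursions raise an error (they signal
#' integrator instability rather than round-off).
#'
#' @param state numeric state vector.
#' @param dt step size (must be positive).
#' @param deriv function \code{(t, state) -> d(state)/dt}.
#' @param t current time (passed to \code{deriv}).
#' @param clipGates names of state elements to treat as gating variables.
#' @return the state advanced by \code{dt}.
#' @examples
#' # linear test equation dy/dt = -y
#' rk4Step(c(y = 1), 0.1, function(t, s) -s)
#' @export
rk4Step <- function(state, dt, deriv, t = 0, clipGates = character()) {
  if (dt <= 0) stop("dt must be positive")
  k1 <- deriv(t, state)
  k2 <- deriv(t + dt / 2, state + dt / 2 * k1)
  k3 <- deriv(t + dt / 2, state + dt / 2 * k2)
  k4 <- deriv(t + dt, state + dt * k3)
  out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out)))
    stop("integration failure: non-finite state after RK4 step at t = ", t)
  for (g in intersect(clipGates, names(out))) {
    x <- out[[g]]
    if (x < 0) {
      if (x < -1e-9) stop("integration instability: gate ", g, " = ", x)
      out[[g]] <- 0
    } else if (x > 1) {
      if (x > 1 + 1e-9) stop("integration instability: gate ", g, " = ", x)
      out[[g]] <- 1
    }
  }
  out
}

#' Stable resting state of an isolated neuron
#'
#' Finds the hyperpolarized stable equilibrium of the membrane equation with
#' all gates at steady state and no synaptic or noise input, by locating sign
#' changes of the steady-state current balance on a voltage grid and keeping
#' the most hyperpolarized root with negative slope (a stable fixed point).
#'
#' @param params a \code{\link{neuronParams}} list.
#' @param I_extra additional constant current (uA/cm^2).
#' @return list with V (mV) and the gate values h, n, z at rest.
#' @export
restingState <- function(params, I_extra = 0) {
  f <- function(V) {
    g <- gateKinetics(V)
    -params$g_Na * g$m_inf^3 * g$h_inf * (V - params$E_Na) -
      params$g_Kd * g$n_inf^4 * (V - params$E_K) -
      params$g_Ks * g$z_inf * (V - params$E_K) -
      params$g_L * (V - params$E_L) + params$I_DC + I_extra
  }
  grid <- seq(-140, -20, by = 0.5)
  fv <- vapply(grid, f, numeric(1))
  idx <- which(fv[-length(fv)] > 0 & fv[-1] <= 0) # downward crossing: stable
  if (!length(idx)) {
    # fully below zero on the grid: rest is below -140 or does not exist
    idx0 <- which(diff(sign(fv)) != 0)
    if (!length(idx0)) stop("no resting state found in [-140, -20] mV")
    idx <- idx0[1]
  }
  r <- stats::uniroot(f, c(grid[idx[1]], grid[idx[1] + 1]), tol = 1e-10)
  g <- gateKinetics(r$root)
  list(V = r$root, h = g$h_inf, n = g$n_inf, z = g$z_inf)
}

#' Simulate an isolated neuron
#'
#' Integrates a single model neuron with the compiled RK4 engine, with an
#' optional constant current, deterministic current pulses and excitatory
#' synaptic events (AMPA+NMDA sharing one conductance, event scale 1).
#'
#' @param params a \code{\link{neuronParams}} list; \code{params$g_Ks} is the
#'   M-current conductance used.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param I_extra constant additional current (uA/cm^2).
#' @param pulseTimes onset times of rectangular current pulses (ms).
#' @param pulseDuration,pulseAmplitude pulse shape (ms, uA/cm^2).
#' @param eventTimes,eventWeights excitatory synaptic event onsets (ms) and
#'   conductances (mS/cm^2).
#' @param synapse a \code{\link{synapseParams}} list (its P factors scale the
#'   delivered events).
#' @param init numeric (V, h, n, z) initial state; default: rest of the
#'   passive equation at -70 mV.
#' @param recordTrace if TRUE, return the voltage trace sampled every step.
#' @return list with \code{spikes} (times of upward 0 mV crossings, 2 ms
#'   lockout), \code{final_state}, and optionally \code{trace}.
#' @export
simulateNeuron <- function(params = neuronParams(), duration = 1000,
                           dt = 0.05, I_extra = 0,
                           pulseTimes = numeric(), pulseDuration = 2,
                           pulseAmplitude = 4,
                           eventTimes = numeric(), eventWeights = numeric(),
                           synapse = synapseParams(),
                           init = NULL, recordTrace = FALSE) {
  if (length(eventTimes) != length(eventWeights))
    stop("eventTimes and eventWeights must have equal length")
  cpp_simulate_single(unclass(params), params$g_Ks, unclass(synapse),
                      duration, dt, I_extra,
                      as.numeric(pulseTimes), pulseDuration, pulseAmplitude,
                      as.numeric(eventTimes), as.numeric(eventWeights),
                      if (is.null(init)) numeric() else as.numeric(init),
                      recordTrace)
}

#' Firing frequency versus injected current (f-I curve)
#'
#' Simulates the neuron at each current value without noise, discards the
#' initial transient and reports the steady firing frequency. With the
#' M-current off (g_Ks = 0) the onset of firing at rheobase is continuous
#' (Type 1 excitability); with g_Ks = 1.5 mS/cm^2 firing starts at a non-zero
#' frequency (Type 2).
#'
#' @param params a \code{\link{neuronParams}} list.
#' @param I_values injected currents (uA/cm^2).
#' @param duration per-current simulation length (ms; >= 2000 recommended).
#' @param discard initial transient excluded from the rate (ms).
#' @param dt integration step (ms).
#' @return data.frame with columns I and rate_hz.
#' @export
fiCurve <- function(params, I_values, duration = 2000, discard = 500,
                    dt = 0.05) {
  rest <- restingState(params)
  init <- c(rest$V, rest$h, rest$n, rest$z)
  rate <- vapply(I_values, function(I) {
    sim <- simulateNeuron(params, duration = duration, dt = dt,
                          I_extra = I, init = init)
    sum(sim$spikes >= discard) / ((duration - discard) / 1000)
  }, numeric(1))
  data.frame(I = I_values, rate_hz = rate)
}

#' Rheobase current by bisection
#'
#' Minimal constant current that elicits sustained firing, located by
#' bisection on the f-I curve.
#'
#' @param params a \code{\link{neuronParams}} list.
#' @param lower,upper bracketing currents (uA/cm^2); the cell must be silent
#'   at \code{lower} and firing at \code{upper}.
#' @param tol bisection tolerance on the current.
#' @param duration,dt simulation settings per probe.
#' @return list with \code{I} (the rheobase estimate) and \code{onset_hz}
#'   (firing frequency just above rheobase).
#' @export
rheobase <- function(params, lower = 0, upper = 10, tol = 1e-3,
                     duration = 3000, dt = 0.05) {
  fires <- function(I)
    fiCurve(params, I, duration = duration, discard = 1000, dt = dt)$rate_hz > 0
  if (fires(lower)) stop("cell already fires at the lower bracket")
  if (!fires(upper)) stop("cell silent at the upper bracket")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  onset <- fiCurve(params, hi + tol, duration = duration, discard = 1000,
                   dt = dt)$rate_hz
  list(I = hi, onset_hz = onset)
}
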