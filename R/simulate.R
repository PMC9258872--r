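#' Simulate the E-I network under one anesthetic condition
#'
#' Integrates the full network with the compiled RK4 engine. Each excitatory
#' edge delivers AMPA and NMDA currents sharing its lognormal conductance;
#' inhibitory edges deliver GABA-A. Every presynaptic spike draws an event
#' scale v_half ~ U[0.5, 1] independently per edge. The level's receptor
#' factors (P_AMPA, P_NMDA, P_GABA) scale the currents and its g_Ks sets the
#' M-current conductance of excitatory cells (inhibitory cells use
#' \code{gKsInh}, 0 by default). Initial conditions are drawn uniformly
#' (V in [-72, -32] mV, h and n in [0.2, 0.6], z in [0.2, 0.3]) from the
#' simulation seed, and the initial transient is discarded from the returned
#' raster.
#'
#' The per-edge conductance is capped at \code{wCap} when delivered: the
#' untruncated lognormal weight tail (theta = 9.4 log-units) spans dozens of
#' orders of magnitude and is neither physical nor integrable, while a
#' suprathreshold synapse fires its target once per presynaptic spike
#' whatever its conductance, so a cap just above the single-spike firing
#' threshold (about 0.14 mS/cm^2 at the default biophysics) preserves the
#' functional effect of every edge while bounding the aggregate drive (see
#' the package vignette). Steps in which a neuron's synaptic conductance
#' load would make the explicit step stiff are subdivided automatically.
#'
#' @param topology a \code{\linkS4class{NetworkTopology}}.
#' @param level named list or one-row data.frame with P_NMDA, P_GABA,
#'   P_AMPA, g_Ks (and optionally a label), e.g. one row of
#'   \code{\link{levelParameters}()}.
#' @param duration total simulated time (ms), including the transient.
#' @param dt integration step (ms).
#' @param seed simulation seed (noise, initial conditions, event scales).
#' @param transient initial interval discarded from the raster (ms).
#' @param params a \code{\link{neuronParams}} list (biophysics + noise).
#' @param synapse a \code{\link{synapseParams}} list; its P factors are
#'   overridden by \code{level}.
#' @param gKsInh M-current conductance of inhibitory cells (mS/cm^2).
#' @param weightScale conversion factor from sampled lognormal weights to
#'   conductance (mS/cm^2 per unit); weights are used as sampled by default.
#' @param wCap delivered-conductance cap (mS/cm^2), applied after scaling.
#' @param noise logical; disable to run without noise pulses.
#' @param quiescentInit start all cells at -70 mV with gates at steady state
#'   (instead of random initial conditions).
#' @param init optional n x 4 matrix (V, h, n, z) of initial states.
#' @return a \code{\linkS4class{SpikeRaster}}; times are relative to the end
#'   of the transient and \code{rasterDuration} is
#'   \code{duration - transient}.
#' @examples
#' net <- buildNetwork(80, 20, seed = 1)
#' lev <- list(label = "A1", P_NMDA = 1.64, P_GABA = 3.98,
#'             P_AMPA = 1.22, g_Ks = 0.97)
#' r <- simulateNetwork(net, lev, duration = 3000, seed = 1)
#' @export
simulateNetwork <- function(topology, level, duration = 20000, dt = 0.05,
                            seed = 1L, transient = 1000,
                            params = neuronParams(),
                            synapse = synapseParams(),
                            gKsInh = 0, weightScale = 1, wCap = 0.22,
                            noise = TRUE, quiescentInit = FALSE,
                            init = NULL) {
  stopifnot(is(topology, "NetworkTopology"))
  level <- as.list(level)
  for (k in c("P_NMDA", "P_GABA", "P_AMPA", "g_Ks"))
    if (is.null(level[[k]])) stop("level is missing ", k)
  if (duration < transient)
    stop("duration (", duration, " ms) shorter than the transient (",
         transient, " ms)")
  syn <- unclass(synapse)
  syn$P_AMPA <- level$P_AMPA
  syn$P_NMDA <- level$P_NMDA
  syn$P_GABA <- level$P_GABA
  noisePar <- list(rate_hz = if (noise) params$noise_rate else 0,
                   duration_ms = params$noise_duration,
                   amplitude = params$noise_amplitude)
  res <- cpp_simulate_network(topology@nExc, topology@nInh,
                              topology@pre, topology@post,
                              topology@weight * weightScale,
                              unclass(params), syn, noisePar,
                              level$g_Ks, gKsInh,
                              duration, dt, transient, wCap,
                              as.integer(seed), quiescentInit, init)
  SpikeRaster(neuron = res$neuron,
              time = pmin(res$time, duration - transient),
              nNeurons = nNeurons(topology),
              duration = duration - transient,
              metadata = list(label = level$label, seed = as.integer(seed),
                              dt = dt, transient_ms = transient,
                              level = level[c("P_NMDA", "P_GABA",
                                              "P_AMPA", "g_Ks")],
                              topology_seed = topology@seed))
}
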