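#' Sample lognormal synaptic conductances
#'
#' Draws conductances whose natural logarithm is Normal(mu, theta), the
#' heavy-tailed weight distribution of cortical synapses used for all edges
#' of the model network (defaults mu = -20.0, theta = 9.4).
#'
#' @param mu mean of log-conductance.
#' @param theta standard deviation of log-conductance (> 0).
#' @param count number of samples.
#' @param seed optional RNG seed (the caller's RNG state is preserved).
#' @return numeric vector of positive conductances (mS/cm^2).
#' @examples
#' w <- sampleLognormalWeights(count = 1000, seed = 1)
#' mean(log(w))  # close to -20
#' @export
sampleLognormalWeights <- function(mu = -20.0, theta = 9.4, count, seed = NULL) {
  if (theta <= 0) stop("theta must be positive")
  if (count < 0) stop("count must be non-negative")
  if (count == 0) return(numeric(0))
  withSeed(seed, exp(rnorm(count, mean = mu, sd = theta)))
}

#' Build a random E-I network topology
#'
#' Directed Erdos-Renyi graph over \code{nExc} excitatory and \code{nInh}
#' inhibitory neurons (default 800/200, the 4:1 cortical ratio): every
#' ordered pair excluding self-edges is connected independently with
#' probability \code{pConn}, and each edge receives one lognormal
#' conductance.
#'
#' @param nExc,nInh excitatory / inhibitory neuron counts.
#' @param pConn connection probability per ordered pair.
#' @param mu,theta lognormal weight parameters
#'   (see \code{\link{sampleLognormalWeights}}).
#' @param seed RNG seed; the same seed reproduces the identical topology and
#'   weights.
#' @return a \code{\linkS4class{NetworkTopology}}.
#' @examples
#' net <- buildNetwork(80, 20, seed = 1)
#' nEdges(net)
#' @export
buildNetwork <- function(nExc = 800, nInh = 200, pConn = 0.1,
                         mu = -20.0, theta = 9.4, seed = 1L) {
  if (nExc < 1 || nInh < 0) stop("invalid neuron counts")
  if (pConn <= 0 || pConn > 1) stop("pConn must be in (0, 1]")
  n <- nExc + nInh
  withSeed(seed, {
    pre <- integer(0); post <- integer(0)
    for (i in seq_len(n) - 1L) {
      hit <- which(runif(n) < pConn) - 1L
      hit <- hit[hit != i]
      pre <- c(pre, rep.int(i, length(hit)))
      post <- c(post, hit)
    }
    w <- sampleLognormalWeights(mu, theta, length(pre))
    new("NetworkTopology", nExc = as.integer(nExc), nInh = as.integer(nInh),
        pre = pre, post = post, weight = w,
        pConn = pConn, seed = as.integer(seed))
  })
}

#' Synaptic current of one receptor at a given time since the spike
#'
#' Double-exponential synaptic current
#' \deqn{I_X = P_X B_X(V) v g (e^{-t/\tau_s} - e^{-t/\tau_f}) (V - E_X)}
#' where \eqn{B} is 1 for AMPA and GABA-A and the sigmoidal magnesium-block
#' factor \eqn{1/(1+e^{-(V+10)/3.57})} for NMDA. The returned current uses
#' the membrane-equation sign convention: it is subtracted from the membrane
#' balance, so negative values depolarize.
#'
#' @param receptor one of "AMPA", "NMDA", "GABA_A".
#' @param w synaptic conductance (mS/cm^2).
#' @param elapsed time since the presynaptic spike (ms, >= 0); vectorized.
#' @param V_post postsynaptic voltage (mV).
#' @param P receptor efficacy scaling factor.
#' @param v_half event-scale factor in [0.5, 1].
#' @param synapse a \code{\link{synapseParams}} list.
#' @return synaptic current (uA/cm^2), one value per \code{elapsed}.
#' @export
synapticCurrent <- function(receptor, w, elapsed, V_post, P = 1, v_half = 1,
                            synapse = synapseParams()) {
  if (any(elapsed < 0)) stop("elapsed must be non-negative")
  if (v_half < 0.5 || v_half > 1) stop("v_half must lie in [0.5, 1]")
  tf <- synapse$tau_fast
  spec <- switch(receptor,
    AMPA = list(ts = synapse$tau_ampa_slow, E = synapse$E_exc, B = 1),
    NMDA = list(ts = synapse$tau_nmda_slow, E = synapse$E_exc,
                B = 1 / (1 + exp(-(V_post + 10) / 3.57))),
    GABA_A = list(ts = synapse$tau_gaba_slow, E = synapse$E_inh, B = 1),
    stop("unknown receptor: ", receptor))
  kernel <- exp(-elapsed / spec$ts) - exp(-elapsed / tf)
  P * spec$B * v_half * w * kernel * (V_post - spec$E)
}

#' Fraction of excitatory connections that fire a resting cell
#'
#' Bisects (on a log-conductance scale) the minimal single-edge conductance
#' whose lone presynaptic spike (event scale 1, AMPA+NMDA sharing the
#' weight) elicits an action potential in a postsynaptic cell initialized at
#' its resting state, then reports the lognormal tail probability above that
#' threshold (the analytic fraction of "suprathreshold" connections) and,
#' optionally, the empirical fraction of supplied weights above it.
#'
#' @param P_AMPA,P_NMDA receptor efficacy factors of the condition tested
#'   (wake-state values by default).
#' @param g_Ks postsynaptic M-current conductance (mS/cm^2).
#' @param params a \code{\link{neuronParams}} list.
#' @param mu,theta lognormal weight parameters.
#' @param weights optional sampled weights for the empirical fraction.
#' @param tol relative bisection tolerance on the threshold conductance.
#' @param dt integration step (ms).
#' @return list with \code{threshold} (mS/cm^2), \code{analytic_fraction},
#'   \code{empirical_fraction} (NA when no weights are supplied).
#' @export
fractionSuprathreshold <- function(P_AMPA = 1.22, P_NMDA = 1.64, g_Ks = 0.97,
                                   params = neuronParams(), mu = -20.0,
                                   theta = 9.4, weights = NULL,
                                   tol = 1e-4, dt = 0.05) {
  p <- params
  p$g_Ks <- g_Ks
  rest <- restingState(p)
  init <- c(rest$V, rest$h, rest$n, rest$z)
  syn <- synapseParams(P_AMPA = P_AMPA, P_NMDA = P_NMDA)
  fires <- function(w) {
    sim <- simulateNeuron(p, duration = 400, dt = dt,
                          eventTimes = 20, eventWeights = w,
                          synapse = syn, init = init)
    length(sim$spikes) > 0
  }
  lo <- 1e-6; hi <- 1e4
  if (fires(lo)) stop("threshold below search bound ", lo)
  if (!fires(hi)) stop("threshold above search bound ", hi)
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (fires(mid)) hi <- mid else lo <- mid
  }
  gstar <- hi
  list(threshold = gstar,
       analytic_fraction = 1 - pnorm((log(gstar) - mu) / theta),
       empirical_fraction = if (is.null(weights)) NA_real_
                            else mean(weights > gstar))
}
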