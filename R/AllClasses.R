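#' @import methods
#' @importFrom stats runif rnorm sd cor pt quantile median ks.test pnorm qnorm
#' @importFrom utils read.csv write.csv head
#' @importFrom Rcpp evalCpp
#' @useDynLib anesnet, .registration = TRUE
NULL

#' SpikeRaster: a population spike train
#'
#' Container for (neuron, time) spike events from a simulation, a recording,
#' or a synthetic generator. Times are in milliseconds on \code{[0, duration]};
#' neuron ids are 0-based integers in \code{[0, nNeurons)}. Events are stored
#' sorted by time.
#'
#' @slot neuron integer vector of 0-based neuron ids.
#' @slot time numeric vector of spike times (ms), sorted non-decreasing.
#' @slot nNeurons total number of neurons in the population.
#' @slot duration recording length (ms).
#' @slot metadata list of provenance fields (seed, dt, level label, ...).
#' @export
setClass("SpikeRaster",
  representation(neuron = "integer", time = "numeric",
                 nNeurons = "integer", duration = "numeric",
                 metadata = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@neuron) != length(object@time))
      msg <- c(msg, "neuron and time must have equal length")
    if (length(object@nNeurons) != 1L || object@nNeurons < 1L)
      msg <- c(msg, "nNeurons must be a single positive integer")
    if (length(object@duration) != 1L || object@duration <= 0)
      msg <- c(msg, "duration must be a single positive number")
    if (length(object@time) && is.unsorted(object@time))
      msg <- c(msg, "times must be sorted non-decreasing")
    if (length(object@time) &&
        (min(object@time) < 0 || max(object@time) > object@duration))
      msg <- c(msg, "spike times must lie in [0, duration]")
    if (length(object@neuron) &&
        (min(object@neuron) < 0L || max(object@neuron) >= object@nNeurons))
      msg <- c(msg, "neuron ids must lie in [0, nNeurons)")
    if (is.null(msg)) TRUE else msg
  })

#' NetworkTopology: directed weighted E-I graph
#'
#' Directed Erdos-Renyi graph over \code{nExc} excitatory followed by
#' \code{nInh} inhibitory neurons, with one lognormal conductance per edge.
#' The receptor class of an edge is implied by its presynaptic type:
#' excitatory edges deliver AMPA+NMDA (sharing the weight), inhibitory edges
#' deliver GABA-A.
#'
#' @slot nExc,nInh neuron counts.
#' @slot pre,post 0-based edge endpoints (directed pre -> post).
#' @slot weight edge conductances (mS/cm^2), lognormally distributed.
#' @slot pConn connection probability used to build the graph.
#' @slot seed RNG seed the graph was built from.
#' @export
setClass("NetworkTopology",
  representation(nExc = "integer", nInh = "integer",
                 pre = "integer", post = "integer", weight = "numeric",
                 pConn = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    n <- object@nExc + object@nInh
    if (object@nExc < 1L || object@nInh < 0L)
      msg <- c(msg, "need at least one excitatory neuron")
    if (length(object@pre) != length(object@post) ||
        length(object@pre) != length(object@weight))
      msg <- c(msg, "pre, post and weight must have equal length")
    if (length(object@pre) && any(object@pre == object@post))
      msg <- c(msg, "self-edges are not allowed")
    if (length(object@pre) &&
        (min(c(object@pre, object@post)) < 0L ||
         max(c(object@pre, object@post)) >= n))
      msg <- c(msg, "edge endpoints out of range")
    if (length(object@weight) && any(object@weight <= 0))
      msg <- c(msg, "all weights must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Correlogram: pairwise lagged coincidence counts
#'
#' Cross-correlogram between a reference and a comparison spike train:
#' comparison-spike lags relative to each reference spike, binned at 1.3 ms
#' over a 40 ms window centred on zero lag (30 full bins; the partial
#' rightmost bin is dropped).
#'
#' @slot lags bin centres (ms).
#' @slot counts coincidence counts per bin.
#' @slot binWidth bin width (ms).
#' @slot nRefSpikes number of reference spikes.
#' @export
setClass("Correlogram",
  representation(lags = "numeric", counts = "integer",
                 binWidth = "numeric", nRefSpikes = "integer"),
  validity = function(object) {
    if (length(object@lags) != length(object@counts))
      return("lags and counts must have equal length")
    TRUE
  })

#' FunctionalNetwork: inferred functional connectivity
#'
#' Result of cross-correlogram edge classification over the eligible-neuron
#' subsample of a raster: one row per tested ordered pair with its sign,
#' standardized strength and peak lag, plus per-sign connection probabilities
#' and mean strengths.
#'
#' @slot edges data.frame with columns pre, post, sign, strength, peak_lag_ms,
#'   significant.
#' @slot eligible 0-based ids of the analysed neurons.
#' @slot probability named numeric: excitatory and inhibitory connection
#'   probability (significant pairs / tested ordered pairs).
#' @slot meanStrength named numeric: mean standardized strength per sign over
#'   significant pairs.
#' @export
setClass("FunctionalNetwork",
  representation(edges = "data.frame", eligible = "integer",
                 probability = "numeric", meanStrength = "numeric"),
  validity = function(object) {
    if (length(object@probability) &&
        (any(object@probability < 0) || any(object@probability > 1)))
      return("probabilities must lie in [0, 1]")
    TRUE
  })

#' DEPopulation: differential-evolution population
#'
#' A 30-agent population of candidate parameter sets (P_NMDA, P_GABA, P_AMPA,
#' g_Ks) with their costs, the generation counter, and the best-cost history.
#'
#' @slot agents numeric matrix, one row per agent, named parameter columns.
#' @slot cost numeric vector of agent costs.
#' @slot breakdown matrix of per-measure cost terms (one row per agent).
#' @slot generation generation counter.
#' @slot bestHistory best cost per generation so far.
#' @export
setClass("DEPopulation",
  representation(agents = "matrix", cost = "numeric", breakdown = "matrix",
                 generation = "integer", bestHistory = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@agents) != length(object@cost))
      msg <- c(msg, "one cost per agent required")
    if (any(object@agents <= 0))
      msg <- c(msg, "all parameters must be positive")
    if (any(object@cost < -1e-12, na.rm = TRUE))
      msg <- c(msg, "costs must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SpikeRaster", function(object) {
  cat("SpikeRaster:", length(object@time), "spikes,",
      object@nNeurons, "neurons,",
      sprintf("%.1f s", object@duration / 1000), "\n")
  if (length(object@time)) {
    rate <- length(object@time) / object@nNeurons / (object@duration / 1000)
    cat("  mean rate:", sprintf("%.2f Hz", rate), "\n")
  }
  if (!is.null(object@metadata$label))
    cat("  level:", object@metadata$label, "\n")
  invisible(object)
})

setMethod("show", "NetworkTopology", function(object) {
  cat("NetworkTopology:", object@nExc, "excitatory +", object@nInh,
      "inhibitory neurons,", length(object@pre), "edges",
      sprintf("(p = %.2f, seed = %d)", object@pConn, object@seed), "\n")
  invisible(object)
})

setMethod("show", "Correlogram", function(object) {
  cat("Correlogram:", length(object@lags), "bins of",
      object@binWidth, "ms,", object@nRefSpikes, "reference spikes\n")
  invisible(object)
})

setMethod("show", "FunctionalNetwork", function(object) {
  cat("FunctionalNetwork:", length(object@eligible), "neurons,",
      nrow(object@edges), "tested pairs\n")
  cat(sprintf("  excitatory: p = %.4f, mean strength = %.2f\n",
              object@probability[["excitatory"]],
              object@meanStrength[["excitatory"]]))
  cat(sprintf("  inhibitory: p = %.4f, mean strength = %.2f\n",
              object@probability[["inhibitory"]],
              object@meanStrength[["inhibitory"]]))
  invisible(object)
})

setMethod("show", "DEPopulation", function(object) {
  cat("DEPopulation:", nrow(object@agents), "agents, generation",
      object@generation, "\n")
  best <- which.min(object@cost)
  cat("  best cost:", format(object@cost[best], digits = 4), "at",
      paste(sprintf("%s = %.3f", colnames(object@agents),
                    object@agents[best, ]), collapse = ", "), "\n")
  invisible(object)
})
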