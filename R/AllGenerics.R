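#' @rdname SpikeRaster-class
#' @param neuron integer vector of 0-based neuron ids.
#' @param time numeric vector of spike times in ms.
#' @param nNeurons number of neurons in the population.
#' @param duration recording duration in ms.
#' @param metadata optional list of provenance fields.
#' @return A \code{SpikeRaster} object with events sorted by time.
#' @examples
#' r <- SpikeRaster(neuron = c(0L, 1L, 0L), time = c(5, 2.5, 9),
#'                  nNeurons = 2, duration = 10)
#' nNeurons(r)
#' @export
SpikeRaster <- function(neuron, time, nNeurons, duration, metadata = list()) {
  o <- order(time, neuron)
  new("SpikeRaster", neuron = as.integer(neuron)[o], time = as.numeric(time)[o],
      nNeurons = as.integer(nNeurons), duration = as.numeric(duration),
      metadata = metadata)
}

#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' Number of neurons in a raster or topology
#' @param x a \code{SpikeRaster} or \code{NetworkTopology}.
#' @return integer count of neurons.
#' @rdname nNeurons
#' @export
setMethod("nNeurons", "SpikeRaster", function(x) x@nNeurons)
#' @rdname nNeurons
#' @export
setMethod("nNeurons", "NetworkTopology", function(x) x@nExc + x@nInh)

#' @export
setGeneric("rasterDuration", function(x) standardGeneric("rasterDuration"))
#' Duration of a spike raster in ms
#' @param x a \code{SpikeRaster}.
#' @rdname rasterDuration
#' @export
setMethod("rasterDuration", "SpikeRaster", function(x) x@duration)

#' @export
setGeneric("spikeEvents", function(x) standardGeneric("spikeEvents"))
#' Spike events as a data.frame
#' @param x a \code{SpikeRaster}.
#' @return data.frame with columns \code{neuron_id} and \code{time_ms}.
#' @rdname spikeEvents
#' @export
setMethod("spikeEvents", "SpikeRaster", function(x)
  data.frame(neuron_id = x@neuron, time_ms = x@time))

#' Spike trains of selected neurons
#'
#' @param x a \code{SpikeRaster}.
#' @param ids 0-based neuron ids (default: all neurons).
#' @param interval optional \code{c(start, end)} ms window; only spikes with
#'   \code{start <= t < end} are kept.
#' @return named list of sorted spike-time vectors, one per requested id.
#' @export
spikeTrains <- function(x, ids = NULL, interval = NULL) {
  stopifnot(is(x, "SpikeRaster"))
  if (is.null(ids)) ids <- seq_len(x@nNeurons) - 1L
  t <- x@time
  nrn <- x@neuron
  if (!is.null(interval)) {
    keep <- t >= interval[1] & t < interval[2]
    t <- t[keep]
    nrn <- nrn[keep]
  }
  out <- split(t, factor(nrn, levels = ids))
  lapply(out, as.numeric)
}

#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' Number of directed edges in a topology
#' @param x a \code{NetworkTopology}.
#' @rdname nEdges
#' @export
setMethod("nEdges", "NetworkTopology", function(x) length(x@pre))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' Edge list of a topology as a data.frame
#' @param x a \code{NetworkTopology}.
#' @return data.frame with pre, post, weight and receptor class
#'   (\code{"exc"} edges carry AMPA+NMDA, \code{"inh"} edges GABA-A).
#' @rdname edgeTable
#' @export
setMethod("edgeTable", "NetworkTopology", function(x)
  data.frame(pre = x@pre, post = x@post, weight = x@weight,
             class = ifelse(x@pre < x@nExc, "exc", "inh")))

#' @export
setGeneric("ccgCounts", function(x) standardGeneric("ccgCounts"))
#' Coincidence counts of a correlogram
#' @param x a \code{Correlogram}.
#' @rdname ccgCounts
#' @export
setMethod("ccgCounts", "Correlogram", function(x) x@counts)

#' @export
setGeneric("ccgLags", function(x) standardGeneric("ccgLags"))
#' Lag bin centres of a correlogram (ms)
#' @param x a \code{Correlogram}.
#' @rdname ccgLags
#' @export
setMethod("ccgLags", "Correlogram", function(x) x@lags)

#' @export
setGeneric("functionalEdges", function(x) standardGeneric("functionalEdges"))
#' Edge table of a functional network
#' @param x a \code{FunctionalNetwork}.
#' @rdname functionalEdges
#' @export
setMethod("functionalEdges", "FunctionalNetwork", function(x) x@edges)

#' @export
setGeneric("connectionProbability",
           function(x) standardGeneric("connectionProbability"))
#' Per-sign functional connection probability
#' @param x a \code{FunctionalNetwork}.
#' @rdname connectionProbability
#' @export
setMethod("connectionProbability", "FunctionalNetwork",
          function(x) x@probability)

#' @export
setGeneric("connectionStrength",
           function(x) standardGeneric("connectionStrength"))
#' Per-sign mean functional connection strength
#' @param x a \code{FunctionalNetwork}.
#' @rdname connectionStrength
#' @export
setMethod("connectionStrength", "FunctionalNetwork",
          function(x) x@meanStrength)

#' @export
setGeneric("bestAgent", function(x) standardGeneric("bestAgent"))
#' Lowest-cost agent of a DE population
#' @param x a \code{DEPopulation}.
#' @return list with \code{params} (named numeric), \code{cost} and the
#'   per-measure \code{breakdown}.
#' @rdname bestAgent
#' @export
setMethod("bestAgent", "DEPopulation", function(x) {
  i <- which.min(x@cost)
  list(params = x@agents[i, ], cost = x@cost[i], breakdown = x@breakdown[i, ])
})

#' @export
setGeneric("costHistory", function(x) standardGeneric("costHistory"))
#' Best cost per generation of a DE population
#' @param x a \code{DEPopulation}.
#' @rdname costHistory
#' @export
setMethod("costHistory", "DEPopulation", function(x) x@bestHistory)
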