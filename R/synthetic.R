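#' Independent Poisson spike rasters
#'
#' Homogeneous Poisson trains with per-neuron rates, either constant or
#' drawn from a lognormal rate distribution — the baseline fixture for
#' testing every measurement stage without the simulator. Rates and
#' structure emulate cortical multi-unit recordings (tens of units at
#' 1-10 Hz).
#'
#' @param nNeurons number of neurons.
#' @param duration raster length (ms).
#' @param rate scalar rate (Hz) for all neurons, or a vector of per-neuron
#'   rates.
#' @param rateLogMean,rateLogSd if not NULL, draw per-neuron rates from
#'   exp(Normal(rateLogMean, rateLogSd)) Hz instead (overrides \code{rate}).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{SpikeRaster}}.
#' @examples
#' r <- poissonRaster(10, 10000, rate = 5, seed = 1)
#' @export
poissonRaster <- function(nNeurons, duration, rate = 5,
                          rateLogMean = NULL, rateLogSd = NULL, seed = 1L) {
  withSeed(seed, {
    rates <- if (!is.null(rateLogMean)) {
      exp(rnorm(nNeurons, rateLogMean, rateLogSd))
    } else rep_len(rate, nNeurons)
    if (any(rates <= 0)) stop("rates must be positive")
    ev <- lapply(seq_len(nNeurons), function(i) {
      n <- stats::rpois(1, rates[i] * duration / 1000)
      sort(runif(n, 0, duration))
    })
    SpikeRaster(neuron = rep(seq_len(nNeurons) - 1L, lengths(ev)),
                time = unlist(ev), nNeurons = nNeurons, duration = duration,
                metadata = list(generator = "poisson", seed = seed,
                                rates = rates))
  })
}

#' Phase-locked spike rasters from a common oscillator
#'
#' Every neuron spikes once per cycle of a common oscillator of period
#' \code{period}, at a fixed per-neuron phase offset, plus Gaussian timing
#' jitter — the fixture for the mean-phase-coherence contract (MPC is 1 at
#' zero jitter and falls towards the independent baseline as jitter grows).
#'
#' @param nNeurons number of neurons.
#' @param duration raster length (ms).
#' @param period oscillator period (ms).
#' @param jitterSd Gaussian jitter of each spike time (ms).
#' @param phases per-neuron phase offsets in [0, 1) (default: evenly
#'   spread).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{SpikeRaster}}.
#' @export
synchronizedRaster <- function(nNeurons, duration, period = 100,
                               jitterSd = 0, phases = NULL, seed = 1L) {
  if (period <= 0) stop("period must be positive")
  withSeed(seed, {
    if (is.null(phases)) phases <- (seq_len(nNeurons) - 1) / nNeurons
    cycles <- seq(0, duration - period, by = period)
    nrn <- integer(0); tim <- numeric(0)
    for (i in seq_len(nNeurons)) {
      t <- cycles + phases[i] * period
      if (jitterSd > 0) t <- t + rnorm(length(t), 0, jitterSd)
      t <- t[t >= 0 & t < duration]
      nrn <- c(nrn, rep.int(i - 1L, length(t)))
      tim <- c(tim, t)
    }
    SpikeRaster(neuron = nrn, time = tim, nNeurons = nNeurons,
                duration = duration,
                metadata = list(generator = "synchronized", period = period,
                                jitter_sd = jitterSd, seed = seed))
  })
}

#' Poisson rasters with embedded monosynaptic couplings
#'
#' Independent Poisson trains in which each presynaptic spike of a coupled
#' pair adds a postsynaptic spike at a fixed lag with a given transmission
#' probability (collisions within 0.5 ms merge) — the fixture for
#' cross-correlogram edge detection.
#'
#' @param nNeurons number of neurons.
#' @param duration raster length (ms).
#' @param rate baseline Poisson rate (Hz), scalar or per-neuron.
#' @param coupling data.frame with columns \code{pre}, \code{post} (0-based
#'   ids), \code{lag_ms} (>= 0) and \code{prob} (transmission probability in
#'   [0, 1]).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{SpikeRaster}}.
#' @export
coupledRaster <- function(nNeurons, duration, rate = 5,
                          coupling = NULL, seed = 1L) {
  withSeed(seed, {
    rates <- rep_len(rate, nNeurons)
    trains <- lapply(seq_len(nNeurons), function(i) {
      n <- stats::rpois(1, rates[i] * duration / 1000)
      sort(runif(n, 0, duration))
    })
    if (!is.null(coupling)) {
      stopifnot(all(c("pre", "post", "lag_ms", "prob") %in% names(coupling)))
      if (any(coupling$lag_ms < 0)) stop("lags must be non-negative")
      if (any(coupling$prob < 0 | coupling$prob > 1))
        stop("transmission probability must lie in [0, 1]")
      for (k in seq_len(nrow(coupling))) {
        pre <- trains[[coupling$pre[k] + 1L]]
        hit <- pre[runif(length(pre)) < coupling$prob[k]] + coupling$lag_ms[k]
        hit <- hit[hit < duration]
        post <- sort(c(trains[[coupling$post[k] + 1L]], hit))
        # merge collisions closer than 0.5 ms
        if (length(post) > 1)
          post <- post[c(TRUE, diff(post) >= 0.5)]
        trains[[coupling$post[k] + 1L]] <- post
      }
    }
    SpikeRaster(neuron = rep(seq_len(nNeurons) - 1L, lengths(trains)),
                time = unlist(trains), nNeurons = nNeurons,
                duration = duration,
                metadata = list(generator = "coupled", seed = seed))
  })
}
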