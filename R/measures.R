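#' Bin spikes into a binary pattern matrix
#'
#' Discretizes a raster (or a time window of it) into 1 ms bins, yielding the
#' neurons x bins binary occupancy matrix that feeds the entropy measures.
#' Multiple spikes of one neuron in a bin collapse to a single 1.
#'
#' @param raster a \code{\linkS4class{SpikeRaster}}.
#' @param interval \code{c(start, end)} ms window (default: whole raster).
#' @param binWidth bin width in ms.
#' @param ids 0-based neuron ids to include (default all); row order follows
#'   \code{ids}.
#' @return binary integer matrix with one row per neuron and
#'   \code{floor(window / binWidth)} columns.
#' @export
binSpikes <- function(raster, interval = NULL, binWidth = 1, ids = NULL) {
  stopifnot(is(raster, "SpikeRaster"))
  if (is.null(interval)) interval <- c(0, raster@duration)
  if (diff(interval) <= 0) stop("empty interval")
  if (is.null(ids)) ids <- seq_len(raster@nNeurons) - 1L
  nbins <- floor(diff(interval) / binWidth)
  if (nbins < 1) stop("interval shorter than one bin")
  keep <- raster@time >= interval[1] & raster@time < interval[1] + nbins * binWidth
  nrn <- raster@neuron[keep]
  bin <- floor((raster@time[keep] - interval[1]) / binWidth)
  m <- matrix(0L, nrow = length(ids), ncol = nbins,
              dimnames = list(ids, NULL))
  ridx <- match(nrn, ids)
  ok <- !is.na(ridx)
  m[cbind(ridx[ok], bin[ok] + 1L)] <- 1L
  m
}

# Plug-in (maximum-likelihood) entropy of a count vector, in bits.
pluginEntropy <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Column-pattern keys of a binary matrix (active row indices per column).
patternKeys <- function(m) {
  act <- which(m == 1L, arr.ind = TRUE)
  keys <- rep("", ncol(m))
  if (nrow(act)) {
    byCol <- split(act[, 1L], act[, 2L])
    keys[as.integer(names(byCol))] <-
      vapply(byCol, function(r) paste(sort(r), collapse = ","), character(1))
  }
  keys
}

#' Integration of a binned spike pattern matrix
#'
#' Integration is the sum of the single-neuron entropies minus the joint
#' entropy of the column patterns,
#' \deqn{I(X) = \sum_i H(X_i) - H(X),}
#' with all entropies plug-in estimates in bits. It is zero when neurons are
#' statistically independent and grows with any form of interaction.
#'
#' @param patterns binary matrix from \code{\link{binSpikes}}.
#' @return integration in bits (non-negative up to estimator round-off).
#' @export
integrationMeasure <- function(patterns) {
  if (!is.matrix(patterns) || nrow(patterns) < 1 || ncol(patterns) < 1)
    stop("patterns must be a non-empty matrix")
  hMarg <- sum(apply(patterns, 1, function(r)
    pluginEntropy(c(sum(r == 1L), sum(r == 0L)))))
  hJoint <- pluginEntropy(table(patternKeys(patterns)))
  hMarg - hJoint
}

#' Interaction complexity of a binned spike pattern matrix
#'
#' Complexity is the joint entropy minus the summed conditional entropies of
#' each neuron given the rest,
#' \deqn{C(X) = H(X) - \sum_i H(X_i | X - X_i).}
#' It is low both for independent and for fully synchronized populations and
#' peaks for structured interaction. Computed through the identity
#' \eqn{H(X_i | X - X_i) = H(X) - H(X - X_i)}, so
#' \eqn{C = \sum_i H(X - X_i) - (N - 1) H(X)}. A single-neuron matrix
#' returns 0 by convention.
#'
#' @param patterns binary matrix from \code{\link{binSpikes}}.
#' @param direct if TRUE, compute the conditional entropies directly from
#'   joint (row, rest-pattern) counts instead of via the subtraction
#'   identity (used for cross-checking; both agree to round-off).
#' @return complexity in bits.
#' @export
complexityMeasure <- function(patterns, direct = FALSE) {
  if (!is.matrix(patterns) || nrow(patterns) < 1 || ncol(patterns) < 1)
    stop("patterns must be a non-empty matrix")
  N <- nrow(patterns)
  if (N < 2) return(0)
  keysFull <- patternKeys(patterns)
  hJoint <- pluginEntropy(table(keysFull))
  if (direct) {
    condSum <- 0
    for (i in seq_len(N)) {
      rest <- patternKeys(patterns[-i, , drop = FALSE])
      joint <- table(paste(patterns[i, ], rest, sep = "|"))
      condSum <- condSum + (pluginEntropy(joint) - pluginEntropy(table(rest)))
    }
    return(hJoint - condSum)
  }
  hRest <- vapply(seq_len(N), function(i)
    pluginEntropy(table(patternKeys(patterns[-i, , drop = FALSE]))),
    numeric(1))
  sum(hRest) - (N - 1) * hJoint
}

#' Pairwise and network mean phase coherence
#'
#' For an ordered pair (reference i, comparison j), every comparison spike
#' falling inside a reference interspike interval contributes a unit phasor
#' at phase \eqn{(t_{j,k} - t_{i,k}) / (t_{i,k+1} - t_{i,k})}; the pairwise
#' coherence is the modulus of the mean phasor (1 = perfect locking, 0 =
#' random phases). The network value is the mean over all ordered pairs with
#' at least one contributing spike; pairs without contributing spikes (or
#' fewer than two reference spikes) are excluded.
#'
#' @param raster a \code{\linkS4class{SpikeRaster}}, or a list of sorted
#'   spike-time vectors.
#' @param ids 0-based neuron ids to analyse (raster input only; default all).
#' @param interval optional \code{c(start, end)} ms window.
#' @return list with \code{mpc} (network mean), \code{sigma} (matrix of
#'   pairwise values, reference neurons in rows, NA where undefined) and
#'   \code{n_pairs} (number of contributing ordered pairs).
#' @export
meanPhaseCoherence <- function(raster, ids = NULL, interval = NULL) {
  trains <- if (is.list(raster)) {
    lapply(raster, as.numeric)
  } else {
    spikeTrains(raster, ids = ids, interval = interval)
  }
  sig <- cpp_mpc_matrix(trains)
  ok <- !is.na(sig)
  list(mpc = if (any(ok)) mean(sig[ok]) else NA_real_,
       sigma = sig, n_pairs = sum(ok))
}

#' Pairwise phase coherence of two spike trains
#'
#' Convenience wrapper around \code{\link{meanPhaseCoherence}} for one
#' ordered (reference, comparison) pair.
#'
#' @param ref,cmp sorted spike-time vectors (ms).
#' @return the pairwise coherence, or NA if undefined.
#' @export
pairPhaseCoherence <- function(ref, cmp) {
  cpp_mpc_matrix(list(as.numeric(ref), as.numeric(cmp)))[1, 2]
}

#' Per-neuron firing rates and their distribution shape
#'
#' @param raster a \code{\linkS4class{SpikeRaster}}.
#' @param breaks histogram break specification (passed to \code{hist}).
#' @return list with \code{rates} (Hz per neuron), \code{mean_rate},
#'   \code{skewness} (Fisher-Pearson moment coefficient of the rate
#'   distribution; 0 when degenerate) and \code{histogram}.
#' @export
rateStats <- function(raster, breaks = "Sturges") {
  stopifnot(is(raster, "SpikeRaster"))
  rates <- tabulate(raster@neuron + 1L, nbins = raster@nNeurons) /
    (raster@duration / 1000)
  s <- sd(rates)
  skew <- if (is.na(s) || s == 0) 0 else mean(((rates - mean(rates)) / s)^3)
  list(rates = rates, mean_rate = mean(rates), skewness = skew,
       histogram = graphics::hist(rates, breaks = breaks, plot = FALSE))
}

#' The four fitted network measures under the subsampling protocol
#'
#' Computes mean firing rate, mean phase coherence, integration and
#' complexity the way the model is fitted and evaluated: one random
#' subsample of \code{nSub} neurons (fixed across intervals), measures
#' computed on \code{nIntervals} non-overlapping random windows of
#' \code{intervalLen} and averaged.
#'
#' @param raster a \code{\linkS4class{SpikeRaster}}.
#' @param nSub neurons in the random subsample (all neurons if the
#'   population is smaller).
#' @param nIntervals number of analysis windows.
#' @param intervalLen window length in ms.
#' @param seed RNG seed for the subsample and window placement.
#' @param binWidth bin width for the entropy measures (ms).
#' @return list of class \code{"MeasureSet"}: \code{mean_rate} (Hz),
#'   \code{mpc}, \code{integration}, \code{complexity} (bits), plus a
#'   \code{per_interval} data.frame and the subsampled \code{ids}.
#' @export
measureSuite <- function(raster, nSub = 60, nIntervals = 3,
                         intervalLen = 6000, seed = 1L, binWidth = 1) {
  stopifnot(is(raster, "SpikeRaster"))
  dur <- raster@duration
  if (dur < nIntervals * intervalLen)
    stop("raster too short: need at least ", nIntervals * intervalLen,
         " ms for ", nIntervals, " non-overlapping intervals")
  withSeed(seed, {
    ids <- if (nSub >= raster@nNeurons) seq_len(raster@nNeurons) - 1L
           else sort(sample.int(raster@nNeurons, nSub) - 1L)
    # non-overlapping interval starts: draw gaps, spread the slack
    slack <- dur - nIntervals * intervalLen
    cuts <- sort(runif(nIntervals, 0, slack))
    starts <- cuts + (seq_len(nIntervals) - 1) * intervalLen
    per <- lapply(seq_len(nIntervals), function(k) {
      iv <- c(starts[k], starts[k] + intervalLen)
      pat <- binSpikes(raster, interval = iv, binWidth = binWidth, ids = ids)
      nSpk <- sum(raster@time >= iv[1] & raster@time < iv[2] &
                    raster@neuron %in% ids)
      data.frame(interval = k, start_ms = iv[1],
                 mean_rate_hz = nSpk / length(ids) / (intervalLen / 1000),
                 mpc = meanPhaseCoherence(raster, ids = ids, interval = iv)$mpc,
                 integration_bits = integrationMeasure(pat),
                 complexity_bits = complexityMeasure(pat))
    })
    per <- do.call(rbind, per)
    out <- list(mean_rate = mean(per$mean_rate_hz),
                mpc = mean(per$mpc, na.rm = TRUE),
                integration = mean(per$integration_bits),
                complexity = mean(per$complexity_bits),
                per_interval = per, ids = ids)
    class(out) <- c("MeasureSet", "list")
    out
  })
}

#' @export
print.MeasureSet <- function(x, ...) {
  cat(sprintf(
    "MeasureSet: rate %.2f Hz | MPC %.3f | I(X) %.2f bits | C(X) %.2f bits\n",
    x$mean_rate, x$mpc, x$integration, x$complexity))
  invisible(x)
}
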