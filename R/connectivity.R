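# Cross-correlogram functional-connectivity inference with a jittered
# surrogate null, following the event-synchrony conventions used for
# monosynaptic connection detection in multi-unit recordings.

ccgLo <- -19.5       # leftmost bin edge (ms): 30 bins of 1.3 ms centred on 0
ccgBinWidth <- 1.3
ccgNBins <- 30L
ccgStrengthBins <- 16:19  # left edges 0, 1.3, 2.6, 3.9 ms

#' Cross-correlogram of two spike trains
#'
#' For every reference spike, comparison spikes within the +/- 20 ms window
#' are binned by relative lag at 1.3 ms resolution (30 full bins centred on
#' zero; the partial rightmost bin of the 40 ms window is dropped).
#'
#' @param ref,cmp sorted spike-time vectors (ms); both non-empty.
#' @return a \code{\linkS4class{Correlogram}}.
#' @examples
#' ccg <- crossCorrelogram(c(100, 200), c(103, 203))
#' ccgLags(ccg)[which.max(ccgCounts(ccg))]  # ~ +3 ms
#' @export
crossCorrelogram <- function(ref, cmp) {
  ref <- as.numeric(ref); cmp <- as.numeric(cmp)
  if (!length(ref) || !length(cmp)) stop("spike trains must be non-empty")
  counts <- cpp_ccg_counts(ref, cmp, ccgLo, ccgBinWidth, ccgNBins)
  new("Correlogram",
      lags = ccgLo + ccgBinWidth * (seq_len(ccgNBins) - 0.5),
      counts = as.integer(counts), binWidth = ccgBinWidth,
      nRefSpikes = length(ref))
}

#' Jitter a spike train
#'
#' Displaces every spike independently by U[-halfWidth, +halfWidth] ms and
#' re-sorts — the surrogate that destroys fine-timescale correlations while
#' preserving spike counts and slow rate structure.
#'
#' @param train spike-time vector (ms).
#' @param halfWidth jitter half-width (ms).
#' @param seed optional RNG seed.
#' @return jittered, sorted spike-time vector of the same length.
#' @export
jitterTrain <- function(train, halfWidth = 5, seed = NULL) {
  if (halfWidth < 0) stop("halfWidth must be non-negative")
  if (!length(train) || halfWidth == 0) return(sort(as.numeric(train)))
  withSeed(seed, sort(train + runif(length(train), -halfWidth, halfWidth)))
}

#' Jittered-surrogate null band for one ordered pair
#'
#' Builds the null distribution for edge classification from \code{nSurr}
#' surrogates in which the comparison train is jittered by +/-
#' \code{jitter} ms: per-surrogate peak and trough within the strength
#' window (lags 0-5.2 ms), their moments, the 97th-percentile offsets of the
#' global extrema from their means, and the per-bin surrogate moments.
#'
#' @param ref,cmp sorted spike-time vectors (ms).
#' @param nSurr number of surrogates.
#' @param jitter jitter half-width (ms).
#' @param seed RNG seed for the surrogate jitters.
#' @return list of class \code{"SurrogateBand"}.
#' @export
surrogateBand <- function(ref, cmp, nSurr = 100, jitter = 5, seed = 1L) {
  ref <- as.numeric(ref); cmp <- as.numeric(cmp)
  if (!length(ref) || !length(cmp)) stop("spike trains must be non-empty")
  s <- cpp_pair_surrogates(ref, cmp, ccgLo, ccgBinWidth, ccgNBins,
                           as.integer(ccgStrengthBins), nSurr, jitter,
                           as.integer(seed))
  binMean <- s$surr_bin_moments[1, ] / nSurr
  binVar <- pmax(s$surr_bin_moments[2, ] / nSurr - binMean^2, 0)
  grand <- mean(binMean)
  band <- list(
    observed = as.integer(s$observed),
    peak_mean = mean(s$surr_peak), peak_sd = sd(s$surr_peak),
    trough_mean = mean(s$surr_trough), trough_sd = sd(s$surr_trough),
    grand_mean = grand,
    band97_peak_offset =
      unname(quantile(s$surr_global_peak, 0.97)) - grand,
    band97_trough_offset =
      unname(quantile(s$surr_global_trough, 0.03)) - grand,
    bin_mean = binMean, bin_sd = sqrt(binVar),
    n_surrogates = nSurr, jitter = jitter)
  class(band) <- c("SurrogateBand", "list")
  band
}

#' Classify a functional edge from a correlogram and its null band
#'
#' The standardized statistic is (extremum within lags 0-5.2 ms -
#' surrogate mean) / surrogate SD, computed separately for the peak
#' (excitatory candidate) and the trough (inhibitory candidate). An edge is
#' excitatory when the raw peak, measured from the surrogate grand mean of
#' the correlogram, exceeds twice the 97th-percentile excursion of the
#' surrogate global peak above that mean; the mirrored criterion (3rd
#' percentile of the global trough below the mean) applies to the trough.
#' When both pass, the larger standardized magnitude wins. The standardized
#' statistics are reported regardless of significance.
#'
#' @param ccg a \code{\linkS4class{Correlogram}} for the ordered pair.
#' @param band the matching \code{\link{surrogateBand}}.
#' @return list with \code{sign} ("excitatory", "inhibitory" or "none"),
#'   \code{strength} (standardized extremum of the classified sign; the
#'   peak-based statistic when unclassified), \code{peak_lag_ms},
#'   \code{significant}, and the per-sign statistics \code{strength_exc},
#'   \code{strength_inh}.
#' @export
classifyEdge <- function(ccg, band) {
  stopifnot(is(ccg, "Correlogram"))
  w <- ccg@counts[ccgStrengthBins]
  lags <- ccg@lags[ccgStrengthBins]
  peak <- max(w); trough <- min(w)
  degenerate_exc <- !is.finite(band$peak_sd) || band$peak_sd == 0
  degenerate_inh <- !is.finite(band$trough_sd) || band$trough_sd == 0
  sExc <- if (degenerate_exc) NA_real_ else (peak - band$peak_mean) / band$peak_sd
  sInh <- if (degenerate_inh) NA_real_ else (trough - band$trough_mean) / band$trough_sd
  excSig <- !degenerate_exc && band$band97_peak_offset > 0 &&
    (peak - band$grand_mean) > 2 * band$band97_peak_offset
  inhSig <- !degenerate_inh && band$band97_trough_offset < 0 &&
    (trough - band$grand_mean) < 2 * band$band97_trough_offset
  if (degenerate_exc && degenerate_inh)
    warning("degenerate surrogate null (zero SD); edge marked none")
  sign <- "none"
  if (excSig && inhSig) sign <- if (abs(sExc) >= abs(sInh)) "excitatory" else "inhibitory"
  else if (excSig) sign <- "excitatory"
  else if (inhSig) sign <- "inhibitory"
  lag <- if (sign == "inhibitory") lags[which.min(w)] else lags[which.max(w)]
  list(sign = sign,
       strength = switch(sign, inhibitory = sInh, sExc),
       peak_lag_ms = lag, significant = sign != "none",
       strength_exc = sExc, strength_inh = sInh)
}

#' Infer the functional network of a raster
#'
#' Applies the cross-correlogram / jitter-null classification to all ordered
#' pairs of eligible neurons (minimum average rate 1 Hz, subsampled to at
#' most 60, seeded). Per-pair surrogate seeds derive deterministically from
#' \code{seed}.
#'
#' @param raster a \code{\linkS4class{SpikeRaster}}.
#' @param seed RNG seed (subsampling and surrogates).
#' @param nSurr surrogates per pair.
#' @param jitter jitter half-width (ms).
#' @param minRate eligibility threshold (Hz).
#' @param maxNeurons subsample size cap.
#' @param eligible optional pre-chosen 0-based neuron ids (overrides the
#'   eligibility filter; used to hold the subsample fixed across conditions).
#' @return a \code{\linkS4class{FunctionalNetwork}}.
#' @export
inferFunctionalNetwork <- function(raster, seed = 1L, nSurr = 100,
                                   jitter = 5, minRate = 1,
                                   maxNeurons = 60, eligible = NULL) {
  stopifnot(is(raster, "SpikeRaster"))
  if (is.null(eligible)) {
    rates <- tabulate(raster@neuron + 1L, raster@nNeurons) /
      (raster@duration / 1000)
    eligible <- which(rates >= minRate) - 1L
    if (length(eligible) > maxNeurons)
      eligible <- withSeed(seed,
        sort(sample(eligible, maxNeurons)))
  }
  eligible <- as.integer(eligible)
  if (length(eligible) < 2) {
    warning("fewer than 2 eligible neurons; returning empty network")
    return(new("FunctionalNetwork",
               edges = data.frame(), eligible = eligible,
               probability = c(excitatory = NA_real_, inhibitory = NA_real_),
               meanStrength = c(excitatory = NA_real_, inhibitory = NA_real_)))
  }
  trains <- spikeTrains(raster, ids = eligible)
  n <- length(eligible)
  np <- n * (n - 1)
  pre <- post <- integer(np)
  sgn <- character(np)
  stren <- lag <- sExcV <- sInhV <- numeric(np)
  sig <- logical(np)
  lagsAll <- ccgLo + ccgBinWidth * (seq_len(ccgNBins) - 0.5)
  k <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    k <- k + 1
    pre[k] <- eligible[i]; post[k] <- eligible[j]
    ref <- trains[[i]]; cmp <- trains[[j]]
    if (!length(ref) || !length(cmp)) {
      sgn[k] <- "none"
      stren[k] <- lag[k] <- sExcV[k] <- sInhV[k] <- NA_real_
      next
    }
    band <- surrogateBand(ref, cmp, nSurr = nSurr, jitter = jitter,
                          seed = deriveSeed(seed, i, j))
    ccg <- new("Correlogram", lags = lagsAll, counts = band$observed,
               binWidth = ccgBinWidth, nRefSpikes = length(ref))
    # degenerate nulls are expected for sparse pairs; they classify as none
    e <- suppressWarnings(classifyEdge(ccg, band))
    sgn[k] <- e$sign
    stren[k] <- e$strength
    lag[k] <- e$peak_lag_ms
    sig[k] <- e$significant
    sExcV[k] <- e$strength_exc
    sInhV[k] <- e$strength_inh
  }
  edges <- data.frame(pre = pre, post = post, sign = sgn, strength = stren,
                      peak_lag_ms = lag, significant = sig,
                      strength_exc = sExcV, strength_inh = sInhV)
  nTested <- nrow(edges)
  excSig <- edges$significant & edges$sign == "excitatory"
  inhSig <- edges$significant & edges$sign == "inhibitory"
  new("FunctionalNetwork", edges = edges, eligible = eligible,
      probability = c(excitatory = sum(excSig) / nTested,
                      inhibitory = sum(inhSig) / nTested),
      meanStrength = c(
        excitatory = if (any(excSig)) mean(edges$strength[excSig]) else NA_real_,
        inhibitory = if (any(inhSig)) mean(edges$strength[inhSig]) else NA_real_))
}

#' Pairwise strength matrix of a functional network
#'
#' @param fn a \code{\linkS4class{FunctionalNetwork}}.
#' @param statistic which standardized statistic fills the matrix:
#'   excitatory (peak-based, the default used for similarity analyses) or
#'   inhibitory (trough-based).
#' @return square matrix over the eligible neurons (NA diagonal).
#' @export
strengthMatrix <- function(fn, statistic = c("excitatory", "inhibitory")) {
  statistic <- match.arg(statistic)
  stopifnot(is(fn, "FunctionalNetwork"))
  ids <- fn@eligible
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  col <- if (statistic == "excitatory") "strength_exc" else "strength_inh"
  e <- fn@edges
  if (nrow(e))
    m[cbind(match(e$pre, ids), match(e$post, ids))] <- e[[col]]
  m
}

#' Cosine similarity of two strength matrices
#'
#' Dot product of the vectorized pairwise strengths over their common
#' defined entries, normalized by the vector norms.
#'
#' @param a,b numeric matrices (or vectors) with matched pair ordering.
#' @return cosine similarity in [-1, 1].
#' @export
cosineSimilarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("matrices must have matched dimensions")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined similarity: zero-norm matrix")
  sum(a * b) / (na * nb)
}

#' Similarity Z-score against a jitter null
#'
#' Standardizes an observed cosine similarity against the similarities of
#' jitter-derived null strength matrices.
#'
#' @param observed observed cosine similarity, or a pair of strength
#'   matrices \code{list(a, b)}.
#' @param nullSimilarities numeric vector of null cosine similarities.
#' @return list with \code{cosine} and \code{z}.
#' @export
similarityZscore <- function(observed, nullSimilarities) {
  cosObs <- if (is.list(observed))
    cosineSimilarity(observed[[1]], observed[[2]]) else as.numeric(observed)
  if (length(nullSimilarities) < 2 || sd(nullSimilarities) == 0)
    stop("null similarity set is degenerate")
  list(cosine = cosObs,
       z = (cosObs - mean(nullSimilarities)) / sd(nullSimilarities))
}
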