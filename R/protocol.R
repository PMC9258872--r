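# Orchestration of the in-silico anesthesia / cholinergic-reversal
# experiment: graded parameter schedules, per-level measures, functional
# networks, and trend statistics.

#' Run an anesthesia or reversal series across network realisations
#'
#' For each of \code{nNetworks} seeds, one topology is built and reused
#' across every level of the series (the network structure is fixed within
#' a run; only the receptor factors and g_Ks change). Each (level, seed)
#' simulation yields a \code{\link{measureSuite}} and, optionally, a
#' functional network inferred on a shared neuron subsample.
#'
#' @param series one of "A", "B", "AR", "BR", or a data.frame of levels in
#'   \code{\link{levelParameters}} layout.
#' @param nNetworks number of network realisations (seeds).
#' @param duration per-level simulated time (ms), including the transient.
#' @param seed base seed; topology and simulation seeds derive from it.
#' @param dt integration step (ms).
#' @param nExc,nInh network size.
#' @param connectivity if TRUE, infer the functional network per (level,
#'   seed).
#' @param nSub,nIntervals,intervalLen measurement protocol (see
#'   \code{\link{measureSuite}}).
#' @param measureSeed seed for subsampling/intervals (shared across levels
#'   so measures are comparable).
#' @param ... further arguments passed to \code{\link{simulateNetwork}}.
#' @return list of class \code{"ExperimentResult"}: \code{measures}
#'   (data.frame, one row per level x seed), \code{suites} (nested list),
#'   \code{networks} (nested list of \code{FunctionalNetwork} or NULL),
#'   \code{rates} (per-neuron rate matrix per seed), \code{levels}.
#' @export
runSeries <- function(series = "A", nNetworks = 3, duration = 20000,
                      seed = 1L, dt = 0.05, nExc = 800, nInh = 200,
                      connectivity = FALSE, measureSeed = 1L,
                      nSub = 60, nIntervals = 3, intervalLen = 6000, ...) {
  levels <- if (is.data.frame(series)) series else levelParameters(series)
  if (!nrow(levels)) stop("empty level table")
  suites <- list(); networks <- list(); rates <- list(); rows <- list()
  for (s in seq_len(nNetworks)) {
    topoSeed <- deriveSeed(seed, 101, s)
    net <- buildNetwork(nExc, nInh, seed = topoSeed)
    simSeed <- deriveSeed(seed, 202, s)
    seedRates <- matrix(NA_real_, nExc + nInh, nrow(levels),
                        dimnames = list(NULL, levels$label))
    elig <- NULL
    for (l in seq_len(nrow(levels))) {
      lev <- as.list(levels[l, ])
      r <- simulateNetwork(net, lev, duration = duration, dt = dt,
                           seed = simSeed, ...)
      ms <- measureSuite(r, nSub = nSub, nIntervals = nIntervals,
                         intervalLen = intervalLen, seed = measureSeed)
      seedRates[, l] <- tabulate(r@neuron + 1L, r@nNeurons) /
        (r@duration / 1000)
      fn <- NULL
      if (connectivity) {
        if (is.null(elig)) {
          # eligibility fixed on the first (reference) level of the series
          rr <- seedRates[, l]
          elig <- which(rr >= 1) - 1L
          if (length(elig) > 60)
            elig <- withSeed(deriveSeed(seed, 303, s), sort(sample(elig, 60)))
        }
        fn <- inferFunctionalNetwork(r, seed = deriveSeed(seed, 404, s, l),
                                     eligible = elig)
      }
      suites[[lev$label]][[s]] <- ms
      networks[[lev$label]][[s]] <- fn
      rows[[length(rows) + 1]] <- data.frame(
        series = lev$series %||% NA_character_, label = lev$label,
        level = lev$level %||% l, network = s,
        mean_rate_hz = ms$mean_rate, mpc = ms$mpc,
        integration_bits = ms$integration, complexity_bits = ms$complexity,
        exc_strength = if (!is.null(fn))
          connectionStrength(fn)[["excitatory"]] else NA_real_,
        exc_probability = if (!is.null(fn))
          connectionProbability(fn)[["excitatory"]] else NA_real_,
        inh_strength = if (!is.null(fn))
          connectionStrength(fn)[["inhibitory"]] else NA_real_,
        inh_probability = if (!is.null(fn))
          connectionProbability(fn)[["inhibitory"]] else NA_real_)
    }
    rates[[s]] <- seedRates
  }
  out <- list(measures = do.call(rbind, rows), suites = suites,
              networks = networks, rates = rates, levels = levels)
  class(out) <- c("ExperimentResult", "list")
  out
}

#' Pearson trend test of a measure against ordinal level
#'
#' Pools all (level, seed) points and computes the Pearson correlation of
#' the measure with the ordinal level index, with the two-sided p-value
#' from the t distribution.
#'
#' @param values measure values.
#' @param levels ordinal level index per value.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @examples
#' correlationTest(c(1, 2, 4), c(0, 1, 2))$r  # ~ 0.982
#' @export
correlationTest <- function(values, levels) {
  ok <- is.finite(values) & is.finite(levels)
  values <- values[ok]; levels <- levels[ok]
  if (length(values) < 3) stop("need at least 3 points")
  if (sd(values) == 0 || sd(levels) == 0)
    stop("undefined correlation: zero variance")
  r <- cor(values, levels)
  n <- length(values)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Per-neuron rate preservation between two conditions
#'
#' Regresses the comparison-condition rates of each neuron on its
#' reference-condition (wake) rates: an ordinary least-squares fit with
#' intercept. A slope below 1 with high correlation means rates scale down
#' while the relative ordering of neurons is preserved.
#'
#' @param ratesRef,ratesCmp per-neuron rate vectors on the same index
#'   space, or two \code{\linkS4class{SpikeRaster}} objects.
#' @return list with \code{slope}, \code{intercept}, \code{r}.
#' @export
ratePreservation <- function(ratesRef, ratesCmp) {
  getRates <- function(x)
    if (is(x, "SpikeRaster"))
      tabulate(x@neuron + 1L, x@nNeurons) / (x@duration / 1000)
    else as.numeric(x)
  xr <- getRates(ratesRef); xc <- getRates(ratesCmp)
  if (length(xr) != length(xc)) stop("rate vectors differ in length")
  if (sd(xr) == 0 || sd(xc) == 0)
    stop("zero-variance rates: preservation undefined")
  fit <- stats::lm.fit(cbind(1, xr), xc)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r = cor(xr, xc))
}

#' Cross-level functional-network similarity matrix
#'
#' Cosine similarities between the excitatory strength matrices of all level
#' pairs of an experiment (averaged over network realisations), plus
#' jitter-null Z-scores: the null set is built per pair from strength
#' matrices recomputed on jittered rasters, or approximated from the
#' supplied null matrices.
#'
#' @param result an \code{"ExperimentResult"} from
#'   \code{\link{runSeries}} run with \code{connectivity = TRUE}.
#' @param nullMatrices optional list of null strength matrices (from
#'   jittered data) used to standardize; without it only cosines are
#'   returned.
#' @return list with \code{cosine} (levels x levels matrix, averaged over
#'   seeds) and \code{z} (same shape, NA without a null).
#' @export
crossLevelSimilarity <- function(result, nullMatrices = NULL) {
  labs <- result$levels$label
  nSeeds <- length(result$rates)
  cosM <- matrix(NA_real_, length(labs), length(labs),
                 dimnames = list(labs, labs))
  nullCos <- NULL
  if (!is.null(nullMatrices) && length(nullMatrices) >= 2) {
    nullCos <- numeric(0)
    for (i in seq_along(nullMatrices)) for (j in seq_along(nullMatrices)) {
      if (i < j)
        nullCos <- c(nullCos,
                     cosineSimilarity(nullMatrices[[i]], nullMatrices[[j]]))
    }
  }
  zM <- cosM
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    vals <- vapply(seq_len(nSeeds), function(s) {
      fa <- result$networks[[labs[i]]][[s]]
      fb <- result$networks[[labs[j]]][[s]]
      if (is.null(fa) || is.null(fb)) return(NA_real_)
      cosineSimilarity(strengthMatrix(fa), strengthMatrix(fb))
    }, numeric(1))
    cosM[i, j] <- mean(vals, na.rm = TRUE)
    if (!is.null(nullCos) && length(nullCos) >= 2 && sd(nullCos) > 0)
      zM[i, j] <- (cosM[i, j] - mean(nullCos)) / sd(nullCos)
  }
  list(cosine = cosM, z = zM)
}

#' Paired t-tests against a reference level with Bonferroni alpha
#'
#' Helper for the per-level significance pattern: paired t-tests of each
#' non-reference level against the reference across network realisations,
#' compared to a Bonferroni-corrected alpha.
#'
#' @param result an \code{"ExperimentResult"}.
#' @param measure column of \code{result$measures} to test.
#' @param reference reference level label (default: first level).
#' @param alpha corrected significance threshold (0.0167 for four anesthetic
#'   levels, 0.0125 for five reversal states).
#' @return data.frame with label, mean difference, p, significant.
#' @export
pairedLevelTests <- function(result, measure = "mean_rate_hz",
                             reference = NULL, alpha = 0.0167) {
  m <- result$measures
  labs <- unique(m$label)
  if (is.null(reference)) reference <- labs[1]
  ref <- m[m$label == reference, ]
  out <- lapply(setdiff(labs, reference), function(lab) {
    cmp <- m[m$label == lab, ]
    shared <- intersect(ref$network, cmp$network)
    x <- ref[match(shared, ref$network), measure]
    y <- cmp[match(shared, cmp$network), measure]
    p <- if (length(shared) >= 2 && sd(y - x) > 0)
      stats::t.test(y, x, paired = TRUE)$p.value else NA_real_
    data.frame(label = lab, diff = mean(y - x), p = p,
               significant = !is.na(p) & p < alpha)
  })
  do.call(rbind, out)
}
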