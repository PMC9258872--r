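# Differential-evolution fitting of the synaptic scaling factors and the
# M-current conductance to target network measures.

deParamNames <- c("P_NMDA", "P_GABA", "P_AMPA", "g_Ks")

#' Relative-error cost between simulated and target measures
#'
#' \deqn{L = \sum_x ((x_{exp} - x_{sim}) / x_{exp})^2} over the four fitted
#' measures: mean firing frequency, mean phase coherence, integration and
#' complexity.
#'
#' @param sim,target lists (or \code{\link{measureSuite}} outputs) with
#'   elements mean_rate, mpc, integration, complexity. All target values
#'   must be non-zero.
#' @return list with \code{L} (total cost) and \code{breakdown} (named
#'   per-measure terms).
#' @examples
#' t <- list(mean_rate = 10, mpc = 0.3, integration = 2, complexity = 1)
#' measureCost(t, t)$L  # 0 at a perfect fit
#' @export
measureCost <- function(sim, target) {
  keys <- c("mean_rate", "mpc", "integration", "complexity")
  xe <- unlist(target[keys]); xs <- unlist(sim[keys])
  if (any(!is.finite(xe)) || any(xe == 0))
    stop("target measures must be finite and non-zero")
  m <- ((xe - xs) / xe)^2
  names(m) <- keys
  list(L = sum(m), breakdown = m)
}

# Evaluate a parameter matrix, returning cost vector + breakdown matrix.
evalAgents <- function(agents, evaluate) {
  res <- apply(agents, 1, evaluate)
  if (is.list(res)) {
    cost <- vapply(res, function(r) r$L, numeric(1))
    brk <- t(vapply(res, function(r) r$breakdown, numeric(4)))
  } else {
    cost <- as.numeric(res)
    brk <- matrix(NA_real_, length(cost), 4)
  }
  colnames(brk) <- c("mean_rate", "mpc", "integration", "complexity")
  list(cost = cost, breakdown = brk)
}

newDEPopulation <- function(agents, evaluate) {
  colnames(agents) <- deParamNames
  ev <- evalAgents(agents, evaluate)
  new("DEPopulation", agents = agents, cost = ev$cost,
      breakdown = ev$breakdown, generation = 0L,
      bestHistory = min(ev$cost))
}

#' Seed the 30-agent population for one anesthetic level
#'
#' The 0 percent level starts from the 256-point grid scan (P_AMPA, P_NMDA
#' in {0.5, 1, 1.5, 2}, P_GABA in {2.5, 5, 7.5, 10.5}, g_Ks in {0.3, 0.7,
#' 1.1, 1.5} mS/cm^2). The 6 percent
#' level anchors at the wake fit altered by the reported mean synaptic
#' effects of deep anesthesia (20 percent NMDA decrease, 40 percent GABA
#' increase), perturbed +/- 5 percent. The 2 / 4 percent levels seed from
#' the neighbouring fitted population. In all cases the population is then
#' refreshed by the keep-20 / perturb-10-percent / construct-10 scheme of
#' \code{\link{deGeneration}}.
#'
#' @param evaluate function(params named numeric) -> cost list (see
#'   \code{\link{measureCost}}) or a bare number.
#' @param level anesthetic level in percent: one of 0, 2, 4, 6.
#' @param neighbour a fitted \code{\linkS4class{DEPopulation}} (required for
#'   levels 2 and 4), or the wake best agent (required for level 6: a named
#'   vector or \code{bestAgent} output).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{DEPopulation}} of 30 agents.
#' @export
seedPopulation <- function(evaluate, level, neighbour = NULL, seed = 1L) {
  if (!level %in% c(0, 2, 4, 6)) stop("level must be one of 0, 2, 4, 6")
  withSeed(seed, {
    if (level == 0) {
      grid <- as.matrix(expand.grid(P_NMDA = c(0.5, 1, 1.5, 2),
                                    P_GABA = c(2.5, 5, 7.5, 10.5),
                                    P_AMPA = c(0.5, 1, 1.5, 2),
                                    g_Ks = c(0.3, 0.7, 1.1, 1.5)))
      agents <- grid[, deParamNames]
    } else if (level == 6) {
      if (is.list(neighbour)) neighbour <- neighbour$params
      if (is.null(neighbour) || !all(deParamNames %in% names(neighbour)))
        stop("level 6 seeding needs the wake-fit parameters")
      anchor <- neighbour[deParamNames]
      anchor["P_NMDA"] <- anchor["P_NMDA"] * 0.8
      anchor["P_GABA"] <- anchor["P_GABA"] * 1.4
      agents <- t(vapply(1:30, function(i)
        anchor * runif(4, 0.95, 1.05), numeric(4)))
      colnames(agents) <- deParamNames
    } else {
      if (!is(neighbour, "DEPopulation"))
        stop("levels 2 and 4 seed from a neighbouring fitted population")
      agents <- neighbour@agents
    }
    # population refresh: keep the 20 lowest-cost sets, perturb each
    # parameter uniformly by 10 percent of its value (avoiding duplicates),
    # and construct the final 10 by the differential-evolution recipe
    ev <- evalAgents(agents, evaluate)
    kept <- agents[order(ev$cost)[seq_len(min(20, nrow(agents)))], ,
                   drop = FALSE]
    kept <- kept * matrix(runif(length(kept), 0.9, 1.1), nrow(kept))
    off <- matrix(NA_real_, 10, 4, dimnames = list(NULL, deParamNames))
    for (kk in 1:10) {
      a <- kept[sample.int(nrow(kept), 1), ]
      bcd <- kept[sample.int(nrow(kept), 3), , drop = FALSE]
      DW <- runif(1, 0, 2)
      e <- a
      for (i in 1:4) if (runif(1) < 0.8)
        e[i] <- bcd[1, i] + DW * (bcd[2, i] - bcd[3, i])
      off[kk, ] <- pmax(e, 1e-6)
    }
    newDEPopulation(rbind(kept, off), evaluate)
  })
}

#' One differential-evolution generation
#'
#' The 10 highest-cost agents are discarded. From the 20 survivors, 10 base
#' agents a are drawn; for each, three further distinct survivors b, c, d
#' are chosen and an offspring e is built element-wise: with probability CR,
#' \eqn{e_i = b_i + DW (c_i - d_i)} (DW drawn once per offspring, uniform on
#' [0, dwMax]), otherwise \eqn{e_i = a_i}. Elements not in \code{free} are
#' copied from a (frozen parameters). Offspring parameters are clipped to be
#' positive. The new agents are evaluated and join the survivors.
#'
#' @param pop a \code{\linkS4class{DEPopulation}}.
#' @param evaluate cost function (see \code{\link{seedPopulation}}).
#' @param CR crossover probability.
#' @param dwMax upper bound of the uniform differential-weight draw.
#' @param free names of parameters allowed to vary.
#' @param seed RNG seed for this generation.
#' @return the advanced \code{\linkS4class{DEPopulation}}.
#' @export
deGeneration <- function(pop, evaluate, CR = 0.8, dwMax = 2,
                         free = deParamNames, seed = 1L) {
  stopifnot(is(pop, "DEPopulation"))
  nPop <- nrow(pop@agents)
  nReplace <- min(10L, nPop - 4L)
  if (nPop - nReplace < 4) stop("fewer than 4 distinct survivors")
  withSeed(seed, {
    keep <- order(pop@cost)[seq_len(nPop - nReplace)]
    surv <- pop@agents[keep, , drop = FALSE]
    freeIdx <- match(intersect(free, deParamNames), deParamNames)
    off <- matrix(NA_real_, nReplace, 4, dimnames = list(NULL, deParamNames))
    for (kk in seq_len(nReplace)) {
      a <- surv[sample.int(nrow(surv), 1), ]
      bcd <- surv[sample.int(nrow(surv), 3), , drop = FALSE]
      DW <- runif(1, 0, dwMax)
      e <- a
      for (i in freeIdx) {
        if (runif(1) < CR) e[i] <- bcd[1, i] + DW * (bcd[2, i] - bcd[3, i])
      }
      off[kk, ] <- pmax(e, 1e-6)
    }
    ev <- evalAgents(off, evaluate)
    agents <- rbind(surv, off)
    cost <- c(pop@cost[keep], ev$cost)
    brk <- rbind(pop@breakdown[keep, , drop = FALSE], ev$breakdown)
    new("DEPopulation", agents = agents, cost = cost, breakdown = brk,
        generation = pop@generation + 1L,
        bestHistory = c(pop@bestHistory, min(cost)))
  })
}

#' Fit one anesthetic level by differential evolution
#'
#' Iterates \code{\link{deGeneration}} until the lowest cost has not
#' improved for \code{stagnation} generations (or \code{maxGenerations} is
#' reached, in which case the result is flagged as partial). In the
#' A-series, levels above 0 percent vary only P_NMDA and P_GABA (P_AMPA and
#' g_Ks stay at their wake values); the B-series additionally frees g_Ks.
#' P_AMPA is only ever fitted at the wake level.
#'
#' @param evaluate cost function (see \code{\link{seedPopulation}}).
#' @param level anesthetic level in percent (0, 2, 4, 6).
#' @param series "A" or "B".
#' @param neighbour seeding input (see \code{\link{seedPopulation}}).
#' @param stagnation stopping criterion: generations without improvement.
#' @param maxGenerations hard budget.
#' @param CR,dwMax evolution settings.
#' @param seed RNG seed.
#' @return list with \code{best} (see \code{\link{bestAgent}}),
#'   \code{population}, \code{history} (best cost per generation),
#'   \code{converged}.
#' @export
fitLevel <- function(evaluate, level, series = c("A", "B"),
                     neighbour = NULL, stagnation = 100,
                     maxGenerations = 1000, CR = 0.8, dwMax = 2,
                     seed = 1L) {
  series <- match.arg(series)
  free <- if (level == 0) deParamNames
          else if (series == "A") c("P_NMDA", "P_GABA")
          else c("P_NMDA", "P_GABA", "g_Ks")
  pop <- seedPopulation(evaluate, level, neighbour,
                        seed = deriveSeed(seed, 1))
  stale <- 0L
  gen <- 0L
  while (stale < stagnation && gen < maxGenerations) {
    prevBest <- min(pop@cost)
    pop <- deGeneration(pop, evaluate, CR = CR, dwMax = dwMax, free = free,
                        seed = deriveSeed(seed, 2 + gen))
    gen <- gen + 1L
    stale <- if (min(pop@cost) < prevBest - 1e-12) 0L else stale + 1L
  }
  list(best = bestAgent(pop), population = pop,
       history = pop@bestHistory, converged = stale >= stagnation)
}

#' Build a simulator-backed cost function for fitting
#'
#' Returns an \code{evaluate} closure for \code{\link{fitLevel}} that
#' simulates the network at a candidate parameter set (fixed topology, fixed
#' seed so agent ranking is consistent) and scores it against target
#' measures.
#'
#' @param topology a \code{\linkS4class{NetworkTopology}} held fixed across
#'   the fit.
#' @param target target measures (list with mean_rate, mpc, integration,
#'   complexity).
#' @param duration evaluation simulation length (ms).
#' @param dt integration step (ms).
#' @param seed simulation and measurement seed.
#' @param ... further arguments passed to \code{\link{simulateNetwork}}.
#' @return function(params) -> \code{\link{measureCost}} output.
#' @export
simulatorCost <- function(topology, target, duration = 20000, dt = 0.05,
                          seed = 1L, ...) {
  extra <- list(...)
  function(params) {
    level <- as.list(params[deParamNames])
    level$label <- "fit"
    r <- do.call(simulateNetwork,
                 c(list(topology = topology, level = level,
                        duration = duration, dt = dt, seed = seed), extra))
    nSub <- min(60L, nNeurons(topology))
    ms <- measureSuite(r, nSub = nSub,
                       nIntervals = max(1L, min(3L, floor(r@duration / 6000))),
                       seed = seed)
    measureCost(ms, target)
  }
}
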