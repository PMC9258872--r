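#' The packaged anesthesia / reversal parameter schedule
#'
#' Best-fit receptor scaling factors (P_NMDA, P_GABA, P_AMPA) and M-current
#' conductance (g_Ks) per condition: the A-series (anesthetic levels 0, 2,
#' 4, 6 percent desflurane with cholinergic tone held fixed), the B-series
#' (g_Ks co-fitted per level), and the AR/BR reversal schedules that keep
#' the deepest-level synaptic factors while stepping g_Ks down to 0.40
#' mS/cm^2.
#'
#' @param series optional subset: one or more of "A", "B", "AR", "BR".
#' @return data.frame with columns series, level, label, P_NMDA, P_GABA,
#'   P_AMPA, g_Ks.
#' @examples
#' levelParameters("A")
#' @export
levelParameters <- function(series = NULL) {
  path <- system.file("extdata", "level_parameters.csv", package = "anesnet")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(series)) {
    bad <- setdiff(series, unique(tab$series))
    if (length(bad)) stop("unknown series: ", paste(bad, collapse = ", "))
    tab <- tab[tab$series %in% series, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

# Default run configuration: every tunable of the model with its default.
defaultRunConfig <- function() {
  list(
    neuron = unclass(neuronParams()),
    synapse = unclass(synapseParams()),
    network = list(n_exc = 800L, n_inh = 200L, p_conn = 0.1,
                   weight_mu = -20.0, weight_theta = 9.4),
    simulation = list(duration_ms = 20000, dt_ms = 0.05,
                      transient_ms = 1000, w_cap = 0.22,
                      weight_scale = 1, gKs_inh = 0),
    measures = list(n_sub = 60L, n_intervals = 3L, interval_len_ms = 6000,
                    bin_width_ms = 1),
    connectivity = list(n_surrogates = 100L, jitter_ms = 5, min_rate_hz = 1,
                        max_neurons = 60L),
    fit = list(population = 30L, cr = 0.8, dw_max = 2,
               stagnation_generations = 100L, eval_duration_ms = 20000),
    seed = 1L)
}

#' Read a run configuration
#'
#' Loads a YAML configuration, filling unset keys from the package defaults
#' (which equal the published model constants). Unknown sections or keys are
#' rejected so that typos cannot silently fall back to defaults.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  badSec <- setdiff(names(user), c(names(cfg)))
  if (length(badSec)) stop("unknown config section(s): ",
                           paste(badSec, collapse = ", "))
  for (sec in names(user)) {
    if (!is.list(cfg[[sec]])) { cfg[[sec]] <- user[[sec]]; next }
    badKey <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(badKey)) stop("unknown key(s) in section '", sec, "': ",
                             paste(badKey, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

#' Write a fully-resolved run configuration
#'
#' @param config nested configuration list (see \code{\link{readRunConfig}}).
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
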