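#' Read a scenario configuration file
#'
#' YAML (or JSON) scenario configuration of the form
#' ```
#' model: chain | fmo | werner | discard
#' parameters:            # model-specific, all optional
#'   J12: 1, J23: 1, gamma: 0.01          # chain
#'   T_kelvin: 15, sink_rate: 5.3         # fmo
#'   p: 0.8                               # werner
#' measured_site: 1
#' target_site: 3
#' measurement_set: pauli
#' time_grid: {start: 0, stop: 10, steps: 100}
#' measure: weight | robustness
#' ```
#' The measured site is fixed by the model (qubit 1 for the chain, site 6
#' for the FMO complex); `measurement_set` currently supports `pauli`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A list with elements `scenario`, `times` and `measure`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$measurement_set) &&
      !identical(tolower(cfg$measurement_set), "pauli")) {
    stop("only the Pauli X, Y, Z measurement set is supported",
         call. = FALSE)
  }
  pars <- cfg$parameters %||% list()
  sc <- switch(
    cfg$model %||% stop("config needs a `model` field", call. = FALSE),
    chain = three_qubit_chain_scenario(
      J12 = pars$J12 %||% 1, J23 = pars$J23 %||% 1,
      gamma = pars$gamma %||% 0,
      target = cfg$target_site %||% 3
    ),
    fmo = fmo_scenario(
      target_site = cfg$target_site %||% 5,
      T_kelvin = pars$T_kelvin %||% 15,
      sink_rate = pars$sink_rate %||% 5.3
    ),
    werner = werner_scenario(pars$p %||% 1),
    discard = discard_channel_scenario(
      rho_fixed = if (is.null(pars$bloch)) diag(2) / 2
                  else bloch_state(unlist(pars$bloch))
    ),
    stop("unknown model: ", cfg$model, call. = FALSE)
  )
  tg <- cfg$time_grid %||% list(start = 0, stop = 1, steps = 11)
  if ((tg$start %||% 0) != 0) {
    stop("time grids must start at 0", call. = FALSE)
  }
  times <- seq(0, tg$stop, length.out = tg$steps)
  list(scenario = sc, times = times,
       measure = cfg$measure %||% "weight")
}
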