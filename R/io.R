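#' Read a simulation configuration
#'
#' YAML or JSON file with a `mode` field
#' (`vasomotion_macro`, `vasomotion_cellular`, `fh_impulse`, `fh_step`,
#' `myography`, `voltage_clamp`) plus mode-specific fields; unknown fields
#' are passed through to the corresponding runner.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @return A named list.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$mode)) abort("Simulation config needs a `mode` field.")
  cfg
}

#' Run a simulation described by a configuration list
#'
#' Dispatches on `config$mode` to the corresponding runner with the
#' default network (or one loaded from `config$network`).
#'
#' @param config A list from [read_sim_config()].
#' @return The runner's result object.
#' @export
run_simulation <- function(config) {
  net <- if (!is.null(config$network)) read_network(config$network) else
    build_network(network_config())
  mode <- config$mode
  if (mode == "vasomotion_macro") {
    mp <- do.call(macro_params, config$macro_params %||% list())
    simulate_vasomotion(net, params = mp,
                        duration = config$duration %||% 600,
                        abnp = config$abnp %||% 60,
                        vbnp = config$vbnp %||% 10,
                        record = config$record %||% "pa10",
                        freeze_pd_at = config$freeze_pd_at %||% Inf)
  } else if (mode %in% c("vasomotion_cellular", "fh_impulse", "fh_step")) {
    cp <- do.call(cellular_params, config$cellular_params %||% list())
    proto <- NULL
    if (mode != "vasomotion_cellular") {
      pargs <- config$protocol %||% list()
      pargs$kind <- if (mode == "fh_impulse") "impulse" else "step"
      proto <- do.call(stimulus_protocol, pargs)
    }
    simulate_cellular_pa(net, pa = config$pa %||% 1, params = cp,
                         duration = config$duration %||% 60,
                         protocol = proto,
                         gap_junctions = config$gap_junctions %||% TRUE,
                         init = if (mode == "vasomotion_cellular") "onset" else "baseline",
                         abnp = config$abnp %||% 60,
                         vbnp = config$vbnp %||% 10)
  } else if (mode == "myography") {
    cp <- do.call(cellular_params, config$cellular_params %||% list())
    myography_mt(config$ip_steps %||% seq(5, 95, by = 10), params = cp)
  } else if (mode == "voltage_clamp") {
    cp <- do.call(cellular_params, config$cellular_params %||% list())
    run_voltage_clamp(config$v_grid %||% seq(-100, 40, by = 2),
                      ip = config$ip %||% 30, params = cp)
  } else {
    abort(sprintf("Unknown simulation mode '%s'.", mode))
  }
}

#' Export a simulation trace to CSV
#'
#' Long-format CSV with floats at 9 significant digits.
#'
#' @param sim A `vd_sim` / `vd_cell_sim` (or any tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  tr <- if (is.data.frame(sim)) sim else sim$trace
  tr <- dplyr::mutate(tr, dplyr::across(dplyr::where(is.numeric),
                                        ~ signif(.x, 9)))
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' Export a metrics report to JSON
#'
#' @param report A `vd_report`, `vd_metrics`, or plain named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
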