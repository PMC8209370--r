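# Front end to the compiled AdEx integrator.

#' Simulation configuration
#'
#' @param dt integration step (ms), > 0; fixed-step forward Euler
#' @param v_init initial membrane potential (mV); `NULL` means "start at the
#'   leak reversal potential E_L", the standard resting initialization
#' @param w_init initial adaptation current (pA)
#' @param exp_clip cap on the dimensionless exponential argument
#'   (V - V_T)/Delta_T before exponentiation; prevents overflow during the
#'   upward spike stroke without changing spike timing at dt resolution
#' @param record_traces record V and w at every step?
#' @return a `simulation_config` object
#' @export
simulation_config <- function(dt = 0.1, v_init = NULL, w_init = 0,
                              exp_clip = 30, record_traces = FALSE) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(exp_clip) || exp_clip <= 0) stop("exp_clip must be > 0")
  structure(list(dt = dt, v_init = v_init, w_init = w_init,
                 exp_clip = exp_clip, record_traces = isTRUE(record_traces)),
            class = "simulation_config")
}

#' Simulate the AdEx neuron under a stimulation protocol
#'
#' Integrates the two AdEx state equations with fixed-step forward Euler at
#' resolution `config$dt` (ms) from t = 0 to the end of the stimulus window,
#' applying the reset rule (V -> V_r, w -> w + b) and recording a spike
#' whenever V exceeds V_peak at a step. The run is fully deterministic:
#' identical inputs give bit-identical outputs.
#'
#' A non-finite state flags the result as diverged and stops the run
#' without raising; downstream scoring treats diverged candidates with a
#' finite penalty.
#'
#' @param params an `adex_parameters` object
#' @param protocol an `adex_protocol`
#' @param config a `simulation_config`
#' @return an `adex_simulation`: list with `spike_times` (s, strictly
#'   increasing), `diverged` (logical) and, if requested, `trace`
#'   (data.frame time_ms, V_mV, w_pA)
#' @export
#' @examples
#' p <- example_parameters(1)
#' sim <- simulate_adex(p, step_protocol(16, 1))
#' length(sim$spike_times)
simulate_adex <- function(params, protocol, config = simulation_config()) {
  params <- as_adex_parameters(params)
  stopifnot(inherits(protocol, "adex_protocol"),
            inherits(config, "simulation_config"))
  v0 <- if (is.null(config$v_init)) params[["E_L"]] else config$v_init
  res <- adex_simulate_cpp(
    unclass(params)[.adex_param_names],
    kind = if (protocol$kind == "step") 0L else 1L,
    amplitude = protocol$amplitude, offset = protocol$offset,
    frequency = protocol$frequency,
    phase0 = protocol$phase_deg * pi / 180,
    onset_s = protocol$onset, duration_s = protocol$duration,
    dt_ms = config$dt, v_init = v0, w_init = config$w_init,
    exp_clip = config$exp_clip, record = config$record_traces)
  res$protocol_id <- protocol$id
  class(res) <- "adex_simulation"
  res
}

#' @export
print.adex_simulation <- function(x, ...) {
  cat(sprintf("AdEx simulation [%s]: %d spikes%s\n", x$protocol_id,
              length(x$spike_times),
              if (isTRUE(x$diverged)) " (DIVERGED)" else ""))
  invisible(x)
}

#' Write recorded traces as two-column CSV files
#'
#' @param sim an `adex_simulation` run with `record_traces = TRUE`
#' @param v_path output path for the (time_ms, V_mV) table
#' @param w_path optional output path for the (time_ms, w_pA) table
#' @return invisibly, the trace data.frame
#' @export
write_trace_csv <- function(sim, v_path, w_path = NULL) {
  if (is.null(sim$trace)) stop("simulation was run without record_traces")
  write.csv(sim$trace[, c("time_ms", "V_mV")], v_path, row.names = FALSE)
  if (!is.null(w_path))
    write.csv(sim$trace[, c("time_ms", "w_pA")], w_path, row.names = FALSE)
  invisible(sim$trace)
}
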