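# Spike-train features: mean firing frequency and first-spike latency under
# step currents, per-cycle burst frequency under sinusoidal stimulation.

#' Mean firing frequency over a window
#'
#' Number of spikes falling in `[window[1], window[2])` divided by the
#' window length.
#'
#' @param spike_times spike times (s)
#' @param window numeric length-2 interval (s), positive length
#' @return frequency in Hz
#' @export
mean_frequency <- function(spike_times, window) {
  stopifnot(length(window) == 2)
  len <- window[2] - window[1]
  if (!is.finite(len) || len <= 0) stop("window must have positive length")
  sum(spike_times >= window[1] & spike_times < window[2]) / len
}

#' First-spike latency
#'
#' Time from stimulus onset to the first spike at or after onset. When the
#' train holds no such spike the full stimulus `duration` is returned as a
#' documented sentinel, so that non-spiking candidates incur a finite,
#' proportional latency penalty during scoring.
#'
#' @param spike_times spike times (s)
#' @param onset stimulus onset (s)
#' @param duration stimulus duration (s), the no-spike sentinel value
#' @return latency in seconds
#' @export
first_spike_latency <- function(spike_times, onset, duration) {
  stopifnot(onset >= 0)
  s <- spike_times[spike_times >= onset]
  if (!length(s)) return(duration)
  s[1] - onset
}

#' Consecutive cycle windows of a sinusoidal protocol
#'
#' Partitions the start of the stimulus into `n_cycles` abutting windows of
#' one stimulation period each, beginning at the analysis onset (default:
#' stimulus onset).
#'
#' @param protocol a sinusoidal `adex_protocol`
#' @param n_cycles number of cycles to analyze (default 10)
#' @param analysis_onset start of the first window (s); default the
#'   protocol onset
#' @return data.frame with columns `cycle`, `start`, `end` (s)
#' @export
#' @examples
#' cycle_windows(sinusoid_protocol(6, 12, 10, 22.5))  # ten 0.1-s windows
cycle_windows <- function(protocol, n_cycles = 10, analysis_onset = NULL) {
  stopifnot(inherits(protocol, "adex_protocol"))
  if (protocol$kind != "sinusoid")
    stop("cycle windows require a sinusoidal protocol")
  if (is.null(analysis_onset)) analysis_onset <- protocol$onset
  period <- 1 / protocol$frequency
  end_needed <- analysis_onset - protocol$onset + n_cycles * period
  if (end_needed > protocol$duration + 1e-9)
    stop(sprintf("stimulus too short: %d cycles at %g Hz need %g s, have %g s",
                 n_cycles, protocol$frequency, end_needed, protocol$duration))
  starts <- analysis_onset + (seq_len(n_cycles) - 1) * period
  data.frame(cycle = seq_len(n_cycles), start = starts, end = starts + period)
}

#' Burst frequency within one stimulation cycle
#'
#' The inverse of the mean inter-spike interval (ISI) of the spikes falling
#' inside the window. Cycles holding one or no spike have no ISI and are
#' assigned a burst frequency of zero, mirroring how resonance measurements
#' treat silent cycles. Only ISIs between in-window spikes are used; ISIs
#' straddling the window edge are excluded.
#'
#' @param spike_times spike times (s)
#' @param window numeric length-2 interval (s), `[start, end)`
#' @return burst frequency in Hz; `(k - 1) / (t_k - t_1)` for `k >= 2`
#'   in-window spikes, else 0
#' @export
burst_frequency_cycle <- function(spike_times, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  s <- spike_times[spike_times >= window[1] & spike_times < window[2]]
  k <- length(s)
  if (k <= 1) return(0)
  1 / mean(diff(s))
}

#' Extract the full behavioral feature set of a candidate
#'
#' Simulates the candidate once per protocol and computes: per step
#' stimulus, the mean firing frequency (Hz) and first-spike latency (s);
#' per sinusoidal condition, the per-cycle burst frequencies over
#' `n_cycles` consecutive stimulation cycles, their mean and their
#' population standard deviation (Hz). The extraction is a pure function of
#' (params, suite, config). If any simulation diverges, the feature set is
#' flagged invalid.
#'
#' @param params an `adex_parameters` object
#' @param suite a `protocol_suite` holding at least one step and one
#'   sinusoidal protocol
#' @param config a `simulation_config`
#' @param n_cycles number of sinusoidal cycles analyzed (default 10)
#' @return a `feature_set`: list with data.frames `steps` (protocol_id,
#'   amplitude_pA, mean_frequency_Hz, latency_s), `sinusoids` (protocol_id,
#'   amplitude_pA, frequency_Hz, burst_mean_Hz, burst_sd_Hz), the per-cycle
#'   frequencies in `cycles` (named list), and `valid` (logical)
#' @export
extract_features <- function(params, suite, config = simulation_config(),
                             n_cycles = 10) {
  stopifnot(inherits(suite, "protocol_suite"))
  kinds <- vapply(suite, `[[`, character(1), "kind")
  if (!any(kinds == "step") || !any(kinds == "sinusoid"))
    stop("suite must contain at least one step and one sinusoidal protocol")

  valid <- TRUE
  n_step <- sum(kinds == "step"); n_sin <- sum(kinds == "sinusoid")
  steps <- data.frame(protocol_id = character(n_step),
                      amplitude_pA = numeric(n_step),
                      mean_frequency_Hz = numeric(n_step),
                      latency_s = numeric(n_step),
                      stringsAsFactors = FALSE)
  sins <- data.frame(protocol_id = character(n_sin),
                     amplitude_pA = numeric(n_sin),
                     frequency_Hz = numeric(n_sin),
                     burst_mean_Hz = numeric(n_sin),
                     burst_sd_Hz = numeric(n_sin),
                     stringsAsFactors = FALSE)
  cycles <- vector("list", n_sin)

  i_step <- 0L; i_sin <- 0L
  for (p in suite) {
    sim <- simulate_adex(params, p, config)
    if (isTRUE(sim$diverged)) valid <- FALSE
    if (p$kind == "step") {
      i_step <- i_step + 1L
      steps$protocol_id[i_step] <- p$id
      steps$amplitude_pA[i_step] <- p$amplitude
      steps$mean_frequency_Hz[i_step] <-
        mean_frequency(sim$spike_times, c(p$onset, p$onset + p$duration))
      steps$latency_s[i_step] <-
        first_spike_latency(sim$spike_times, p$onset, p$duration)
    } else {
      i_sin <- i_sin + 1L
      win <- cycle_windows(p, n_cycles)
      bf <- vapply(seq_len(nrow(win)), function(k)
        burst_frequency_cycle(sim$spike_times, c(win$start[k], win$end[k])),
        numeric(1))
      sins$protocol_id[i_sin] <- p$id
      sins$amplitude_pA[i_sin] <- p$amplitude
      sins$frequency_Hz[i_sin] <- p$frequency
      sins$burst_mean_Hz[i_sin] <- mean(bf)
      sins$burst_sd_Hz[i_sin] <- pop_sd(bf)
      cycles[[i_sin]] <- bf
    }
  }
  names(cycles) <- sins$protocol_id
  structure(list(steps = steps, sinusoids = sins, cycles = cycles,
                 valid = valid),
            class = "feature_set")
}

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature set", if (!x$valid) "(INVALID: simulation diverged)", "\n")
  cat("Step responses:\n"); print(x$steps, row.names = FALSE)
  cat("Sinusoidal responses:\n"); print(x$sinusoids, row.names = FALSE)
  invisible(x)
}

#' Flatten a feature set to a tidy table
#'
#' One row per (protocol, feature): columns `protocol_id`, `feature`,
#' `value`, `units`. This is the flat form used by the CSV/JSON interfaces
#' and by reference files.
#'
#' @param fs a `feature_set`
#' @return a data.frame
#' @export
feature_set_to_table <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  rbind(
    data.frame(protocol_id = fs$steps$protocol_id, feature = "mean_frequency",
               value = fs$steps$mean_frequency_Hz, units = "Hz",
               stringsAsFactors = FALSE),
    data.frame(protocol_id = fs$steps$protocol_id,
               feature = "first_spike_latency",
               value = fs$steps$latency_s, units = "s",
               stringsAsFactors = FALSE),
    data.frame(protocol_id = fs$sinusoids$protocol_id,
               feature = "burst_frequency",
               value = fs$sinusoids$burst_mean_Hz, units = "Hz",
               stringsAsFactors = FALSE)
  )
}
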