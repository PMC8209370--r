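# Stimulation protocols: injected-current descriptions evaluated lazily,
# both by the R helper stimulus_current() and inside the C++ integrator.

#' Build a step-current stimulation protocol
#'
#' @param amplitude step amplitude (pA)
#' @param duration stimulus duration (s), > 0
#' @param onset stimulus onset (s), >= 0
#' @param id optional protocol identifier; autogenerated when NULL
#' @return an `adex_protocol` object
#' @export
#' @examples
#' step_protocol(10, 1)   # 10 pA for 1 s
step_protocol <- function(amplitude, duration, onset = 0, id = NULL) {
  if (!is.finite(amplitude)) stop("invalid protocol: amplitude must be finite")
  if (!is.finite(duration) || duration <= 0)
    stop("invalid protocol: duration must be > 0")
  if (onset < 0) stop("invalid protocol: onset must be >= 0")
  if (is.null(id)) id <- sprintf("step_%gpA", amplitude)
  structure(list(kind = "step", amplitude = amplitude, offset = 0,
                 frequency = 0, phase_deg = 0,
                 duration = duration, onset = onset, id = id),
            class = "adex_protocol")
}

#' Build a sinusoidal-current stimulation protocol
#'
#' The injected current is
#' \eqn{I(t) = offset + amplitude \cdot \sin(2\pi f (t - onset) + \phi_0)}
#' inside the stimulus window and 0 outside. The phase convention is that the
#' sine starts at `phase_deg` degrees at stimulus onset (default 0, so
#' I(onset) = offset).
#'
#' @param amplitude oscillation amplitude (pA)
#' @param offset constant offset (pA)
#' @param frequency oscillation frequency (Hz), > 0
#' @param duration stimulus duration (s), > 0
#' @param onset stimulus onset (s)
#' @param phase_deg phase at onset, in degrees
#' @param id optional protocol identifier
#' @return an `adex_protocol` object
#' @export
#' @examples
#' sinusoid_protocol(6, 12, 10, 22.5)  # 6 pA around a 12 pA offset at 10 Hz
sinusoid_protocol <- function(amplitude, offset, frequency, duration,
                              onset = 0, phase_deg = 0, id = NULL) {
  if (!is.finite(frequency) || frequency <= 0)
    stop("invalid protocol: frequency must be > 0")
  if (!is.finite(duration) || duration <= 0)
    stop("invalid protocol: duration must be > 0")
  if (onset < 0) stop("invalid protocol: onset must be >= 0")
  if (is.null(id)) id <- sprintf("sin_%gpA_%gHz", amplitude, frequency)
  structure(list(kind = "sinusoid", amplitude = amplitude, offset = offset,
                 frequency = frequency, phase_deg = phase_deg,
                 duration = duration, onset = onset, id = id),
            class = "adex_protocol")
}

#' Evaluate the injected current of a protocol at given times
#'
#' Pure, deterministic evaluation of I(t); zero outside the stimulus window.
#'
#' @param protocol an `adex_protocol`
#' @param t time(s) in seconds, >= 0 (vectorized)
#' @return current in pA, same length as `t`
#' @export
stimulus_current <- function(protocol, t) {
  stopifnot(inherits(protocol, "adex_protocol"), all(t >= 0))
  on <- t >= protocol$onset & t < protocol$onset + protocol$duration
  I <- numeric(length(t))
  if (protocol$kind == "step") {
    I[on] <- protocol$amplitude
  } else {
    phi0 <- protocol$phase_deg * pi / 180
    I[on] <- protocol$offset + protocol$amplitude *
      sin(2 * pi * protocol$frequency * (t[on] - protocol$onset) + phi0)
  }
  I
}

#' @export
print.adex_protocol <- function(x, ...) {
  if (x$kind == "step") {
    cat(sprintf("Step protocol [%s]: %g pA, %g s from t = %g s\n",
                x$id, x$amplitude, x$duration, x$onset))
  } else {
    cat(sprintf(
      "Sinusoid protocol [%s]: %g pA @ %g Hz on %g pA offset, %g s from t = %g s\n",
      x$id, x$amplitude, x$frequency, x$offset, x$duration, x$onset))
  }
  invisible(x)
}

#' Assemble a protocol suite
#'
#' @param ... `adex_protocol` objects (or a single list of them)
#' @return a list of protocols with class `protocol_suite`
#' @export
protocol_suite <- function(...) {
  protos <- list(...)
  if (length(protos) == 1 && !inherits(protos[[1]], "adex_protocol"))
    protos <- protos[[1]]
  if (!length(protos)) stop("protocol suite must not be empty")
  ok <- vapply(protos, inherits, logical(1), "adex_protocol")
  if (!all(ok)) stop("all elements must be adex_protocol objects")
  ids <- vapply(protos, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate protocol ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(protos) <- ids
  structure(protos, class = "protocol_suite")
}

#' Standard stimulation suite for granule-cell fitting
#'
#' Step currents of 10, 16 and 22 pA for 1 s, and sinusoidal currents of 6
#' and 8 pA amplitude on a 12 pA offset for 22.5 s at a grid of frequencies
#' spanning the theta band where granule cells show spiking resonance.
#'
#' @param step_amplitudes step amplitudes (pA)
#' @param step_duration step length (s)
#' @param sin_amplitudes sinusoid amplitudes (pA)
#' @param sin_offset sinusoid offset (pA)
#' @param sin_frequencies oscillation frequencies (Hz)
#' @param sin_duration sinusoid length (s)
#' @return a `protocol_suite`
#' @export
default_protocol_suite <- function(step_amplitudes = c(10, 16, 22),
                                   step_duration = 1,
                                   sin_amplitudes = c(6, 8),
                                   sin_offset = 12,
                                   sin_frequencies = c(1, 2, 4, 6, 8, 10, 12),
                                   sin_duration = 22.5) {
  steps <- lapply(step_amplitudes, step_protocol, duration = step_duration)
  sins <- list()
  for (a in sin_amplitudes)
    for (f in sin_frequencies)
      sins[[length(sins) + 1]] <- sinusoid_protocol(a, sin_offset, f, sin_duration)
  protocol_suite(c(steps, sins))
}

#' Reduced stimulation suite for fast fitting runs
#'
#' A scaled-down version of [default_protocol_suite()]: 0.5-s steps and
#' 2.5-s sinusoids at three theta-band frequencies (4, 6, 8 Hz) per
#' amplitude. 2.5 s holds exactly ten cycles at the lowest frequency, so
#' the usual ten-cycle burst analysis still applies.
#'
#' @return a `protocol_suite`
#' @export
reduced_protocol_suite <- function() {
  default_protocol_suite(step_duration = 0.5,
                         sin_frequencies = c(4, 6, 8),
                         sin_duration = 2.5)
}

#' Serialize a protocol suite to/from plain lists (JSON/YAML-friendly)
#'
#' @param suite a `protocol_suite`
#' @return `protocol_suite_to_list`: a list of plain records with fields
#'   `id`, `kind`, `amplitude_pA`, `offset_pA`, `frequency_Hz`,
#'   `duration_s`, `onset_s`, `phase_deg`.
#' @export
protocol_suite_to_list <- function(suite) {
  stopifnot(inherits(suite, "protocol_suite"))
  unname(lapply(suite, function(p) {
    list(id = p$id, kind = p$kind, amplitude_pA = p$amplitude,
         offset_pA = p$offset, frequency_Hz = p$frequency,
         duration_s = p$duration, onset_s = p$onset, phase_deg = p$phase_deg)
  }))
}

#' @rdname protocol_suite_to_list
#' @param x a list of records as produced by [protocol_suite_to_list()]
#' @export
protocol_suite_from_list <- function(x) {
  protos <- lapply(x, function(r) {
    for (f in c("kind", "amplitude_pA", "duration_s"))
      if (is.null(r[[f]])) stop("protocol record missing field: ", f)
    onset <- if (is.null(r$onset_s)) 0 else r$onset_s
    if (r$kind == "step") {
      step_protocol(r$amplitude_pA, r$duration_s, onset, id = r$id)
    } else if (r$kind == "sinusoid") {
      phase <- if (is.null(r$phase_deg)) 0 else r$phase_deg
      sinusoid_protocol(r$amplitude_pA, r$offset_pA, r$frequency_Hz,
                        r$duration_s, onset, phase, id = r$id)
    } else stop("unknown protocol kind: ", r$kind)
  })
  protocol_suite(protos)
}
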