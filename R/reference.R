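# Synthetic reference targets: the fitting pipeline needs per-stimulus
# target features (normally taken from in vitro recordings); here they can
# be generated by running a known ground-truth parameter set through the
# protocol suite, optionally with feature-level noise.

#' Construct a reference-features object
#'
#' @param targets data.frame with columns `protocol_id`, `feature`
#'   (`mean_frequency`, `first_spike_latency` or `burst_frequency`),
#'   `value`, `units` (`"Hz"` for frequencies, `"s"` for latency)
#' @param protocols optional `protocol_suite` the targets refer to
#' @param provenance `"synthetic"` or `"file"`
#' @return a `reference_features` object
#' @export
reference_features <- function(targets, protocols = NULL,
                               provenance = "synthetic") {
  stopifnot(is.data.frame(targets),
            all(c("protocol_id", "feature", "value", "units") %in%
                  names(targets)))
  known <- c("mean_frequency", "first_spike_latency", "burst_frequency")
  bad <- setdiff(unique(targets$feature), known)
  if (length(bad)) stop("unknown feature(s) in reference: ",
                        paste(bad, collapse = ", "))
  exp_units <- ifelse(targets$feature == "first_spike_latency", "s", "Hz")
  off <- targets$units != exp_units
  if (any(off))
    stop("wrong units for feature ", targets$feature[off][1], ": got '",
         targets$units[off][1], "', expected '", exp_units[off][1],
         "' (latencies must be stored in seconds)")
  if (any(!is.finite(targets$value))) stop("reference values must be finite")
  freq <- targets$feature != "first_spike_latency"
  if (any(targets$value[freq] < 0))
    stop("reference frequencies must be >= 0")
  structure(list(targets = targets[, c("protocol_id", "feature",
                                       "value", "units")],
                 protocols = protocols, provenance = provenance),
            class = "reference_features")
}

#' @export
print.reference_features <- function(x, ...) {
  cat(sprintf("Reference features (%s), %d targets:\n", x$provenance,
              nrow(x$targets)))
  print(x$targets, row.names = FALSE)
  invisible(x)
}

#' Generate reference features from a ground-truth parameter set
#'
#' Runs [extract_features()] on the ground-truth parameters and stores the
#' resulting features as targets. By construction, scoring the ground
#' truth against its own reference gives a total of exactly 0. The
#' generation is noise-free and deterministic; use [perturb_reference()]
#' for noisy targets.
#'
#' @param params ground-truth `adex_parameters`
#' @param suite the `protocol_suite` defining the stimuli
#' @param config a `simulation_config`
#' @param n_cycles sinusoidal cycles analyzed per condition
#' @return a `reference_features` object (provenance `"synthetic"`)
#' @export
generate_reference <- function(params, suite, config = simulation_config(),
                               n_cycles = 10) {
  fs <- extract_features(params, suite, config, n_cycles)
  if (!fs$valid)
    stop("ground-truth simulation diverged; choose a well-behaved parameter set")
  reference_features(feature_set_to_table(fs), protocols = suite,
                     provenance = "synthetic")
}

#' Add feature-level Gaussian noise to reference targets
#'
#' Independent Gaussian noise is added per target value: `sd_frequency_Hz`
#' for the two frequency features and `sd_latency_s` for latencies.
#' Perturbed frequencies are clipped at 0. Uses the current R random
#' stream; call `set.seed()` beforehand for reproducibility.
#'
#' @param ref a `reference_features` object
#' @param sd_frequency_Hz noise sd on frequency targets (Hz), >= 0
#' @param sd_latency_s noise sd on latency targets (s), >= 0
#' @return a perturbed `reference_features` object
#' @export
perturb_reference <- function(ref, sd_frequency_Hz = 0, sd_latency_s = 0) {
  stopifnot(inherits(ref, "reference_features"),
            sd_frequency_Hz >= 0, sd_latency_s >= 0)
  tab <- ref$targets
  is_lat <- tab$feature == "first_spike_latency"
  sds <- ifelse(is_lat, sd_latency_s, sd_frequency_Hz)
  tab$value <- tab$value + rnorm(nrow(tab), 0, sds)
  tab$value[!is_lat] <- pmax(tab$value[!is_lat], 0)
  reference_features(tab, protocols = ref$protocols,
                     provenance = ref$provenance)
}

#' Read and write reference-feature files
#'
#' JSON files hold `{protocols: [...], targets: [...]}` where each target
#' is `{protocol_id, feature, value, units}`; `.csv` paths hold the flat
#' targets table only. Units are validated on read: latencies must be in
#' seconds (`"s"`), frequencies in `"Hz"`. The round trip
#' `read_reference(write_reference(...))` preserves all values.
#'
#' @param ref a `reference_features` object
#' @param path output/input path, ending in `.json` or `.csv`
#' @return `read_reference`: a `reference_features` object
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_features"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(ref$targets, path, row.names = FALSE)
  } else {
    obj <- list(provenance = ref$provenance,
                protocols = if (is.null(ref$protocols)) list() else
                  protocol_suite_to_list(ref$protocols),
                targets = ref$targets)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    return(reference_features(tab, provenance = "file"))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$targets)) stop("reference file missing 'targets' field")
  tab <- as.data.frame(obj$targets, stringsAsFactors = FALSE)
  for (f in c("protocol_id", "feature", "value", "units"))
    if (is.null(tab[[f]])) stop("reference targets missing field: ", f)
  protos <- NULL
  if (!is.null(obj$protocols) && length(obj$protocols)) {
    plist <- obj$protocols
    if (is.data.frame(plist))
      plist <- lapply(seq_len(nrow(plist)), function(i) as.list(plist[i, ]))
    protos <- protocol_suite_from_list(plist)
  }
  reference_features(tab, protocols = protos, provenance = "file")
}

#' Check that a reference covers a protocol suite
#'
#' Every step protocol must have mean-frequency and latency targets and
#' every sinusoidal protocol a burst-frequency target.
#'
#' @param ref a `reference_features` object
#' @param suite a `protocol_suite`
#' @return invisibly TRUE; errors when a target is missing
#' @export
validate_reference <- function(ref, suite) {
  stopifnot(inherits(ref, "reference_features"),
            inherits(suite, "protocol_suite"))
  kinds <- vapply(suite, `[[`, character(1), "kind")
  ids <- vapply(suite, `[[`, character(1), "id")
  .ref_values(ref, "mean_frequency", ids[kinds == "step"])
  .ref_values(ref, "first_spike_latency", ids[kinds == "step"])
  .ref_values(ref, "burst_frequency", ids[kinds == "sinusoid"])
  invisible(TRUE)
}
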