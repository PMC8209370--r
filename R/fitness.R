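# The scalar multi-feature objective: weighted absolute distances between
# simulated and reference features, with a cycle-stability penalty on the
# burst term.

#' Feature weights of the objective function
#'
#' Mean and burst frequency errors are measured in Hz and weighted 1;
#' first-spike latency is measured in seconds and weighted 1000, so a 1
#' Hz error and a 1 ms lag contribute equally to the total score.
#'
#' @param mean_frequency weight on mean-frequency errors (per Hz)
#' @param latency weight on latency errors (per second)
#' @param burst_frequency weight on burst-frequency errors (per Hz)
#' @return a `feature_weights` object
#' @export
feature_weights <- function(mean_frequency = 1, latency = 1000,
                            burst_frequency = 1) {
  w <- c(mean_frequency = mean_frequency, latency = latency,
         burst_frequency = burst_frequency)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  structure(as.list(w), class = "feature_weights")
}

# Pull reference values for one feature, aligned with the given protocol ids.
.ref_values <- function(ref, feature, protocol_ids) {
  tab <- ref$targets
  sel <- tab[tab$feature == feature, , drop = FALSE]
  idx <- match(protocol_ids, sel$protocol_id)
  if (anyNA(idx))
    stop("reference is missing ", feature, " target(s) for: ",
         paste(protocol_ids[is.na(idx)], collapse = ", "))
  sel$value[idx]
}

#' Mean-frequency score component
#'
#' Sum over step stimuli of the absolute difference between simulated and
#' reference mean frequency, times the mean-frequency weight.
#'
#' @param sim a `feature_set`
#' @param ref a `reference_features` object
#' @param weights a `feature_weights` object
#' @return dimensionless score, >= 0
#' @export
mean_frequency_score <- function(sim, ref, weights = feature_weights()) {
  stopifnot(inherits(sim, "feature_set"), inherits(ref, "reference_features"))
  target <- .ref_values(ref, "mean_frequency", sim$steps$protocol_id)
  sum(abs(sim$steps$mean_frequency_Hz - target)) * weights$mean_frequency
}

#' First-spike-latency score component
#'
#' Sum over step stimuli of the absolute latency difference (in seconds),
#' times the latency weight (default 1000, so a 1 ms lag scores 1).
#'
#' @inheritParams mean_frequency_score
#' @return dimensionless score, >= 0
#' @export
latency_score <- function(sim, ref, weights = feature_weights()) {
  stopifnot(inherits(sim, "feature_set"), inherits(ref, "reference_features"))
  target <- .ref_values(ref, "first_spike_latency", sim$steps$protocol_id)
  sum(abs(sim$steps$latency_s - target)) * weights$latency
}

#' Burst-frequency score component
#'
#' Sum over sinusoidal conditions (amplitude x frequency pairs) of the
#' absolute difference between the simulated mean burst frequency and its
#' reference, times the burst weight, times a stability penalty
#' `(sd + 1)` where `sd` is the population standard deviation of the
#' per-cycle burst frequencies: candidates whose bursts drift across
#' cycles are penalized even at matched means.
#'
#' @inheritParams mean_frequency_score
#' @return dimensionless score, >= 0
#' @export
burst_score <- function(sim, ref, weights = feature_weights()) {
  stopifnot(inherits(sim, "feature_set"), inherits(ref, "reference_features"))
  target <- .ref_values(ref, "burst_frequency", sim$sinusoids$protocol_id)
  sum(abs(sim$sinusoids$burst_mean_Hz - target) *
        (sim$sinusoids$burst_sd_Hz + 1)) * weights$burst_frequency
}

#' Penalty assigned to diverged or invalid candidates
#'
#' A large finite constant rather than infinity, so that every candidate
#' remains comparable and results stay serializable.
#' @export
DIVERGENCE_PENALTY <- 1e9

#' Total objective score with per-feature breakdown
#'
#' The objective minimized during fitting: the sum of the three weighted
#' feature scores. Diverged/invalid feature sets receive the finite
#' penalty [DIVERGENCE_PENALTY] in place of computed components, so the
#' optimizer always receives a total ordering.
#'
#' @inheritParams mean_frequency_score
#' @return a `score_breakdown`: list with `score_mean_frequency`,
#'   `score_latency`, `score_burst_frequency`, `total` (their exact sum),
#'   and `penalty_applied`
#' @export
#' @examples
#' p <- example_parameters(1)
#' suite <- reduced_protocol_suite()
#' ref <- generate_reference(p, suite)
#' fs <- extract_features(p, suite)
#' total_score(fs, ref)$total  # 0: a candidate matches its own reference
total_score <- function(sim, ref, weights = feature_weights()) {
  if (!isTRUE(sim$valid)) {
    return(structure(list(score_mean_frequency = DIVERGENCE_PENALTY,
                          score_latency = 0, score_burst_frequency = 0,
                          total = DIVERGENCE_PENALTY, penalty_applied = TRUE),
                     class = "score_breakdown"))
  }
  s_mf <- mean_frequency_score(sim, ref, weights)
  s_lat <- latency_score(sim, ref, weights)
  s_bf <- burst_score(sim, ref, weights)
  structure(list(score_mean_frequency = s_mf, score_latency = s_lat,
                 score_burst_frequency = s_bf, total = s_mf + s_lat + s_bf,
                 penalty_applied = FALSE),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "Score: total %.4f (MF %.4f + LAT %.4f + BF %.4f)%s\n", x$total,
    x$score_mean_frequency, x$score_latency, x$score_burst_frequency,
    if (x$penalty_applied) " [penalty]" else ""))
  invisible(x)
}
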