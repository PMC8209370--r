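# Post-processing of a final population: ranked score decomposition,
# pairwise distances, classical MDS embedding, and parameter summaries.

#' Rank candidates and decompose their scores
#'
#' Re-extracts features for every species center and recomputes the full
#' score breakdown, returning a table sorted by ascending total score.
#' The recomputed totals equal the fitness values cached by the optimizer
#' (both are the same deterministic pipeline).
#'
#' @param population list of `uego_species` (e.g. from [run_uego()])
#' @param reference a `reference_features` object
#' @param suite the `protocol_suite` used for fitting
#' @param bounds parameter bounds used to denormalize centers
#' @param weights a `feature_weights` object
#' @param sim_config a `simulation_config`
#' @param n_cycles sinusoidal cycles analyzed per condition
#' @return data.frame with one row per candidate: `rank`, the ten
#'   parameters in physical units, per-amplitude burst components
#'   (`score_burst_<amp>pA`), the three component scores, `total` and
#'   `radius`
#' @export
rank_candidates <- function(population, reference, suite,
                            bounds = default_parameter_bounds(),
                            weights = feature_weights(),
                            sim_config = simulation_config(),
                            n_cycles = 10) {
  if (!length(population)) stop("population is empty")
  bounds <- validate_parameter_bounds(bounds)
  amps <- sort(unique(vapply(
    Filter(function(p) p$kind == "sinusoid", unclass(suite)),
    `[[`, numeric(1), "amplitude")))
  rows <- lapply(population, function(sp) {
    p <- denormalize_parameters(sp$center, bounds)
    fs <- extract_features(p, suite, sim_config, n_cycles)
    sb <- total_score(fs, reference, weights)
    row <- as.data.frame(as.list(unclass(p)))
    for (a in amps) {
      sel <- fs$sinusoids$amplitude_pA == a
      target <- .ref_values(reference, "burst_frequency",
                            fs$sinusoids$protocol_id[sel])
      row[[sprintf("score_burst_%gpA", a)]] <- if (sb$penalty_applied) NA else
        sum(abs(fs$sinusoids$burst_mean_Hz[sel] - target) *
              (fs$sinusoids$burst_sd_Hz[sel] + 1)) * weights$burst_frequency
    }
    row$score_mean_frequency <- sb$score_mean_frequency
    row$score_latency <- sb$score_latency
    row$score_burst_frequency <- sb$score_burst_frequency
    row$total <- sb$total
    row$cached_fitness <- sp$fitness
    row$radius <- sp$radius
    row
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$total), , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Pairwise Euclidean distances between candidates
#'
#' Each candidate's full parameter vector is treated as a point
#' ("landscape") and compared by plain Euclidean distance, either in
#' physical units or in the normalized unit box.
#'
#' @param population list of `uego_species`
#' @param space `"physical"` (default) or `"normalized"`
#' @param bounds bounds used for denormalization
#' @return a symmetric distance matrix with zero diagonal
#' @export
pairwise_distances <- function(population, space = c("physical", "normalized"),
                               bounds = default_parameter_bounds()) {
  space <- match.arg(space)
  if (length(population) < 2) stop("need at least 2 candidates")
  X <- t(vapply(population, `[[`, numeric(length(population[[1]]$center)),
                "center"))
  if (space == "physical") {
    bounds <- validate_parameter_bounds(bounds)
    X <- sweep(sweep(X, 2, bounds$upper - bounds$lower, `*`), 2,
               bounds$lower, `+`)
  }
  as.matrix(dist(X))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in `dims` dimensions by double-centering the
#' squared distances, eigendecomposing the resulting Gram matrix and
#' scaling the leading eigenvectors by the square roots of their
#' (non-negative) eigenvalues. Distances exactly realizable in `dims`
#' dimensions are reproduced to numerical precision, and the embedded
#' coordinates always have zero centroid.
#'
#' @param distances square symmetric matrix of pairwise distances
#' @param dims embedding dimension (default 2)
#' @return an `mds_embedding`: list with `points` (n x dims matrix) and
#'   `eigenvalues` (full spectrum of the centered Gram matrix, negative
#'   values truncated at 0)
#' @export
classical_mds <- function(distances, dims = 2) {
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances))
    stop("distance matrix must be square")
  if (max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix must be symmetric")
  n <- nrow(distances)
  fit <- cmdscale(distances, k = min(dims, n - 1), eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dims)
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  structure(list(points = unname(pts), eigenvalues = pmax(fit$eig, 0)),
            class = "mds_embedding")
}

#' Per-parameter quantile summary of a candidate subset
#'
#' For each of the ten parameters over the selected candidates: the
#' median, the first and third quartiles, and the 5th and 95th
#' percentiles, all in physical units. Quantiles use linear interpolation
#' between closest ranks (R's default type 7).
#'
#' @param candidates a ranked candidate table from [rank_candidates()] (or
#'   any data.frame holding the ten parameter columns)
#' @param ranks which rows to summarize (default all)
#' @return data.frame with columns `parameter`, `q05`, `q25`, `median`,
#'   `q75`, `q95`
#' @export
parameter_summary <- function(candidates, ranks = seq_len(nrow(candidates))) {
  stopifnot(is.data.frame(candidates))
  sub <- candidates[ranks, , drop = FALSE]
  if (!nrow(sub)) stop("empty candidate subset")
  out <- lapply(.adex_param_names, function(pn) {
    v <- sub[[pn]]
    q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
    data.frame(parameter = pn, q05 = q[1], q25 = q[2], median = q[3],
               q75 = q[4], q95 = q[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Embed a candidate population with classical MDS
#'
#' @param candidates table or population to embed
#' @inheritParams pairwise_distances
#' @param dims embedding dimension
#' @return data.frame (candidate, x, y, ...) plus the eigenvalue spectrum
#'   as attribute `eigenvalues`
#' @export
embed_population <- function(population, space = "physical",
                             bounds = default_parameter_bounds(), dims = 2) {
  D <- pairwise_distances(population, space, bounds)
  emb <- classical_mds(D, dims)
  out <- data.frame(candidate = seq_len(nrow(emb$points)))
  for (k in seq_len(dims)) out[[c("x", "y", "z")[min(k, 3)]]] <- emb$points[, k]
  attr(out, "eigenvalues") <- emb$eigenvalues
  out
}
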