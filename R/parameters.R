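#' @useDynLib adexfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm quantile cmdscale dist median
#' @importFrom utils write.csv read.csv
NULL

# Canonical parameter order used throughout the package (and by the C++ core).
.adex_param_names <- c("C_m", "g_L", "E_L", "V_T", "Delta_T",
                       "V_peak", "V_r", "a", "b", "tau_w")

#' Construct a validated AdEx parameter set
#'
#' The adaptive exponential integrate-and-fire (AdEx) point neuron has ten
#' free parameters. Units follow the pA/pF/nS/mV/ms convention so that the
#' model equations are dimensionally closed (nS*mV = pA, pF*mV/ms = pA).
#'
#' @param C_m membrane capacitance (pF), > 0
#' @param g_L leak conductance (nS), >= 0
#' @param E_L leak reversal potential (mV)
#' @param V_T threshold potential of the exponential term (mV)
#' @param Delta_T slope factor (mV), > 0
#' @param V_peak reset-trigger potential (mV): crossing it records a spike
#' @param V_r reset potential (mV)
#' @param a subthreshold adaptation conductance (nS)
#' @param b spike-triggered adaptation increment (pA)
#' @param tau_w adaptation time constant (ms), > 0
#' @return a named numeric vector of class `adex_parameters`
#' @export
#' @examples
#' p <- adex_parameters(C_m = 4.2, g_L = 0.33, E_L = -79.2, V_T = -20.4,
#'                      Delta_T = 55.9, V_peak = -20, V_r = -76.6,
#'                      a = 0.12, b = -1, tau_w = 7.1)
adex_parameters <- function(C_m, g_L, E_L, V_T, Delta_T, V_peak, V_r,
                            a, b, tau_w) {
  p <- c(C_m = C_m, g_L = g_L, E_L = E_L, V_T = V_T, Delta_T = Delta_T,
         V_peak = V_peak, V_r = V_r, a = a, b = b, tau_w = tau_w)
  validate_adex_parameters(p)
  structure(p, class = "adex_parameters")
}

#' @rdname adex_parameters
#' @param x a named numeric vector (all ten parameter names present)
#' @export
as_adex_parameters <- function(x) {
  stopifnot(is.numeric(x))
  if (!all(.adex_param_names %in% names(x)))
    stop("missing AdEx parameter(s): ",
         paste(setdiff(.adex_param_names, names(x)), collapse = ", "))
  p <- x[.adex_param_names]
  validate_adex_parameters(p)
  structure(p, class = "adex_parameters")
}

validate_adex_parameters <- function(p) {
  if (!all(is.finite(p))) stop("AdEx parameters must all be finite")
  if (p[["C_m"]] <= 0) stop("C_m must be > 0")
  if (p[["tau_w"]] <= 0) stop("tau_w must be > 0")
  if (p[["Delta_T"]] <= 0) stop("Delta_T must be > 0")
  if (p[["g_L"]] < 0) stop("g_L must be >= 0")
  invisible(p)
}

#' @export
print.adex_parameters <- function(x, ...) {
  cat("AdEx parameters (pA/pF/nS/mV/ms units):\n")
  print(unclass(x))
  invisible(x)
}

#' Default search-space bounds for the AdEx parameters
#'
#' Box constraints used to confine the parameter search: capacitance
#' 0.1--5 pF, slope factor 1--1000 mV, leak conductance 0.001--10 nS,
#' leak reversal and reset potentials -80 to -40 mV, threshold -60 to
#' -20 mV, peak -20 to 20 mV, adaptation conductance -1 to 1 nS,
#' spike-triggered increment -1 to 1 pA, adaptation time constant
#' 1--1000 ms. These are the ranges a cerebellar granule cell model may
#' plausibly occupy.
#'
#' @return a data.frame with columns `parameter`, `lower`, `upper`
#' @export
default_parameter_bounds <- function() {
  data.frame(
    parameter = .adex_param_names,
    lower = c(0.1, 0.001, -80, -60, 1, -20, -80, -1, -1, 1),
    upper = c(5.0, 10.0, -40, -20, 1000, 20, -40, 1, 1, 1000),
    stringsAsFactors = FALSE
  )
}

validate_parameter_bounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("parameter", "lower", "upper") %in% names(bounds)))
  if (!setequal(bounds$parameter, .adex_param_names))
    stop("bounds must cover exactly the ten AdEx parameters")
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)))
    stop("bounds must be finite")
  bad <- bounds$parameter[bounds$lower >= bounds$upper]
  if (length(bad))
    stop("lower >= upper for parameter(s): ", paste(bad, collapse = ", "))
  bounds[match(.adex_param_names, bounds$parameter), , drop = FALSE]
}

#' Map parameters to and from the normalized unit box
#'
#' All optimizer geometry (species radii, distances, local-search steps)
#' lives in the normalized space \eqn{[0,1]^{10}}, where each coordinate is
#' the affine rescaling of one physical parameter onto its bound interval.
#' Without this, parameters with wide ranges (e.g. the slope factor, spanning
#' 999 mV) would dominate every Euclidean distance.
#'
#' @param params an `adex_parameters` object (within bounds)
#' @param bounds a bounds data.frame, see [default_parameter_bounds()]
#' @return `normalize_parameters`: a numeric vector in the unit box;
#'   `denormalize_parameters`: an `adex_parameters` object.
#' @export
normalize_parameters <- function(params, bounds = default_parameter_bounds()) {
  bounds <- validate_parameter_bounds(bounds)
  p <- unclass(as_adex_parameters(params))
  x <- (p - bounds$lower) / (bounds$upper - bounds$lower)
  if (any(x < -1e-12 | x > 1 + 1e-12))
    stop("parameters outside the given bounds: ",
         paste(.adex_param_names[x < -1e-12 | x > 1 + 1e-12], collapse = ", "))
  unname(pmin(pmax(x, 0), 1))
}

#' @rdname normalize_parameters
#' @param x a numeric vector of length 10 in the unit box
#' @export
denormalize_parameters <- function(x, bounds = default_parameter_bounds()) {
  bounds <- validate_parameter_bounds(bounds)
  stopifnot(is.numeric(x), length(x) == length(.adex_param_names))
  if (any(x < -1e-12 | x > 1 + 1e-12))
    stop("point outside the unit box")
  x <- pmin(pmax(x, 0), 1)
  p <- bounds$lower + x * (bounds$upper - bounds$lower)
  names(p) <- .adex_param_names
  structure(p, class = "adex_parameters")
}

#' Example granule-cell-like AdEx parameter sets
#'
#' Two plausible cerebellar granule cell configurations, usable as
#' ground-truth generators for synthetic reference features. Both lie
#' inside [default_parameter_bounds()].
#'
#' @param which 1 or 2
#' @return an `adex_parameters` object
#' @export
example_parameters <- function(which = 1) {
  stopifnot(which %in% c(1, 2))
  if (which == 1) {
    adex_parameters(C_m = 4.226, g_L = 0.333, E_L = -79.225, V_T = -20.446,
                    Delta_T = 55.881, V_peak = -19.981, V_r = -76.638,
                    a = 0.123, b = -0.999, tau_w = 7.138)
  } else {
    adex_parameters(C_m = 4.400, g_L = 0.001, E_L = -67.194, V_T = -38.149,
                    Delta_T = 54.382, V_peak = -7.078, V_r = -43.458,
                    a = 0.202, b = 0.140, tau_w = 73.441)
  }
}
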