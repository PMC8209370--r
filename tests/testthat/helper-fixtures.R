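# Shared fixtures: toy objectives and reference parameter sets built in code.

# convex sphere on the unit box, minimum at the center
sphere_objective <- function(x) sum((x - 0.5)^2)

# 1-d objective with two equal-depth wells at 0.2 and 0.8
bimodal_objective <- function(x) min((x - 0.2)^2, (x - 0.8)^2)

constant_objective <- function(x) 1

# objective that strictly improves on every call (forces SASS successes)
make_improving_objective <- function() {
  k <- 0
  function(x) { k <<- k + 1; -k }
}

# objective that records every evaluated point
make_recording_objective <- function(f) {
  pts <- list()
  list(fn = function(x) { pts[[length(pts) + 1]] <<- x; f(x) },
       points = function() pts)
}

# near-LIF parameter sets (adaptation off): slow version for count oracles,
# sharp version (tiny slope factor) for latency oracles
lif_slow_params <- function() {
  adex_parameters(C_m = 5, g_L = 0.05, E_L = -70, V_T = -40, Delta_T = 1,
                  V_peak = -20, V_r = -70, a = 0, b = 0, tau_w = 100)
}
lif_sharp_params <- function() {
  adex_parameters(C_m = 5, g_L = 0.5, E_L = -70, V_T = -40, Delta_T = 0.001,
                  V_peak = -20, V_r = -70, a = 0, b = 0, tau_w = 100)
}

# closed-form leaky-integrate-and-fire period (ms) with threshold V_T
lif_period_ms <- function(p, I) {
  tau_m <- p[["C_m"]] / p[["g_L"]]
  tau_m * log((I - p[["g_L"]] * (p[["V_r"]] - p[["E_L"]])) /
                (I - p[["g_L"]] * (p[["V_T"]] - p[["E_L"]])))
}

# small fast protocol suite for end-to-end tests (two steps, one sinusoid;
# 1.25 s holds ten 8-Hz cycles)
mini_suite <- function() {
  protocol_suite(step_protocol(10, 0.25), step_protocol(16, 0.25),
                 sinusoid_protocol(8, 12, 8, 1.25))
}

# a tiny hand-written reference with one target per feature
make_simple_ref <- function() {
  reference_features(data.frame(
    protocol_id = c("s1", "s1", "b1"),
    feature = c("mean_frequency", "first_spike_latency", "burst_frequency"),
    value = c(40, 0.05, 50),
    units = c("Hz", "s", "Hz"), stringsAsFactors = FALSE))
}

random_population <- function(n, d, radii = runif(n, 0.1, 1)) {
  lapply(seq_len(n), function(i)
    new_species(runif(d), fitness = runif(1), radius = radii[i]))
}
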